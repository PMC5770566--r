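# Shared synthetic scenarios (memoized: built once per test run) and small
# constructed-trajectory builders.

.scenario_cache <- new.env(parent = emptyenv())

scenario <- function(name, builder) {
  if (!exists(name, envir = .scenario_cache)) {
    assign(name, builder(), envir = .scenario_cache)
  }
  get(name, envir = .scenario_cache)
}

# Standard planted site used across scenarios: 500 ns mean dwell, strong
# capture, tight tether.
std_site <- function(p, lf, mirror = TRUE) {
  planted_site(p, leaflet = lf, species = "MGDG", capture_radius = 0.5,
               k_on = 1.0, k_off = 0.002, capacity = 10, tether_sd = 0.09,
               mirror = mirror)
}

# Main "sites" scenario: realistic-density bilayer, toy dimer, three
# C2-mirrored MGDG sites plus two unmirrored decoy attractors.
sites_scenario_config <- function(seed = 11, n_frames = 4000) {
  synthetic_config(
    total_lipids = 800, n_frames = n_frames, dt_frame = 2,
    planted_sites = list(
      std_site(c(7.2, 13.0), "stromal"),
      std_site(c(9.6, 10.6), "stromal"),
      std_site(c(9.6, 15.4), "lumenal"),
      std_site(c(7.0, 9.0), "stromal", mirror = FALSE),
      std_site(c(18.0, 16.0), "lumenal", mirror = FALSE)),
    seed = seed)
}

sites_run <- function() {
  scenario("sites_run", function() generate_trajectory(sites_scenario_config()))
}

# Cavity scenario: gated exchange cavities, no planted sites.
cavity_scenario_config <- function(seed = 5, n_frames = 3000) {
  synthetic_config(total_lipids = 800, n_frames = n_frames, dt_frame = 2,
                   cavity = cavity_config(), seed = seed)
}

cavity_run <- function() {
  scenario("cavity_run",
           function() generate_trajectory(cavity_scenario_config()))
}

# Free-diffusion scenario: no protein, fine time resolution.
diffusion_scenario_config <- function(seed = 7) {
  synthetic_config(total_lipids = 500, proportions = c(MGDG = 1),
                   box = c(40, 40, 9), n_frames = 1200, dt_frame = 0.1,
                   protein = NULL, seed = seed)
}

diffusion_run <- function() {
  scenario("diffusion_run",
           function() generate_trajectory(diffusion_scenario_config()))
}

# --- constructed-trajectory builders ---------------------------------------

# topology of n free lipids (GL1 + C4A), no protein
lipid_topology <- function(n_lip, species = rep("MGDG", n_lip)) {
  cg_topology(data.frame(
    bead_id = seq_len(2 * n_lip) - 1L,
    name = rep(c("GL1", "C4A"), n_lip),
    residue_id = rep(seq_len(n_lip), each = 2L),
    residue_name = rep(species, each = 2L),
    molecule_id = rep(seq_len(n_lip), each = 2L),
    subunit = "LIPID",
    species = rep(species, each = 2L),
    is_headgroup = rep(c(TRUE, FALSE), n_lip),
    is_tail_terminal = rep(c(FALSE, TRUE), n_lip),
    is_cocrystallized = FALSE,
    stringsAsFactors = FALSE))
}

# topology of k protein residues (one BB bead each) followed by n lipids
protein_lipid_topology <- function(n_prot, n_lip,
                                   res_names = rep(c("ARG", "LYS", "TYR",
                                                     "ASN", "GLY"),
                                                   length.out = n_prot)) {
  prot <- data.frame(
    bead_id = seq_len(n_prot) - 1L, name = "BB",
    residue_id = seq_len(n_prot), residue_name = res_names,
    molecule_id = 1L, subunit = "P1", species = "PROTEIN",
    is_headgroup = FALSE, is_tail_terminal = FALSE,
    is_cocrystallized = FALSE, stringsAsFactors = FALSE)
  lip <- data.frame(
    bead_id = n_prot + seq_len(2 * n_lip) - 1L,
    name = rep(c("GL1", "C4A"), n_lip),
    residue_id = n_prot + rep(seq_len(n_lip), each = 2L),
    residue_name = "MGDG",
    molecule_id = 1L + rep(seq_len(n_lip), each = 2L),
    subunit = "LIPID", species = "MGDG",
    is_headgroup = rep(c(TRUE, FALSE), n_lip),
    is_tail_terminal = rep(c(FALSE, TRUE), n_lip),
    is_cocrystallized = FALSE, stringsAsFactors = FALSE)
  cg_topology(rbind(prot, lip),
              monomer_map = c("1" = "none"))
}

# trajectory from a list of n_beads x 3 coordinate matrices
make_traj <- function(coords_list, box = c(10, 10, 10), dt = 1) {
  nb <- nrow(coords_list[[1]])
  nf <- length(coords_list)
  coords <- array(0, dim = c(nb, 3L, nf))
  for (i in seq_len(nf)) coords[, , i] <- coords_list[[i]]
  cg_trajectory((seq_len(nf) - 1L) * dt, coords,
                matrix(box, nf, 3, byrow = TRUE))
}

# --- independent oracles -----------------------------------------------------

# exhaustive greedy GROMOS clustering, naive O(n^2) set intersections
oracle_gromos <- function(sets, overlap = 0.70) {
  n <- length(sets)
  pool <- seq_len(n)
  nbr <- function(i, j) {
    length(intersect(sets[[i]], sets[[j]])) /
      min(length(sets[[i]]), length(sets[[j]])) >= overlap
  }
  clusters <- list()
  while (length(pool) > 0L) {
    counts <- vapply(pool, function(i) {
      sum(vapply(pool, function(j) nbr(i, j), logical(1)))
    }, numeric(1))
    centre <- pool[which.max(counts)]
    members <- pool[vapply(pool, function(j) nbr(centre, j), logical(1))]
    clusters[[length(clusters) + 1L]] <- sort(members)
    pool <- setdiff(pool, members)
  }
  clusters
}

# exhaustive flood-fill connected components by repeated dilation
oracle_components <- function(occ, threshold, connectivity = 26) {
  above <- which(occ >= threshold, arr.ind = TRUE)
  if (nrow(above) == 0L) return(list())
  touching <- function(a, b) {
    d <- abs(a - b)
    if (connectivity == 26) all(d <= 1L) && any(d > 0L) else sum(d) == 1L
  }
  labels <- rep(0L, nrow(above))
  cur <- 0L
  for (s in seq_len(nrow(above))) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    repeat {
      grown <- FALSE
      for (i in which(labels == cur)) {
        for (j in which(labels == 0L)) {
          if (touching(above[i, ], above[j, ])) {
            labels[j] <- cur
            grown <- TRUE
          }
        }
      }
      if (!grown) break
    }
  }
  lapply(seq_len(cur), function(k) above[labels == k, , drop = FALSE])
}

# canonical form of a voxel set for comparison
voxel_key <- function(vox) {
  paste(sort(paste(vox[, 1], vox[, 2], vox[, 3])), collapse = ";")
}

# single-cutoff contact tracker (per-frame thresholding + run-length
# encoding), the limit oracle for the dual-cutoff machine
oracle_single_cutoff <- function(traj, head_row, site_rows, cutoff) {
  nf <- n_frames(traj)
  inside <- vapply(seq_len(nf), function(f) {
    d <- min_image_dist(traj$coords[head_row, , f],
                        matrix(traj$coords[site_rows, , f], ncol = 3),
                        traj$box[f, ])
    min(d) <= cutoff
  }, logical(1))
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(t_start = traj$times[starts[r$values]],
             t_end = traj$times[pmin(ends[r$values] + 1L, nf)],
             censored = ends[r$values] == nf)
}

# debounced ground-truth crossing list: applies the same persistence rule
# as the detector to the generator's true crossing log
debounced_truth <- function(run, hysteresis = 50) {
  gt <- run$ground_truth
  traj <- run$trajectory
  dt <- diff(traj$times[1:2])
  min_run <- max(1L, ceiling(hysteresis / dt))
  nf <- n_frames(traj)
  out <- list()
  for (lip in unique(gt$crossings$lipid_id)) {
    cr <- gt$crossings[gt$crossings$lipid_id == lip, , drop = FALSE]
    cr <- cr[order(cr$time), , drop = FALSE]
    # rebuild the state sequence on the frame grid
    state0 <- if (cr$direction[1] == "entry") 0L else
      match(cr$monomer[1], c("A", "B"))
    change_frames <- round(cr$time / dt) + 1L
    s <- integer(nf)
    s[] <- state0
    for (k in seq_len(nrow(cr))) {
      new_state <- if (cr$direction[k] == "entry")
        match(cr$monomer[k], c("A", "B")) else 0L
      s[change_frames[k]:nf] <- new_state
    }
    r <- rle(s)
    keep_vals <- r$values[1]
    keep_starts <- 1L
    pos <- 1L
    for (k in seq_along(r$lengths)[-1L]) {
      pos <- pos + r$lengths[k - 1L]
      persistent <- r$lengths[k] >= min_run || k == length(r$lengths)
      if (persistent && r$values[k] != keep_vals[length(keep_vals)]) {
        keep_vals <- c(keep_vals, r$values[k])
        keep_starts <- c(keep_starts, pos)
      }
    }
    if (length(keep_vals) < 2L) next
    for (k in seq_along(keep_vals)[-1L]) {
      to <- keep_vals[k]
      from <- keep_vals[k - 1L]
      f <- keep_starts[k]
      orig <- cr[abs(cr$time - traj$times[f]) < dt / 2, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        lipid_id = lip,
        direction = if (to != 0L) "entry" else "exit",
        channel = if (nrow(orig) > 0L) orig$channel[1] else NA_character_,
        time = traj$times[f],
        monomer = c("A", "B")[if (to != 0L) to else from],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lipid_id = integer(), direction = character(),
                      channel = character(), time = numeric(),
                      monomer = character()))
  }
  d <- do.call(rbind, out)
  d[order(d$time, d$lipid_id), , drop = FALSE]
}
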