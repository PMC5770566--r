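# Synthetic coarse-grained membrane trajectories with known ground truth.
#
# Lipids are represented minimally (one GL1 headgroup bead plus one
# tail-terminal bead) and perform 2D Brownian steps in their leaflet plane
# with periodic wrap and reflection (step rejection) at the protein
# footprint.  Binding sites are Markov traps: a free lipid of the target
# species entering the capture radius binds with a per-step probability and,
# once bound, unbinds each step with probability 1 - exp(-k_off * dt),
# giving analytically known (geometric, i.e. discretized exponential) dwell
# times.  Released lipids are re-injected uniformly into the bulk so that
# successive binding events are independent.  An optional exchange cavity
# per monomer is connected to the bulk by gated channel apertures; every
# boundary crossing is logged to the ground truth.

#' Define a planted binding site
#'
#' @param position length-2 or length-3 position, nm.  Interpreted laterally;
#'   the z position follows the site's leaflet headgroup plane.  Positions
#'   are given for monomer A; with `mirror = TRUE` a C2-image copy is planted
#'   in monomer B.
#' @param leaflet `"stromal"` or `"lumenal"`
#' @param species target lipid species (residue name, e.g. `"MGDG"`)
#' @param capture_radius nm; binding can occur inside this lateral disc
#' @param k_on per-step binding probability while inside the capture radius
#' @param k_off unbinding rate, ns^-1
#' @param capacity maximum number of simultaneously bound lipids (`Inf` for
#'   an uncapacitated trap)
#' @param tether_sd lateral jitter (nm, per axis) of a bound lipid about the
#'   site centre
#' @param mirror also plant the C2-symmetric partner site in monomer B
#' @param release what happens on unbinding: `"eject"` (default) re-injects
#'   the lipid uniformly into the bulk, making successive binding episodes
#'   independent (the right regime for residence-time recovery); `"in_place"`
#'   releases it where it is, which preserves local detailed balance so the
#'   stationary disc enrichment matches [expected_enrichment()] exactly
#' @return list of class `planted_site`
#' @export
planted_site <- function(position, leaflet = "stromal", species = "MGDG",
                         capture_radius = 0.5, k_on = 0.5, k_off = 0.002,
                         capacity = Inf, tether_sd = 0.12, mirror = TRUE,
                         release = c("eject", "in_place")) {
  stopifnot(k_on >= 0, k_on <= 1, k_off > 0, capture_radius > 0)
  release <- match.arg(release)
  structure(list(position = position[1:2], leaflet = leaflet,
                 species = species, capture_radius = capture_radius,
                 k_on = k_on, k_off = k_off, capacity = capacity,
                 tether_sd = tether_sd, mirror = mirror, release = release),
            class = "planted_site")
}

#' Define the exchange cavity geometry
#'
#' One cavity per monomer: a lateral disc whose wall is impenetrable except
#' at named channel apertures, each of which is open in any frame with its
#' own probability.  The monomer-B cavity is the C2 image of the monomer-A
#' one.
#'
#' @param offset length-2 lateral offset of the cavity centre from the
#'   monomer-A protein centre, nm
#' @param radius cavity disc radius, nm
#' @param channels named list (names are channel labels, e.g. `"I"`); each
#'   element a list with `angle` (radians, aperture position on the cavity
#'   circle), `radius` (aperture half-width, nm) and `open_probability`
#'   (per frame)
#' @param initial_occupants named integer vector, residue name -> count of
#'   cocrystallized lipids initially inside each cavity (default 3 PG,
#'   2 DGDG, 2 MGDG, 2 SQDG)
#' @return list of class `cavity_config`
#' @export
cavity_config <- function(offset = c(0, -3.2), radius = 0.8,
                          channels = list(
                            I   = list(angle = pi / 2, radius = 0.3,
                                       open_probability = 0.02),
                            II  = list(angle = 7 * pi / 6, radius = 0.3,
                                       open_probability = 0.0),
                            III = list(angle = 11 * pi / 6, radius = 0.3,
                                       open_probability = 0.05)),
                          initial_occupants = c(PG = 3, DGDG = 2, MGDG = 2,
                                                SQDG = 2)) {
  stopifnot(radius > 0)
  for (ch in channels) {
    stopifnot(ch$open_probability >= 0, ch$open_probability <= 1)
  }
  structure(list(offset = offset, radius = radius, channels = channels,
                 initial_occupants = initial_occupants),
            class = "cavity_config")
}

#' Toy C2-symmetric dimer footprint
#'
#' Two mirrored rings of static backbone beads (one bead per fake residue,
#' residue names cycled over the 20 amino acids), each ring carrying several
#' z layers so that both leaflets contact the protein.  Lipids are excluded
#' from a lateral disc of `exclusion_radius` around each monomer centre.
#'
#' @param box length-3 box, nm
#' @param monomer_offset lateral half-distance between monomer centres, nm
#' @param ring_radius radius of the bead ring, nm
#' @param n_positions angular bead positions per ring
#' @param z_layers bead z offsets from the membrane midplane, nm
#' @param exclusion_radius lateral lipid exclusion radius per monomer, nm
#' @return list of class `protein_footprint`
#' @export
toy_dimer_protein <- function(box = c(26, 26, 9), monomer_offset = 3.4,
                              ring_radius = 1.8, n_positions = 60,
                              z_layers = seq(-1.8, 1.8, by = 0.6),
                              exclusion_radius = 2.2) {
  centre <- c(box[1] / 2, box[2] / 2)
  centers <- rbind(A = c(centre[1] - monomer_offset, centre[2]),
                   B = c(centre[1] + monomer_offset, centre[2]))
  theta <- seq(0, 2 * pi, length.out = n_positions + 1L)[seq_len(n_positions)]
  build_monomer <- function(mon) {
    cx <- centers[mon, 1]; cy <- centers[mon, 2]
    # C2 image: monomer B ring traversed at mirrored angles so that residue
    # labels correspond between the monomers
    ang <- if (mon == "A") theta else theta + pi
    grid <- expand.grid(pos = seq_len(n_positions), layer = seq_along(z_layers))
    data.frame(
      x = cx + ring_radius * cos(ang[grid$pos]),
      y = cy + ring_radius * sin(ang[grid$pos]),
      z = box[3] / 2 + z_layers[grid$layer],
      residue_name = AA3[((grid$pos + grid$layer - 2L) %% 20L) + 1L],
      subunit = paste0("P", mon, ((grid$pos - 1L) %/%
                                    ceiling(n_positions / 4)) + 1L),
      monomer = mon,
      stringsAsFactors = FALSE
    )
  }
  beads <- rbind(build_monomer("A"), build_monomer("B"))
  beads$residue_id <- seq_len(nrow(beads))
  structure(list(beads = beads, centers = centers,
                 exclusion_radius = exclusion_radius,
                 c2_point = c(centre, box[3] / 2)),
            class = "protein_footprint")
}

#' Build a synthetic membrane configuration
#'
#' The defaults emulate a thylakoid-like bilayer: five lipid species at
#' 40/25/15/10/10 mol % (MGDG, DGDG, singly-unsaturated SQDG, saturated
#' SQDG, PG), a lateral diffusion coefficient of 0.05 nm^2/ns (so that a
#' 1 nm displacement takes on average ~5 ns), a static C2-symmetric dimer
#' footprint, and optionally planted binding sites and exchange cavities.
#'
#' @param total_lipids total membrane lipid count (cavity occupants extra)
#' @param proportions named numeric vector of mole fractions per residue name
#' @param box length-3 box, nm
#' @param n_frames number of saved frames (the dynamics time step equals the
#'   frame interval; no sub-stepping)
#' @param dt_frame frame interval, ns
#' @param diffusion_D lateral diffusion coefficient, nm^2/ns
#' @param protein a `protein_footprint`, or `NULL` for a protein-free bilayer
#' @param planted_sites list of [planted_site()]
#' @param cavity a [cavity_config()], or `NULL` (requires `protein`)
#' @param seed integer RNG seed; identical (config, seed) gives bit-identical
#'   trajectories
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(total_lipids = 400,
                             proportions = c(MGDG = 0.40, DGDG = 0.25,
                                             SQDG = 0.15, SQDS = 0.10,
                                             PG = 0.10),
                             box = c(26, 26, 9), n_frames = 1000,
                             dt_frame = 2, diffusion_D = 0.05,
                             protein = toy_dimer_protein(box),
                             planted_sites = list(), cavity = NULL,
                             seed = 1) {
  stopifnot(diffusion_D > 0, n_frames >= 1, dt_frame > 0, all(box > 0),
            all(proportions >= 0))
  if (!is.null(cavity) && is.null(protein)) {
    stop("a cavity requires a protein footprint (cavities are anchored to ",
         "the monomer centres)")
  }
  n_per <- round(proportions / sum(proportions) * total_lipids)
  area_per_lipid <- (box[1] * box[2] * 2) / max(sum(n_per), 1L)
  if (area_per_lipid < 0.4) {
    stop("lipid count too high for box area: ", signif(area_per_lipid, 3),
         " nm^2 per lipid (< 0.4)")
  }
  structure(list(n_lipids_per_species = n_per, box = box,
                 n_frames = n_frames, dt_frame = dt_frame,
                 diffusion_D = diffusion_D, protein = protein,
                 planted_sites = planted_sites, cavity = cavity, seed = seed),
            class = "synthetic_config")
}

SPECIES_OF_RESNAME <- c(MGDG = "MGDG", DGDG = "DGDG", SQDG = "SQDG",
                        SQDS = "SQDG", PG = "PG")

# Expand planted sites (and their C2 mirrors) into a flat data.frame.
expand_sites <- function(config) {
  sites <- config$planted_sites
  if (length(sites) == 0L) {
    return(data.frame(x = numeric(), y = numeric(), leaflet = character(),
                      species = character(), capture_radius = numeric(),
                      k_on = numeric(), k_off = numeric(),
                      capacity = numeric(), tether_sd = numeric(),
                      release = character(),
                      monomer = character(), pair_id = integer(),
                      stringsAsFactors = FALSE))
  }
  centre <- config$box[1:2] / 2
  rows <- list()
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    rows[[length(rows) + 1L]] <-
      data.frame(x = s$position[1], y = s$position[2], leaflet = s$leaflet,
                 species = s$species, capture_radius = s$capture_radius,
                 k_on = s$k_on, k_off = s$k_off, capacity = s$capacity,
                 tether_sd = s$tether_sd, release = s$release %||% "eject",
                 monomer = "A", pair_id = i,
                 stringsAsFactors = FALSE)
    if (isTRUE(s$mirror)) {
      img <- 2 * centre - s$position[1:2]
      rows[[length(rows) + 1L]] <-
        data.frame(x = img[1], y = img[2], leaflet = s$leaflet,
                   species = s$species, capture_radius = s$capture_radius,
                   k_on = s$k_on, k_off = s$k_off, capacity = s$capacity,
                   tether_sd = s$tether_sd, release = s$release %||% "eject",
                   monomer = "B", pair_id = i,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Cavity geometry for both monomers: centres, radii, aperture positions.
expand_cavities <- function(config) {
  cav <- config$cavity
  if (is.null(cav)) return(NULL)
  centre <- config$box[1:2] / 2
  ca <- config$protein$centers["A", ] + cav$offset
  cb <- 2 * centre - ca
  ch_names <- names(cav$channels)
  ap <- function(cc, mirrored) {
    t(vapply(cav$channels, function(ch) {
      a <- if (mirrored) ch$angle + pi else ch$angle
      cc + cav$radius * c(cos(a), sin(a))
    }, numeric(2)))
  }
  list(centers = rbind(A = ca, B = cb), radius = cav$radius,
       channel_names = ch_names,
       open_probability = vapply(cav$channels, `[[`, numeric(1),
                                 "open_probability"),
       channel_radius = vapply(cav$channels, `[[`, numeric(1), "radius"),
       apertures = list(A = ap(ca, FALSE), B = ap(cb, TRUE)))
}

in_disc <- function(xy, centre, radius, box) {
  dx <- xy[, 1] - centre[1]; dy <- xy[, 2] - centre[2]
  dx <- dx - box[1] * floor(dx / box[1] + 0.5)
  dy <- dy - box[2] * floor(dy / box[2] + 0.5)
  dx * dx + dy * dy <= radius * radius
}

lateral_dist <- function(xy, centre, box) {
  dx <- xy[, 1] - centre[1]; dy <- xy[, 2] - centre[2]
  dx <- dx - box[1] * floor(dx / box[1] + 0.5)
  dy <- dy - box[2] * floor(dy / box[2] + 0.5)
  sqrt(dx * dx + dy * dy)
}

#' Generate a synthetic trajectory with ground truth
#'
#' Runs the Brownian dynamics described in the package vignette and returns
#' the topology, the trajectory and a ground-truth record of every true
#' binding episode and every cavity channel crossing.
#'
#' @param config a [synthetic_config()]
#' @return list of class `synthetic_run` with elements `topology`
#'   (`cg_topology`), `trajectory` (`cg_trajectory`), `ground_truth` (list
#'   with `bind_events`, `crossings`, `leaflet`, `sites`, `cavities`) and
#'   `config`
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  box <- config$box
  dt <- config$dt_frame
  nf <- config$n_frames
  midz <- box[3] / 2
  head_dz <- 1.8; tail_dz <- 0.4

  prot <- config$protein
  prot_xyz <- NULL
  n_prot <- 0L
  if (!is.null(prot)) {
    prot_xyz <- as.matrix(prot$beads[, c("x", "y", "z")])
    n_prot <- nrow(prot_xyz)
  }
  cavs <- expand_cavities(config)
  sites <- expand_sites(config)
  n_sites <- nrow(sites)
  site_p_off <- 1 - exp(-sites$k_off * dt)

  # --- membrane lipid bookkeeping -------------------------------------------
  n_per <- config$n_lipids_per_species
  resname <- rep(names(n_per), n_per)
  n_mem <- length(resname)
  # split each species evenly over the leaflets
  leaflet <- unlist(lapply(n_per, function(k) {
    rep(c("stromal", "lumenal"), length.out = k)
  }), use.names = FALSE)
  cav_res <- character(0); cav_leaf <- character(0); cav_of <- integer(0)
  if (!is.null(cavs)) {
    occ <- config$cavity$initial_occupants
    for (m in 1:2) {
      r <- rep(names(occ), occ)
      cav_res <- c(cav_res, r)
      cav_leaf <- c(cav_leaf, rep(c("stromal", "lumenal"),
                                  length.out = length(r)))
      cav_of <- c(cav_of, rep(m, length(r)))
    }
  }
  n_cav <- length(cav_res)
  n_lip <- n_mem + n_cav
  lip_res <- c(resname, cav_res)
  lip_species <- unname(SPECIES_OF_RESNAME[lip_res])
  lip_leaf <- c(leaflet, cav_leaf)
  z_head <- ifelse(lip_leaf == "stromal", midz + head_dz, midz - head_dz)
  z_tail <- ifelse(lip_leaf == "stromal", midz + tail_dz, midz - tail_dz)

  blocked <- function(xy) {
    # protein exclusion discs + (for non-occupants) cavity discs
    bad <- rep(FALSE, nrow(xy))
    if (!is.null(prot)) {
      for (m in 1:2) {
        bad <- bad | in_disc(xy, prot$centers[m, ], prot$exclusion_radius, box)
      }
    }
    if (!is.null(cavs)) {
      for (m in 1:2) bad <- bad | in_disc(xy, cavs$centers[m, ], cavs$radius,
                                          box)
    }
    bad
  }
  draw_free <- function(k) {
    out <- matrix(NA_real_, k, 2)
    need <- seq_len(k)
    while (length(need) > 0L) {
      cand <- cbind(stats::runif(length(need), 0, box[1]),
                    stats::runif(length(need), 0, box[2]))
      bad <- blocked(cand)
      if (n_sites > 0L) {
        for (s in seq_len(n_sites)) {
          bad <- bad | in_disc(cand, c(sites$x[s], sites$y[s]),
                               sites$capture_radius[s], box)
        }
      }
      out[need[!bad], ] <- cand[!bad, , drop = FALSE]
      need <- need[bad]
    }
    out
  }

  pos <- matrix(NA_real_, n_lip, 2)
  pos[seq_len(n_mem), ] <- draw_free(n_mem)
  in_cavity <- rep(NA_integer_, n_lip)
  if (n_cav > 0L) {
    for (i in seq_len(n_cav)) {
      m <- cav_of[i]
      repeat {
        r <- cavs$radius * sqrt(stats::runif(1))
        a <- stats::runif(1, 0, 2 * pi)
        p <- cavs$centers[m, ] + r * c(cos(a), sin(a))
        break
      }
      pos[n_mem + i, ] <- p
      in_cavity[n_mem + i] <- m
    }
  }
  bound_site <- rep(NA_integer_, n_lip)
  bind_start <- rep(NA_real_, n_lip)

  # --- topology --------------------------------------------------------------
  beads <- list()
  if (n_prot > 0L) {
    pb <- prot$beads
    beads$protein <- data.frame(
      bead_id = seq_len(n_prot) - 1L, name = "BB",
      residue_id = pb$residue_id, residue_name = pb$residue_name,
      molecule_id = match(pb$subunit, unique(pb$subunit)),
      subunit = pb$subunit, species = "PROTEIN",
      is_headgroup = FALSE, is_tail_terminal = FALSE,
      is_cocrystallized = FALSE, stringsAsFactors = FALSE)
  }
  n_prot_mol <- if (n_prot > 0L) length(unique(prot$beads$subunit)) else 0L
  lip_mol <- n_prot_mol + seq_len(n_lip)
  beads$lipids <- data.frame(
    bead_id = n_prot + seq_len(2L * n_lip) - 1L,
    name = rep(c("GL1", "C4A"), n_lip),
    residue_id = rep(max(if (n_prot > 0L) prot$beads$residue_id else 0L) +
                       seq_len(n_lip), each = 2L),
    residue_name = rep(lip_res, each = 2L),
    molecule_id = rep(lip_mol, each = 2L),
    subunit = "LIPID",
    species = rep(lip_species, each = 2L),
    is_headgroup = rep(c(TRUE, FALSE), n_lip),
    is_tail_terminal = rep(c(FALSE, TRUE), n_lip),
    is_cocrystallized = rep(c(rep(FALSE, n_mem), rep(TRUE, n_cav)),
                            each = 2L),
    stringsAsFactors = FALSE)
  bead_df <- do.call(rbind, beads)
  rownames(bead_df) <- NULL
  monomer_map <- NULL
  c2_axis <- NULL
  if (n_prot > 0L) {
    mm <- tapply(prot$beads$monomer, match(prot$beads$subunit,
                                           unique(prot$beads$subunit)),
                 function(x) x[1])
    monomer_map <- stats::setNames(as.character(mm), names(mm))
    c2_axis <- list(point = prot$c2_point, direction = c(0, 0, 1))
  }
  topo <- cg_topology(bead_df, monomer_map = monomer_map, c2_axis = c2_axis)

  # site bead sets: protein beads within 0.8 nm (3D) of the site anchor
  site_residues <- vector("list", n_sites)
  if (n_sites > 0L && n_prot > 0L) {
    for (s in seq_len(n_sites)) {
      anchor <- c(sites$x[s], sites$y[s],
                  if (sites$leaflet[s] == "stromal") midz + head_dz
                  else midz - head_dz)
      d <- min_image_dist(anchor, prot_xyz, box)
      site_residues[[s]] <- which(d <= 0.8)  # protein bead rows (1-based)
    }
  }

  # --- dynamics ---------------------------------------------------------------
  step_sd <- sqrt(2 * config$diffusion_D * dt)
  n_beads_total <- n_prot + 2L * n_lip
  coords <- array(0, dim = c(n_beads_total, 3L, nf))
  times <- (seq_len(nf) - 1L) * dt

  bind_log <- list(); cross_log <- list()
  occupancy <- if (n_sites > 0L) integer(n_sites) else integer(0)
  if (n_sites > 0L) {
    site_xy <- cbind(sites$x, sites$y)
  }

  store_frame <- function(f) {
    if (n_prot > 0L) coords[seq_len(n_prot), , f] <<- prot_xyz
    rows <- n_prot + seq_len(2L * n_lip)
    head_rows <- rows[seq(1L, 2L * n_lip, by = 2L)]
    tail_rows <- rows[seq(2L, 2L * n_lip, by = 2L)]
    coords[head_rows, 1:2, f] <<- pos
    coords[head_rows, 3, f] <<- z_head
    coords[tail_rows, 1:2, f] <<- pos
    coords[tail_rows, 3, f] <<- z_tail
  }
  store_frame(1L)

  for (f in seq_len(nf)[-1L]) {
    t_now <- times[f]
    ## 1. unbinding
    if (n_sites > 0L) {
      bnd <- which(!is.na(bound_site))
      if (length(bnd) > 0L) {
        u <- stats::runif(length(bnd))
        rel <- bnd[u < site_p_off[bound_site[bnd]]]
        if (length(rel) > 0L) {
          rel_site <- bound_site[rel]
          for (i in rel) {
            s <- bound_site[i]
            bind_log[[length(bind_log) + 1L]] <-
              c(lipid = i, site = s, t_start = bind_start[i], t_end = t_now,
                censored = 0)
            occupancy[s] <- occupancy[s] - 1L
          }
          bound_site[rel] <- NA_integer_
          bind_start[rel] <- NA_real_
          eject <- rel[sites$release[rel_site] == "eject"]
          if (length(eject) > 0L) pos[eject, ] <- draw_free(length(eject))
        }
      }
    }
    ## 2. channel gating
    if (!is.null(cavs)) {
      open_now <- matrix(stats::runif(2L * length(cavs$channel_names)) <
                           rep(cavs$open_probability, each = 2L),
                         nrow = 2L)
    }
    ## 3. diffusion of unbound lipids
    mobile <- which(is.na(bound_site))
    if (length(mobile) > 0L) {
      prop <- pos[mobile, , drop = FALSE] +
        matrix(stats::rnorm(2L * length(mobile), sd = step_sd), ncol = 2L)
      prop[, 1] <- prop[, 1] - box[1] * floor(prop[, 1] / box[1])
      prop[, 2] <- prop[, 2] - box[2] * floor(prop[, 2] / box[2])
      reject <- rep(FALSE, length(mobile))
      outside_now <- is.na(in_cavity[mobile])
      # protein exclusion applies everywhere
      if (!is.null(prot)) {
        for (m in 1:2) {
          reject <- reject | in_disc(prop, prot$centers[m, ],
                                     prot$exclusion_radius, box)
        }
      }
      new_cav <- rep(NA_integer_, length(mobile))
      if (!is.null(cavs)) {
        for (m in 1:2) {
          ins <- in_disc(prop, cavs$centers[m, ], cavs$radius, box)
          new_cav[ins] <- m
        }
        was <- in_cavity[mobile]
        crossing <- !reject & (!is.na(was) | !is.na(new_cav)) &
          (is.na(was) | is.na(new_cav) | was != new_cav)
        if (any(crossing)) {
          for (j in which(crossing)) {
            m_from <- was[j]; m_to <- new_cav[j]
            m_gate <- if (!is.na(m_to)) m_to else m_from
            # crossing permitted only through an open aperture of that cavity
            apert <- cavs$apertures[[m_gate]]
            d_ap <- lateral_dist(apert, prop[j, ], box)
            ok <- which(open_now[m_gate, ] & d_ap <= cavs$channel_radius)
            if (length(ok) == 0L) {
              reject[j] <- TRUE
            } else {
              ch <- ok[which.min(d_ap[ok])]
              i <- mobile[j]
              cross_log[[length(cross_log) + 1L]] <- data.frame(
                lipid = i, species = lip_species[i],
                direction = if (!is.na(m_to)) "entry" else "exit",
                channel = cavs$channel_names[ch], time = t_now,
                monomer = c("A", "B")[m_gate], stringsAsFactors = FALSE)
            }
          }
        }
        # confined occupants may not cross the wall outside an aperture
      }
      acc <- !reject
      idx <- mobile[acc]
      pos[idx, ] <- prop[acc, , drop = FALSE]
      if (!is.null(cavs)) in_cavity[idx] <- new_cav[acc]
    }
    ## 4. binding
    if (n_sites > 0L) {
      for (s in seq_len(n_sites)) {
        if (occupancy[s] >= sites$capacity[s]) next
        cand <- which(is.na(bound_site) & is.na(in_cavity) &
                        lip_species == sites$species[s] &
                        lip_leaf == sites$leaflet[s])
        if (length(cand) == 0L) next
        d <- lateral_dist(pos[cand, , drop = FALSE], site_xy[s, ], box)
        cand <- cand[d <= sites$capture_radius[s]]
        if (length(cand) == 0L) next
        hit <- cand[stats::runif(length(cand)) < sites$k_on[s]]
        n_slots <- sites$capacity[s] - occupancy[s]
        if (length(hit) > n_slots) hit <- hit[seq_len(n_slots)]
        if (length(hit) > 0L) {
          bound_site[hit] <- s
          bind_start[hit] <- t_now
          occupancy[s] <- occupancy[s] + length(hit)
        }
      }
      # tethered jitter for all bound lipids (including newly bound)
      bnd <- which(!is.na(bound_site))
      if (length(bnd) > 0L) {
        jit <- matrix(stats::rnorm(2L * length(bnd)), ncol = 2L) *
          sites$tether_sd[bound_site[bnd]]
        r <- sqrt(rowSums(jit^2))
        cap <- sites$capture_radius[bound_site[bnd]]
        scale <- ifelse(r > 0.99 * cap, 0.99 * cap / r, 1)
        pos[bnd, ] <- site_xy[bound_site[bnd], , drop = FALSE] + jit * scale
      }
    }
    store_frame(f)
  }

  # censored (still bound) episodes
  if (n_sites > 0L) {
    for (i in which(!is.na(bound_site))) {
      bind_log[[length(bind_log) + 1L]] <-
        c(lipid = i, site = bound_site[i], t_start = bind_start[i],
          t_end = times[nf], censored = 1)
    }
  }
  bind_events <- if (length(bind_log) > 0L) {
    be <- as.data.frame(do.call(rbind, bind_log))
    be$lipid_id <- lip_mol[be$lipid]
    be$species <- lip_species[be$lipid]
    be$duration <- be$t_end - be$t_start
    be$censored <- be$censored == 1
    be[order(be$t_start), c("lipid_id", "species", "site", "t_start",
                            "t_end", "duration", "censored")]
  } else {
    data.frame(lipid_id = integer(), species = character(), site = integer(),
               t_start = numeric(), t_end = numeric(), duration = numeric(),
               censored = logical())
  }
  crossings <- if (length(cross_log) > 0L) {
    cr <- do.call(rbind, cross_log)
    cr$lipid_id <- lip_mol[cr$lipid]
    cr[, c("lipid_id", "species", "direction", "channel", "time", "monomer")]
  } else {
    data.frame(lipid_id = integer(), species = character(),
               direction = character(), channel = character(),
               time = numeric(), monomer = character())
  }
  sites_out <- sites
  if (n_sites > 0L) {
    sites_out$site_bead_rows <- I(site_residues)
    sites_out$z <- ifelse(sites$leaflet == "stromal", midz + head_dz,
                          midz - head_dz)
  }
  structure(list(
    topology = topo,
    trajectory = cg_trajectory(times, coords,
                               matrix(rep(box, nf), nf, 3, byrow = TRUE)),
    ground_truth = list(
      bind_events = bind_events, crossings = crossings,
      leaflet = stats::setNames(lip_leaf, as.character(lip_mol)),
      sites = sites_out, cavities = cavs,
      lipid_molecule_ids = lip_mol,
      cavity_initial = if (n_cav > 0L)
        table(species = lip_species[n_mem + seq_len(n_cav)],
              cavity = cav_of) else NULL),
    config = config), class = "synthetic_run")
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat("Synthetic membrane run:", n_frames(x$trajectory), "frames x",
      x$config$dt_frame, "ns,", sum(x$config$n_lipids_per_species),
      "membrane lipids\n")
  cat("  ground truth:", nrow(x$ground_truth$bind_events), "binding episodes,",
      nrow(x$ground_truth$crossings), "cavity crossings\n")
  invisible(x)
}

#' Expected steady-state annular enrichment of a planted site
#'
#' For the Markov-trap binding model the stationary excess density in a
#' site's capture disc follows from the two-state occupancy balance.  For an
#' uncapacitated trap each lipid independently satisfies detailed balance
#' between "free inside the disc" and "bound", giving an enrichment factor
#' `1 + k_on / p_off` with `p_off = 1 - exp(-k_off * dt)`.  For a finite
#' capacity C the bound count follows a birth-death (Erlang-loss-like)
#' stationary law, evaluated numerically under a Poisson approximation for
#' the in-disc free count.
#'
#' @param config a [synthetic_config()]
#' @return data.frame with one row per expanded site (both monomers):
#'   species, leaflet, monomer and `enrichment` (disc density / bulk density)
#' @export
expected_enrichment <- function(config) {
  sites <- expand_sites(config)
  if (nrow(sites) == 0L) {
    return(data.frame(species = character(), leaflet = character(),
                      monomer = character(), enrichment = numeric()))
  }
  p_off <- 1 - exp(-sites$k_off * config$dt_frame)
  area <- config$box[1] * config$box[2]
  if (!is.null(config$protein)) {
    area <- area - 2 * pi * config$protein$exclusion_radius^2
  }
  if (!is.null(config$cavity)) area <- area - 2 * pi * config$cavity$radius^2
  enr <- numeric(nrow(sites))
  for (s in seq_len(nrow(sites))) {
    if (is.infinite(sites$capacity[s])) {
      enr[s] <- 1 + sites$k_on[s] / p_off[s]
    } else {
      # per-leaflet bulk density of the target species (bound depletion
      # ignored; adequate for sparse traps)
      n_leaf <- config$n_lipids_per_species
      sp_res <- names(SPECIES_OF_RESNAME)[SPECIES_OF_RESNAME ==
                                            sites$species[s]]
      n_sp <- sum(n_leaf[intersect(names(n_leaf), sp_res)]) / 2
      rho <- n_sp / area
      a <- rho * pi * sites$capture_radius[s]^2 * sites$k_on[s] / p_off[s]
      k <- 0:sites$capacity[s]
      log_pi <- k * log(a) - lfactorial(k)
      pk <- exp(log_pi - max(log_pi)); pk <- pk / sum(pk)
      en <- sum(k * pk)
      enr[s] <- 1 + en / (rho * pi * sites$capture_radius[s]^2)
    }
  }
  data.frame(species = sites$species, leaflet = sites$leaflet,
             monomer = sites$monomer, enrichment = enr,
             stringsAsFactors = FALSE)
}

#' Estimate the lateral diffusion coefficient from a trajectory
#'
#' Regression of the lateral mean-squared displacement of lipid headgroups
#' over lag times; for 2D Brownian motion MSD(t) = 4 D t.
#'
#' @param run a `synthetic_run` (or list with `topology` and `trajectory`)
#' @param lags_ns numeric vector of lag times, ns
#' @param max_origins number of time origins averaged per lag
#' @return list with `D` (nm^2/ns) and the per-lag `msd` table
#' @export
estimate_diffusion <- function(run, lags_ns = seq(1, 100, by = 3),
                               max_origins = 20L) {
  traj <- run$trajectory
  b <- run$topology$beads
  rows <- which(b$is_headgroup)
  dt <- diff(traj$times[1:2])
  lag_frames <- unique(pmax(1L, round(lags_ns / dt)))
  nf <- n_frames(traj)
  lag_frames <- lag_frames[lag_frames < nf]
  msd <- vapply(lag_frames, function(L) {
    origins <- unique(round(seq(1L, nf - L, length.out =
                                  min(max_origins, nf - L))))
    m <- vapply(origins, function(o) {
      v <- min_image_vector(traj$coords[rows, , o],
                            traj$coords[rows, , o + L], traj$box[o, ])
      mean(v[, 1]^2 + v[, 2]^2)
    }, numeric(1))
    mean(m)
  }, numeric(1))
  lag_ns <- lag_frames * dt
  fit <- stats::lm(msd ~ lag_ns)
  list(D = unname(stats::coef(fit)[2] / 4),
       msd = data.frame(lag_ns = lag_ns, msd = msd))
}

#' Mean first-passage time to a given lateral displacement
#'
#' For each lipid headgroup, the elapsed time until its unwrapped lateral
#' displacement from the first frame first reaches `r`.  For 2D Brownian
#' motion started at the centre of a disc of radius r the expectation is
#' r^2 / (4 D).
#'
#' Because displacements are only observed on the frame grid, the sampled
#' path systematically overshoots the threshold before the crossing is
#' seen, which biases the sampled first-passage time upward.  With
#' `overshoot_correction = TRUE` (default) the detection threshold is
#' lowered by the expected overshoot of a Gaussian random walk,
#' 0.5826 times the per-step displacement standard deviation (Siegmund's
#' corrected diffusion approximation), so that the estimate refers to the
#' continuous-time path.
#'
#' @param run a `synthetic_run`
#' @param r displacement threshold, nm
#' @param overshoot_correction apply the discrete-sampling threshold
#'   correction
#' @return list with `mean_ns`, `n_reached`, `n_lipids`
#' @export
mean_first_passage <- function(run, r = 1.0, overshoot_correction = TRUE) {
  if (overshoot_correction) {
    dt <- run$config$dt_frame
    step_sd <- sqrt(2 * run$config$diffusion_D * dt)
    r <- r - 0.5826 * step_sd
  }
  traj <- run$trajectory
  b <- run$topology$beads
  rows <- which(b$is_headgroup)
  nf <- n_frames(traj)
  disp2 <- matrix(0, length(rows), nf)
  acc <- matrix(0, length(rows), 2)
  for (f in 2:nf) {
    v <- min_image_vector(traj$coords[rows, , f - 1L],
                          traj$coords[rows, , f], traj$box[f, ])
    acc <- acc + v[, 1:2, drop = FALSE]
    disp2[, f] <- acc[, 1]^2 + acc[, 2]^2
  }
  first <- apply(disp2 >= r^2, 1, function(z) {
    w <- which(z); if (length(w) == 0L) NA_integer_ else w[1]
  })
  reached <- !is.na(first)
  list(mean_ns = mean(traj$times[first[reached]]),
       n_reached = sum(reached), n_lipids = length(rows))
}

#' Write a synthetic run to disk
#'
#' Emits the first frame as GRO, the full trajectory in the plain-text
#' fixture format, the ground-truth events as JSON and the dwell table as
#' CSV.
#'
#' @param run a `synthetic_run`
#' @param prefix output path prefix
#' @return character vector of paths written, invisibly
#' @export
write_synthetic_run <- function(run, prefix) {
  f1 <- get_frame(run$trajectory, 1L)
  paths <- c(gro = paste0(prefix, ".gro"),
             trj = paste0(prefix, ".trj"),
             json = paste0(prefix, "_ground_truth.json"),
             csv = paste0(prefix, "_dwells.csv"))
  write_gro(run$topology, f1$xyz, f1$box, paths["gro"])
  write_fixture_trajectory(run$trajectory, paths["trj"])
  jsonlite::write_json(list(bind_events = run$ground_truth$bind_events,
                            crossings = run$ground_truth$crossings),
                       paths["json"], auto_unbox = TRUE, digits = NA)
  utils::write.csv(run$ground_truth$bind_events, paths["csv"],
                   row.names = FALSE)
  invisible(paths)
}
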