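# Per-species, per-leaflet lateral lipid density maps normalized to the
# species' bulk density in the membrane plane.

#' Quadruple the box and center/fit the trajectory on the protein
#'
#' To avoid periodic-boundary artifacts in lateral density maps, each frame
#' is replicated 2 x 2 in the membrane plane, the protein image closest to
#' the enlarged box centre is chosen as the fit target, the frame is
#' translated so that this image sits at the centre, and a rigid fit onto
#' the reference protein is applied.  Lipid images from all four replicas
#' are retained so that the window centred on the protein is fully sampled.
#'
#' @param traj a `cg_trajectory` (jump-free coordinates assumed)
#' @param topology a `cg_topology`
#' @param reference reference frame (default: first frame, protein centred)
#' @param in_plane restrict the rotational fit to the membrane plane
#' @return list of class `quadrupled_trajectory`: `topology_rep` (bead table
#'   replicated 4x with `replica` column), `frames` (list of fitted frames),
#'   `window_box` (the reference box, centred on the protein)
#' @export
quadruple_and_center <- function(traj, topology, reference = NULL,
                                 in_plane = FALSE) {
  b <- topology$beads
  prot_rows <- which(b$species == "PROTEIN")
  if (length(prot_rows) == 0L) stop("no protein beads in topology")
  sel <- protein_backbone_selection(topology)
  if (is.null(reference)) reference <- get_frame(traj, 1L)

  nb <- nrow(b)
  offsets <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  nf <- n_frames(traj)
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    big_box <- c(2 * fr$box[1], 2 * fr$box[2], fr$box[3])
    centre <- c(big_box[1] / 2, big_box[2] / 2)
    xyz4 <- do.call(rbind, lapply(seq_len(4L), function(r) {
      out <- fr$xyz
      out[, 1] <- out[, 1] + offsets[r, 1] * fr$box[1]
      out[, 2] <- out[, 2] + offsets[r, 2] * fr$box[2]
      out
    }))
    # protein image nearest the enlarged-box centre
    cent_dist <- vapply(seq_len(4L), function(r) {
      rows <- prot_rows + (r - 1L) * nb
      cm <- colMeans(xyz4[rows, 1:2, drop = FALSE])
      sum((cm - centre)^2)
    }, numeric(1))
    r_best <- which.min(cent_dist)
    target_rows <- prot_rows + (r_best - 1L) * nb
    shift <- centre - colMeans(xyz4[target_rows, 1:2, drop = FALSE])
    xyz4[, 1] <- xyz4[, 1] + shift[1]
    xyz4[, 2] <- xyz4[, 2] + shift[2]
    big <- list(time = fr$time, xyz = xyz4, box = big_box)
    fit_sel <- sel + (r_best - 1L) * nb
    ref_sel_xyz <- reference$xyz[sel, , drop = FALSE]
    ref_centre <- c(reference$box[1] / 2, reference$box[2] / 2)
    # place the reference protein at the window centre
    ref_shift <- c(centre - ref_centre, 0) +
      c(ref_centre - colMeans(reference$xyz[prot_rows, 1:2, drop = FALSE]), 0)
    ref_xyz <- sweep(ref_sel_xyz, 2, -ref_shift)
    fit <- kabsch_fit(big$xyz[fit_sel, , drop = FALSE], ref_xyz,
                      in_plane = in_plane)
    big$xyz <- sweep(big$xyz %*% fit$R, 2, fit$t, "+")
    frames[[i]] <- big
  }
  win_origin <- c((2 * traj$box[1, 1]) / 2 - traj$box[1, 1] / 2,
                  (2 * traj$box[1, 2]) / 2 - traj$box[1, 2] / 2)
  structure(list(topology_rep = data.frame(b[rep(seq_len(nb), 4L), ],
                                           replica = rep(1:4, each = nb)),
                 frames = frames,
                 window_origin = win_origin,
                 window_box = traj$box[1, ]),
            class = "quadrupled_trajectory")
}

#' Compute a normalized lateral density map
#'
#' Time-averaged 2D histogram of the reference-bead (default GL1) positions
#' of one lipid species in one leaflet, over the window centred on the
#' protein, divided by the mean over all bins so that 1 corresponds to the
#' bulk density in the membrane plane.  Cocrystallized lipids are included.
#' Leaflets are re-assigned per frame.
#'
#' @param quad a `quadrupled_trajectory` from [quadruple_and_center()], or a
#'   plain `cg_trajectory` (then `topology` is used directly and no window
#'   cropping beyond the box is applied)
#' @param topology a `cg_topology` (required when `quad` is a plain
#'   trajectory)
#' @param species lipid species (`"MGDG"`, `"DGDG"`, `"SQDG"`, `"PG"`)
#' @param leaflet `"stromal"` or `"lumenal"`
#' @param bin_size lateral bin size, nm
#' @param reference_bead bead name representing the lipid position
#' @param exclude_footprint if TRUE, bins whose time-averaged count is zero
#'   (the protein footprint) are excluded from the normalization mean
#' @return object of class `density_map`: list with `grid` (matrix, x rows),
#'   `species`, `leaflet`, `bin_size`, `n_frames`, `origin`
#' @export
compute_density_map <- function(quad, topology = NULL, species, leaflet,
                                bin_size = 0.25, reference_bead = "GL1",
                                exclude_footprint = FALSE) {
  if (inherits(quad, "quadrupled_trajectory")) {
    beads <- quad$topology_rep
    frames <- quad$frames
    origin <- quad$window_origin
    window <- quad$window_box[1:2]
    base_topology <- topology
  } else if (inherits(quad, "cg_trajectory")) {
    if (is.null(topology)) stop("supply a topology with a plain trajectory")
    beads <- topology$beads
    frames <- lapply(seq_len(n_frames(quad)), function(i) get_frame(quad, i))
    origin <- c(0, 0)
    window <- quad$box[1, 1:2]
    base_topology <- topology
  } else {
    stop("quad must be a quadrupled_trajectory or cg_trajectory")
  }
  sel_sp <- beads$species == species & beads$name == reference_bead
  if (!any(sel_sp)) {
    stop("no '", reference_bead, "' beads of species ", species,
         " in the system")
  }
  nx <- max(1L, round(window[1] / bin_size))
  ny <- max(1L, round(window[2] / bin_size))
  counts <- matrix(0, nx, ny)
  nf <- length(frames)
  for (i in seq_len(nf)) {
    fr <- frames[[i]]
    leaf <- leaflet_of_rows(fr, beads)
    rows <- which(sel_sp & leaf == leaflet)
    if (length(rows) == 0L) next
    x <- fr$xyz[rows, 1] - origin[1]
    y <- fr$xyz[rows, 2] - origin[2]
    keep <- x >= 0 & x < window[1] & y >= 0 & y < window[2]
    if (!any(keep)) next
    ix <- pmin(nx, floor(x[keep] / bin_size) + 1L)
    iy <- pmin(ny, floor(y[keep] / bin_size) + 1L)
    tab <- table(factor(ix + nx * (iy - 1L), levels = seq_len(nx * ny)))
    counts <- counts + matrix(as.numeric(tab), nx, ny)
  }
  if (sum(counts) == 0) {
    stop("no ", species, " ", reference_bead, " beads observed in the ",
         leaflet, " leaflet")
  }
  mean_count <- if (exclude_footprint) {
    mean(counts[counts > 0])
  } else {
    mean(counts)
  }
  grid <- counts / mean_count
  structure(list(grid = grid, species = species, leaflet = leaflet,
                 bin_size = bin_size, n_frames = nf, origin = origin,
                 exclude_footprint = exclude_footprint),
            class = "density_map")
}

# per-bead leaflet label for one frame ("stromal"/"lumenal"/NA for
# non-lipid beads), matched to headgroup molecules
leaflet_of_rows <- function(frame, beads) {
  tail_rows <- which(beads$is_tail_terminal)
  midplane <- stats::median(frame$xyz[tail_rows, 3])
  out <- rep(NA_character_, nrow(beads))
  lip <- which(beads$is_headgroup)
  out[lip] <- ifelse(frame$xyz[lip, 3] >= midplane, "stromal", "lumenal")
  out
}

#' @export
print.density_map <- function(x, ...) {
  cat("Density map:", x$species, "/", x$leaflet, "-", nrow(x$grid), "x",
      ncol(x$grid), "bins of", x$bin_size, "nm,", x$n_frames, "frames\n")
  cat("  normalized mean:", format(mean(x$grid)), " max:",
      format(max(x$grid)), "\n")
  invisible(x)
}

#' Plot a density map as a heat map
#'
#' @param x a `density_map`
#' @param cap display cap in units of bulk density (values above are shown
#'   at the cap; the stored grid is never capped)
#' @param ... passed to [graphics::image()]
#' @export
plot.density_map <- function(x, cap = 2, ...) {
  g <- pmin(x$grid, cap)
  xs <- x$origin[1] + (seq_len(nrow(g)) - 0.5) * x$bin_size
  ys <- x$origin[2] + (seq_len(ncol(g)) - 0.5) * x$bin_size
  graphics::image(xs, ys, g, xlab = "x (nm)", ylab = "y (nm)",
                  main = paste0(x$species, " / ", x$leaflet,
                                " (bulk-normalized, cap ", cap, ")"),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Write a density map as a CSV matrix
#' @param map a `density_map`
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_density_csv <- function(map, path) {
  utils::write.csv(map$grid, path, row.names = FALSE)
  invisible(path)
}
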