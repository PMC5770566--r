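# Binding-site detection from 3D headgroup occupancy grids.
#
# A voxel's occupancy is the fraction of frames in which at least one
# headgroup bead of the species falls inside it.  Candidate sites are
# maximal 26-connected components of voxels at or above a per-species
# threshold; only sites observed in both monomers (within a tolerance after
# C2 mapping) are kept.

#' Compute a 3D headgroup occupancy grid
#'
#' @param traj a `cg_trajectory` whose frames are already fitted on the
#'   protein (see [fit_frame()]); for a static-protein synthetic run the raw
#'   trajectory is already in the protein frame
#' @param topology a `cg_topology`
#' @param species lipid species
#' @param resolution voxel edge, nm (default 0.2)
#' @param origin grid origin, nm (default c(0,0,0))
#' @param dims integer grid dimensions; default covers the first-frame box
#' @return object of class `occupancy_grid`: `occupancy` (3D array of
#'   fraction-of-frames in [0,1]), `resolution`, `origin`, `species`,
#'   `n_frames`
#' @export
compute_occupancy_grid <- function(traj, topology, species, resolution = 0.2,
                                   origin = c(0, 0, 0), dims = NULL) {
  if (resolution <= 0) stop("resolution must be > 0")
  b <- topology$beads
  rows <- which(b$species == species & b$is_headgroup)
  if (length(rows) == 0L) stop("no headgroup beads of species ", species)
  box <- traj$box[1, ]
  if (is.null(dims)) dims <- pmax(1L, ceiling((box - origin) / resolution))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  hit_count <- numeric(nx * ny * nz)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, rows, f)
    ix <- floor((xyz[, 1] - origin[1]) / resolution) + 1L
    iy <- floor((xyz[, 2] - origin[2]) / resolution) + 1L
    iz <- floor((xyz[, 3] - origin[3]) / resolution) + 1L
    keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny & iz >= 1L & iz <= nz
    if (!any(keep)) next
    lin <- unique(ix[keep] + nx * (iy[keep] - 1L) +
                    nx * ny * (iz[keep] - 1L))
    hit_count[lin] <- hit_count[lin] + 1
  }
  structure(list(occupancy = array(hit_count / nf, dim = c(nx, ny, nz)),
                 resolution = resolution, origin = origin, species = species,
                 n_frames = nf),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  occ <- x$occupancy
  cat("Occupancy grid:", x$species, "-", paste(dim(occ), collapse = " x "),
      "voxels of", x$resolution, "nm,", x$n_frames, "frames\n")
  cat("  max occupancy:", format(max(occ)), " mean (occupied voxels):",
      format(mean(occ[occ > 0])), "\n")
  invisible(x)
}

#' Ratio of a threshold to the bulk mean occupancy
#'
#' Helper reporting how a chosen iso-occupancy threshold compares with the
#' mean occupancy of all lipid-visited voxels ("bulk occupancy"); note that
#' bulk occupancy is not the same as bulk concentration, since not every
#' grid point is occupied by a lipid in every frame.
#'
#' @param grid an `occupancy_grid`
#' @param threshold occupancy threshold
#' @return threshold / mean occupancy over voxels with occupancy > 0
#' @export
threshold_bulk_ratio <- function(grid, threshold) {
  occ <- grid$occupancy
  threshold / mean(occ[occ > 0])
}

NEIGHBOR_OFFSETS_26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1,
                                             dz = -1:1))
NEIGHBOR_OFFSETS_26 <- NEIGHBOR_OFFSETS_26[
  rowSums(abs(NEIGHBOR_OFFSETS_26)) > 0, ]
NEIGHBOR_OFFSETS_6 <- NEIGHBOR_OFFSETS_26[
  rowSums(abs(NEIGHBOR_OFFSETS_26)) == 1, ]

#' Extract candidate binding-site blobs from an occupancy grid
#'
#' Maximal connected components (26-neighbour by default) of voxels with
#' occupancy >= threshold.  Blobs smaller than `min_voxels` are discarded.
#' Blobs are sorted by peak occupancy (descending), ties broken by
#' lexicographic centroid order.
#'
#' @param grid an `occupancy_grid`
#' @param threshold occupancy threshold in (0, 1]
#' @param min_voxels minimum voxel count per blob
#' @param connectivity 26 (default) or 6
#' @return list of blobs; each a list with `voxels` (n x 3 integer matrix of
#'   voxel indices), `centroid` (nm), `peak_occupancy`, `n_voxels`,
#'   `species`
#' @export
extract_sites <- function(grid, threshold, min_voxels = 2L,
                          connectivity = 26) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  occ <- grid$occupancy
  dims <- dim(occ)
  above <- which(occ >= threshold)
  if (length(above) == 0L) return(list())
  offsets <- if (connectivity == 26) NEIGHBOR_OFFSETS_26 else
    if (connectivity == 6) NEIGHBOR_OFFSETS_6 else
      stop("connectivity must be 6 or 26")
  coord <- arrayInd(above, dims)
  lin_index <- above
  lookup <- integer(0)
  lookup[lin_index] <- seq_along(lin_index)  # sparse positional lookup
  label <- integer(length(lin_index))
  current <- 0L
  for (start in seq_along(lin_index)) {
    if (label[start] != 0L) next
    current <- current + 1L
    queue <- start
    label[start] <- current
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      base <- coord[v, ]
      nb <- sweep(offsets, 2, base, "+")
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
        nb[, 2] >= 1L & nb[, 2] <= dims[2] &
        nb[, 3] >= 1L & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      nb_lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) +
        dims[1] * dims[2] * (nb[, 3] - 1L)
      nb_pos <- lookup[nb_lin]
      nb_pos <- nb_pos[!is.na(nb_pos) & nb_pos > 0L]
      nb_pos <- nb_pos[label[nb_pos] == 0L]
      if (length(nb_pos) > 0L) {
        label[nb_pos] <- current
        queue <- c(queue, nb_pos)
      }
    }
  }
  blobs <- lapply(seq_len(current), function(k) {
    vox <- coord[label == k, , drop = FALSE]
    vals <- occ[lin_index[label == k]]
    centroid <- grid$origin + (colMeans(vox) - 0.5) * grid$resolution
    list(voxels = vox, centroid = centroid, peak_occupancy = max(vals),
         n_voxels = nrow(vox), species = grid$species)
  })
  blobs <- Filter(function(bl) bl$n_voxels >= min_voxels, blobs)
  if (length(blobs) == 0L) return(blobs)
  ord <- order(-vapply(blobs, `[[`, numeric(1), "peak_occupancy"),
               vapply(blobs, function(b) b$centroid[1], numeric(1)),
               vapply(blobs, function(b) b$centroid[2], numeric(1)),
               vapply(blobs, function(b) b$centroid[3], numeric(1)))
  blobs[ord]
}

#' C2 image of a position
#'
#' Two-fold rotation about the (membrane-normal) axis through
#' `c2_axis$point`: lateral coordinates are point-reflected, z is kept.
#'
#' @param pos length-3 position or n x 3 matrix, nm
#' @param c2_axis list with `point` and `direction` (assumed along z)
#' @return mapped position(s)
#' @export
c2_image <- function(pos, c2_axis) {
  p <- c2_axis$point
  if (is.matrix(pos)) {
    cbind(2 * p[1] - pos[, 1], 2 * p[2] - pos[, 2], pos[, 3])
  } else {
    c(2 * p[1] - pos[1], 2 * p[2] - pos[2], pos[3])
  }
}

#' Keep only binding sites observed in both monomers
#'
#' Each blob centroid is mapped through the C2 rotation; a blob is kept iff
#' another blob of the same species and leaflet lies within
#' `match_tolerance` of its image.  Kept blobs are paired, assigned ids of
#' the form `<species letter><leaflet letter><index>` (index by descending
#' peak occupancy of the pair), and labelled with `*` (monomer A) or `#`
#' (monomer B).
#'
#' @param blobs list of blobs from [extract_sites()]; each must additionally
#'   carry a `leaflet` element (set it from the grid's leaflet, or use
#'   [detect_binding_sites()] which does this)
#' @param c2_axis the topology's C2 axis
#' @param match_tolerance nm
#' @return data.frame of binding sites (site_id, label, species, leaflet,
#'   monomer, partner_id, x, y, z, peak_occupancy, n_voxels) plus a `blob`
#'   list-column with the voxel sets
#' @export
symmetry_filter <- function(blobs, c2_axis, match_tolerance = 0.5) {
  if (length(blobs) == 0L) return(empty_sites_df())
  cent <- t(vapply(blobs, `[[`, numeric(3), "centroid"))
  species <- vapply(blobs, `[[`, character(1), "species")
  leaflet <- vapply(blobs, function(b) b$leaflet %||% "stromal", character(1))
  img <- c2_image(cent, c2_axis)
  n <- length(blobs)
  partner <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(partner[i])) next
    cand <- setdiff(which(species == species[i] & leaflet == leaflet[i] &
                            is.na(partner)), i)
    if (length(cand) == 0L) next
    d <- sqrt(rowSums(sweep(cent[cand, , drop = FALSE], 2, img[i, ])^2))
    j <- cand[which.min(d)]
    if (min(d) <= match_tolerance) {
      partner[i] <- j
      partner[j] <- i
    }
  }
  keep <- which(!is.na(partner))
  if (length(keep) == 0L) return(empty_sites_df())
  # monomer label: side of the C2 axis along x (convention: A on -x side)
  monomer <- ifelse(cent[, 1] < c2_axis$point[1], "A", "B")
  pair_first <- keep[keep < partner[keep]]
  peak <- vapply(blobs, `[[`, numeric(1), "peak_occupancy")
  pair_peak <- pmax(peak[pair_first], peak[partner[pair_first]])
  rows <- list()
  sp_letter <- c(MGDG = "M", DGDG = "D", SQDG = "S", PG = "P")
  lf_letter <- c(stromal = "S", lumenal = "L")
  for (key in unique(paste(species[pair_first], leaflet[pair_first]))) {
    sel <- pair_first[paste(species[pair_first], leaflet[pair_first]) == key]
    sel <- sel[order(-pair_peak[match(sel, pair_first)])]
    for (k in seq_along(sel)) {
      i <- sel[k]; j <- partner[i]
      id <- paste0(sp_letter[[species[i]]], lf_letter[[leaflet[i]]], k)
      for (m in c(i, j)) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = id,
          label = paste0(id, if (monomer[m] == "A") "*" else "#"),
          species = species[m], leaflet = leaflet[m], monomer = monomer[m],
          partner_id = paste0(id, if (monomer[m] == "A") "#" else "*"),
          x = cent[m, 1], y = cent[m, 2], z = cent[m, 3],
          peak_occupancy = peak[m],
          n_voxels = blobs[[m]]$n_voxels,
          stringsAsFactors = FALSE)
        rows[[length(rows)]]$blob <- I(list(blobs[[m]]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_sites_df <- function() {
  data.frame(site_id = character(), label = character(),
             species = character(), leaflet = character(),
             monomer = character(), partner_id = character(),
             x = numeric(), y = numeric(), z = numeric(),
             peak_occupancy = numeric(), n_voxels = integer(),
             stringsAsFactors = FALSE)
}

#' Detect symmetric binding sites for one species and leaflet
#'
#' Convenience wrapper: occupancy grid (restricted to the leaflet's
#' headgroup z range) -> blob extraction -> C2 symmetry filter.
#'
#' @param traj fitted `cg_trajectory`
#' @param topology `cg_topology` with a `c2_axis`
#' @param species lipid species
#' @param leaflet `"stromal"` or `"lumenal"`
#' @param threshold occupancy threshold (standard defaults: 0.36 MGDG,
#'   0.06 PG, 0.45 DGDG, 0.30 SQDG; see [default_site_thresholds()])
#' @param resolution voxel edge, nm
#' @param min_voxels minimum blob size
#' @param match_tolerance C2 match tolerance, nm
#' @return data.frame of binding sites (see [symmetry_filter()])
#' @export
detect_binding_sites <- function(traj, topology, species, leaflet,
                                 threshold = default_site_thresholds()[species],
                                 resolution = 0.2, min_voxels = 2L,
                                 match_tolerance = 0.5) {
  if (is.null(topology$c2_axis)) stop("topology has no C2 axis")
  grid <- compute_occupancy_grid(traj, topology, species, resolution)
  # restrict voxels to the leaflet: z above/below the tail-bead midplane
  fr <- get_frame(traj, 1L)
  midplane <- stats::median(fr$xyz[topology$beads$is_tail_terminal, 3])
  zc <- grid$origin[3] + (seq_len(dim(grid$occupancy)[3]) - 0.5) *
    grid$resolution
  mask <- if (leaflet == "stromal") zc >= midplane else zc < midplane
  grid$occupancy[, , !mask] <- 0
  blobs <- extract_sites(grid, threshold, min_voxels = min_voxels)
  blobs <- lapply(blobs, function(b) { b$leaflet <- leaflet; b })
  symmetry_filter(blobs, topology$c2_axis, match_tolerance)
}

#' Per-species iso-occupancy thresholds
#'
#' Fraction-of-frames thresholds used to draw candidate binding sites:
#' 36% for MGDG, 6% for PG, 45% for DGDG, 30% for SQDG.  The non-MGDG
#' values compensate for relative abundance and headgroup size and are
#' plain configuration values.
#'
#' @return named numeric vector
#' @export
default_site_thresholds <- function() {
  c(MGDG = 0.36, PG = 0.06, DGDG = 0.45, SQDG = 0.30)
}

#' Write an occupancy grid in OpenDX format
#'
#' Readable by VMD and PyMOL for iso-surface inspection.
#'
#' @param grid an `occupancy_grid`
#' @param path output .dx file
#' @return `path`, invisibly
#' @export
write_dx <- function(grid, path) {
  d <- dim(grid$occupancy)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1] * 10, grid$origin[2] * 10,
            grid$origin[3] * 10),
    sprintf("delta %g 0 0", grid$resolution * 10),
    sprintf("delta 0 %g 0", grid$resolution * 10),
    sprintf("delta 0 0 %g", grid$resolution * 10),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX order: z fastest
  vals <- as.numeric(aperm(grid$occupancy, c(1, 2, 3))[
    cbind(rep(seq_len(d[1]), each = d[2] * d[3]),
          rep(rep(seq_len(d[2]), each = d[3]), d[1]),
          rep(seq_len(d[3]), d[1] * d[2]))])
  apply(matrix(c(vals, rep(NA, (3 - length(vals) %% 3) %% 3)),
               ncol = 3, byrow = TRUE), 1, function(row) {
    writeLines(paste(format(row[!is.na(row)], digits = 6), collapse = " "),
               con)
  })
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
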