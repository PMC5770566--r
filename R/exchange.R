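# Lipid exchange between the protein cavity and the bulk membrane:
# entry/exit detection with hysteresis debouncing, channel assignment,
# fluxes, cavity composition time series, and cocrystallized-lipid mobility
# classes.

#' Define cavity regions for exchange analysis
#'
#' @param centers 2 x 2 matrix (rows A, B) of lateral cavity centres, nm
#' @param radius cavity disc radius, nm
#' @param apertures list with elements `A` and `B`, each a k x 2 matrix of
#'   lateral aperture positions (rownames = channel labels)
#' @return list of class `cavity_region`
#' @export
cavity_region <- function(centers, radius, apertures) {
  stopifnot(nrow(centers) == 2L, radius > 0)
  d <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  if (d < 2 * radius) {
    stop("cavity regions of the two monomers overlap (centre distance ",
         signif(d, 3), " < 2 x radius)")
  }
  structure(list(centers = centers, radius = radius, apertures = apertures),
            class = "cavity_region")
}

#' Cavity region of a synthetic run
#'
#' @param run a `synthetic_run` with a cavity
#' @return a [cavity_region()]
#' @export
cavity_region_of <- function(run) {
  cavs <- run$ground_truth$cavities
  if (is.null(cavs)) stop("synthetic run has no cavity")
  ap <- lapply(cavs$apertures, function(m) {
    rownames(m) <- cavs$channel_names
    m
  })
  cavity_region(cavs$centers, cavs$radius, ap)
}

# n_frames x n_lipids matrix of region states: 0 outside, 1 cavity A,
# 2 cavity B
region_states <- function(traj, topology, region, head_rows) {
  nf <- n_frames(traj)
  states <- matrix(0L, nf, length(head_rows))
  for (f in seq_len(nf)) {
    xy <- frame_coords(traj, head_rows, f)[, 1:2, drop = FALSE]
    box <- traj$box[f, ]
    for (m in 1:2) {
      ins <- in_disc(xy, region$centers[m, ], region$radius, box)
      states[f, ins] <- m
    }
  }
  states
}

#' Detect lipid entry/exit events for the cavity regions
#'
#' A lipid's inside/outside state changes only if the new state persists
#' for at least `dwell_hysteresis` (debouncing boundary flicker); the event
#' time is the first frame of the persistent new state.  Each crossing is
#' assigned to the channel whose aperture is nearest the headgroup at the
#' crossing frame, within `assignment_radius`; farther crossings are
#' `"unassigned"`.
#'
#' @param traj a `cg_trajectory`
#' @param topology a `cg_topology`
#' @param region a [cavity_region()]
#' @param dwell_hysteresis ns (default 50)
#' @param assignment_radius nm (default 1.0)
#' @return data.frame of exchange events: `lipid_id`, `species`,
#'   `direction` (entry/exit), `channel`, `time` (ns), `monomer`
#' @export
detect_exchange_events <- function(traj, topology, region,
                                   dwell_hysteresis = 50,
                                   assignment_radius = 1.0) {
  b <- topology$beads
  head_rows <- which(b$is_headgroup)
  head_rows <- head_rows[!duplicated(b$molecule_id[head_rows])]
  states <- region_states(traj, topology, region, head_rows)
  dt <- if (n_frames(traj) > 1L) diff(traj$times[1:2]) else dwell_hysteresis
  min_run <- max(1L, ceiling(dwell_hysteresis / dt))
  events <- list()
  for (li in seq_along(head_rows)) {
    s <- states[, li]
    r <- rle(s)
    # absorb flickers: runs shorter than the hysteresis merge into the
    # preceding persistent state (the final run is kept regardless, so a
    # genuine crossing near the trajectory end is not silently dropped)
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
      from <- keep_vals[k - 1L]; to <- keep_vals[k]
      f <- keep_starts[k]
      m <- if (to != 0L) to else from
      direction <- if (to != 0L) "entry" else "exit"
      # a direct A->B hop cannot occur for disjoint regions, but guard:
      if (from != 0L && to != 0L) direction <- "entry"
      ap <- region$apertures[[m]]
      d_ap <- lateral_dist(ap, traj$coords[head_rows[li], 1:2, f],
                           traj$box[f, ])
      ch <- if (min(d_ap) <= assignment_radius) {
        rownames(ap)[which.min(d_ap)]
      } else "unassigned"
      i <- head_rows[li]
      events[[length(events) + 1L]] <- data.frame(
        lipid_id = b$molecule_id[i], species = b$species[i],
        direction = direction, channel = ch, time = traj$times[f],
        monomer = c("A", "B")[m], stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L) {
    return(data.frame(lipid_id = integer(), species = character(),
                      direction = character(), channel = character(),
                      time = numeric(), monomer = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  out[order(out$time, out$lipid_id), , drop = FALSE]
}

#' Entry and exit fluxes per monomer per millisecond
#'
#' `flux = count(direction) / (n_monomers * analysis_duration)`, converted
#' to events per monomer per ms.  The arithmetic is exact up to the unit
#' conversion; rounding to integers happens only in reports.
#'
#' @param events data.frame with a `direction` column, or a named count
#'   vector `c(entry = ..., exit = ...)`
#' @param analysis_duration_us analysis duration, microseconds
#' @param n_monomers number of monomers (default 2)
#' @return named numeric vector: `entry` and `exit` flux,
#'   events per monomer per ms
#' @export
compute_flux <- function(events, analysis_duration_us, n_monomers = 2) {
  stopifnot(analysis_duration_us > 0, n_monomers >= 1)
  if (is.data.frame(events)) {
    n_entry <- sum(events$direction == "entry")
    n_exit <- sum(events$direction == "exit")
  } else {
    n_entry <- events[["entry"]]; n_exit <- events[["exit"]]
  }
  dur_ms <- analysis_duration_us / 1000
  c(entry = n_entry / (n_monomers * dur_ms),
    exit = n_exit / (n_monomers * dur_ms))
}

#' Cavity composition time series
#'
#' Per-window mean occupant count per species per cavity, plus the net
#' change: (mean total occupants over the final averaging period) minus
#' the initial total.
#'
#' @param traj a `cg_trajectory`
#' @param topology a `cg_topology`
#' @param region a [cavity_region()]
#' @param window averaging window, ns (default 1000)
#' @param final_period duration at the trajectory end used for the final
#'   composition average, ns (default: the last window)
#' @return list of class `cavity_composition`: `timeseries` (data.frame:
#'   window, t_mid, monomer, species, mean_count), `initial` (counts at the
#'   first frame), `final_mean` (per species per cavity), `net_change_per_cavity`
#' @export
cavity_composition_timeseries <- function(traj, topology, region,
                                          window = 1000,
                                          final_period = NULL) {
  span <- diff(range(traj$times))
  if (window > span) {
    stop("window (", window, " ns) longer than the trajectory (", span,
         " ns)")
  }
  if (is.null(final_period)) final_period <- window
  b <- topology$beads
  head_rows <- which(b$is_headgroup)
  head_rows <- head_rows[!duplicated(b$molecule_id[head_rows])]
  sp <- b$species[head_rows]
  states <- region_states(traj, topology, region, head_rows)
  nf <- n_frames(traj)
  win_id <- pmin(floor((traj$times - traj$times[1]) / window) + 1L,
                 ceiling(span / window))
  species_levels <- sort(unique(sp))
  rows <- list()
  for (w in unique(win_id)) {
    fr <- which(win_id == w)
    for (m in 1:2) {
      cnt <- vapply(species_levels, function(s) {
        mean(rowSums(states[fr, sp == s, drop = FALSE] == m))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        window = w, t_mid = mean(traj$times[fr]), monomer = c("A", "B")[m],
        species = species_levels, mean_count = cnt,
        stringsAsFactors = FALSE)
    }
  }
  ts <- do.call(rbind, rows)
  rownames(ts) <- NULL
  initial <- matrix(vapply(1:2, function(m) {
    vapply(species_levels, function(s) sum(states[1, sp == s] == m),
           numeric(1))
  }, numeric(length(species_levels))), nrow = length(species_levels))
  dimnames(initial) <- list(species_levels, c("A", "B"))
  final_frames <- which(traj$times > traj$times[nf] - final_period)
  final_mean <- matrix(vapply(1:2, function(m) {
    vapply(species_levels, function(s) {
      mean(rowSums(states[final_frames, sp == s, drop = FALSE] == m))
    }, numeric(1))
  }, numeric(length(species_levels))), nrow = length(species_levels))
  dimnames(final_mean) <- dimnames(initial)
  net <- mean(colSums(final_mean) - colSums(initial))
  structure(list(timeseries = ts, initial = initial,
                 final_mean = final_mean, net_change_per_cavity = net),
            class = "cavity_composition")
}

#' Net change in cavity occupancy
#'
#' Arithmetic helper: (summed final mean composition) minus (summed initial
#' composition), per cavity.
#'
#' @param initial numeric vector of initial per-species counts in one cavity
#' @param final_mean numeric vector of final per-species mean counts
#' @return net change in lipids per cavity
#' @export
cavity_net_change <- function(initial, final_mean) {
  stopifnot(length(initial) == length(final_mean))
  sum(final_mean) - sum(initial)
}

#' @export
print.cavity_composition <- function(x, ...) {
  cat("Cavity composition: net change",
      sprintf("%+.2f", x$net_change_per_cavity), "lipids per cavity\n")
  cat("  initial (per cavity):\n"); print(x$initial)
  cat("  final mean:\n"); print(round(x$final_mean, 2))
  invisible(x)
}

#' Classify the mobility of a cocrystallized lipid
#'
#' Quantitative replacement for a visual mobility assessment: the class is
#' set by the maximum sustained displacement of the lipid headgroup from
#' its initial site position — `"none"` (below the limited threshold),
#' `"limited"`, `"large"`, `"escape"` (beyond the escape threshold for a
#' sustained period), and `"exchange"` when an escaped lipid is replaced by
#' another lipid of the same species dwelling near the vacated site.
#'
#' @param traj a `cg_trajectory`
#' @param topology a `cg_topology`
#' @param lipid_molecule molecule id of the cocrystallized lipid
#' @param initial_site_position length-2 or -3 position, nm (default: the
#'   lipid's first-frame headgroup position)
#' @param thresholds list with `limited` (nm), `large` (nm), `escape` (nm)
#'   and `sustain` (ns) — defaults 0.5, 1.5, 3.0, 1000
#' @param replacement_radius nm within which a replacement lipid must dwell
#'   (default 0.8)
#' @param replacement_dwell minimum replacement dwell, ns (default 1000)
#' @return list of class `mobility_class`: `lipid_id`, `class`,
#'   `max_displacement`, `replaced_by`
#' @export
classify_cocryst_mobility <- function(traj, topology, lipid_molecule,
                                      initial_site_position = NULL,
                                      thresholds = list(limited = 0.5,
                                                        large = 1.5,
                                                        escape = 3.0,
                                                        sustain = 1000),
                                      replacement_radius = 0.8,
                                      replacement_dwell = 1000) {
  b <- topology$beads
  row <- which(b$is_headgroup & b$molecule_id == lipid_molecule)[1]
  if (is.na(row)) stop("lipid molecule ", lipid_molecule,
                       " not found in topology")
  nf <- n_frames(traj)
  if (is.null(initial_site_position)) {
    initial_site_position <- traj$coords[row, 1:2, 1]
  }
  p0 <- initial_site_position[1:2]
  disp <- vapply(seq_len(nf), function(f) {
    lateral_dist(matrix(traj$coords[row, 1:2, f], 1), p0, traj$box[f, ])
  }, numeric(1))
  dt <- if (nf > 1L) diff(traj$times[1:2]) else 1
  sustain_frames <- max(1L, ceiling(thresholds$sustain / dt))
  sustained_beyond <- function(x, thr) {
    r <- rle(x > thr)
    any(r$values & r$lengths >= sustain_frames)
  }
  escaped <- sustained_beyond(disp, thresholds$escape)
  max_disp <- max(disp)
  cls <- if (max_disp < thresholds$limited) "none"
  else if (max_disp < thresholds$large) "limited"
  else if (!escaped) "large"
  else "escape"
  replaced_by <- NA_integer_
  if (escaped) {
    esc_frame <- which(disp > thresholds$escape)[1]
    others <- which(b$is_headgroup & b$species == b$species[row] &
                      b$molecule_id != lipid_molecule)
    others <- others[!duplicated(b$molecule_id[others])]
    dwell_frames <- max(1L, ceiling(replacement_dwell / dt))
    for (o in others) {
      if (esc_frame >= nf) break
      near <- vapply(esc_frame:nf, function(f) {
        lateral_dist(matrix(traj$coords[o, 1:2, f], 1), p0,
                     traj$box[f, ]) <= replacement_radius
      }, logical(1))
      r <- rle(near)
      if (any(r$values & r$lengths >= dwell_frames)) {
        replaced_by <- b$molecule_id[o]
        cls <- "exchange"
        break
      }
    }
  }
  structure(list(lipid_id = lipid_molecule, class = cls,
                 max_displacement = max_disp, replaced_by = replaced_by),
            class = "mobility_class")
}

#' @export
print.mobility_class <- function(x, ...) {
  cat("Lipid", x$lipid_id, "mobility:", x$class,
      sprintf("(max displacement %.2f nm%s)\n", x$max_displacement,
              if (!is.na(x$replaced_by))
                paste0(", replaced by lipid ", x$replaced_by) else ""))
  invisible(x)
}
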