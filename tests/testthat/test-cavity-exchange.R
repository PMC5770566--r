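toy_region <- function() {
  cavity_region(
    centers = rbind(A = c(5, 5), B = c(15, 15)),
    radius = 1,
    apertures = list(
      A = matrix(c(5, 6, 5, 4), 2, 2, byrow = TRUE,
                 dimnames = list(c("I", "III"), NULL)),
      B = matrix(c(15, 16, 15, 14), 2, 2, byrow = TRUE,
                 dimnames = list(c("I", "III"), NULL))))
}

# trajectory of one lipid following a given lateral path
path_traj <- function(path_xy, z = 7, box = c(20, 20, 10), dt = 10) {
  frames <- lapply(seq_len(nrow(path_xy)), function(i) {
    rbind(c(path_xy[i, ], z), c(path_xy[i, ], 5.2))
  })
  make_traj(frames, box = box, dt = dt)
}

test_that("overlapping monomer regions are rejected", {
  expect_error(
    cavity_region(rbind(A = c(5, 5), B = c(6, 5)), radius = 1,
                  apertures = list(A = matrix(0, 1, 2), B = matrix(0, 1, 2))),
    "overlap")
})

test_that("a lipid that never enters the region produces no events", {
  path <- cbind(seq(10, 12, length.out = 20), rep(10, 20))
  ev <- detect_exchange_events(path_traj(path), lipid_topology(1),
                               toy_region())
  expect_equal(nrow(ev), 0L)
})

test_that("a constructed in-and-out path gives one entry and one exit through channel III", {
  # approach through the aperture at (5, 4): enter, dwell, leave
  path <- rbind(
    cbind(rep(5, 10), seq(2.0, 3.9, length.out = 10)),  # outside
    cbind(rep(5, 10), rep(4.5, 10)),                    # inside via (5,4)
    cbind(rep(5, 10), seq(3.9, 2.0, length.out = 10)))  # outside again
  ev <- detect_exchange_events(path_traj(path), lipid_topology(1),
                               toy_region(), dwell_hysteresis = 50)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$direction, c("entry", "exit"))
  expect_equal(ev$channel, c("III", "III"))
  expect_equal(ev$monomer, c("A", "A"))
  expect_equal(ev$time, c(100, 200))
})

test_that("boundary flicker shorter than the hysteresis is debounced", {
  path <- rbind(
    cbind(rep(5, 10), rep(2, 10)),
    cbind(rep(5, 2), rep(4.5, 2)),   # 20 ns blip inside
    cbind(rep(5, 10), rep(2, 10)))
  ev <- detect_exchange_events(path_traj(path), lipid_topology(1),
                               toy_region(), dwell_hysteresis = 50)
  expect_equal(nrow(ev), 0L)
})

test_that("flux arithmetic reproduces the published worked example", {
  flux <- compute_flux(c(entry = 9, exit = 7), analysis_duration_us = 87.7,
                       n_monomers = 2)
  expect_equal(unname(round(flux)), c(51, 40))
  expect_equal(unname(flux["entry"]), 9 / (2 * 0.0877), tolerance = 1e-12)
  expect_equal(unname(flux["entry"]), 51.31, tolerance = 1e-4)
  expect_equal(unname(flux["exit"]), 39.91, tolerance = 1e-4)
  expect_equal(unname(compute_flux(c(entry = 0, exit = 0), 87.7, 2)),
               c(0, 0))
})

test_that("cavity composition net change reproduces the published arithmetic", {
  expect_equal(cavity_net_change(c(PG = 3, DGDG = 2, MGDG = 2, SQDG = 2),
                                 c(PG = 3.0, DGDG = 1.5, MGDG = 3.2,
                                   SQDG = 2.5)),
               1.2, tolerance = 1e-12)
})

test_that("windowed composition means match a per-frame recount on a toy path", {
  # lipid inside cavity A for the first half, outside for the second
  path <- rbind(cbind(rep(5, 50), rep(5, 50)),
                cbind(rep(10, 50), rep(10, 50)))
  traj <- path_traj(path, dt = 10)
  comp <- cavity_composition_timeseries(traj, lipid_topology(1),
                                        toy_region(), window = 250)
  ts <- comp$timeseries
  a_mgdg <- ts[ts$monomer == "A" & ts$species == "MGDG", ]
  expect_equal(a_mgdg$mean_count[1:2], c(1, 1))
  expect_equal(a_mgdg$mean_count[3:4], c(0, 0))
  expect_equal(sum(comp$initial), 1)
  expect_equal(comp$net_change_per_cavity, -0.5)
  expect_error(cavity_composition_timeseries(traj, lipid_topology(1),
                                             toy_region(), window = 1e6),
               "window")
})

test_that("detected events match the debounced ground truth of a synthetic run", {
  run <- cavity_run()
  region <- cavity_region_of(run)
  ev <- detect_exchange_events(run$trajectory, run$topology, region,
                               dwell_hysteresis = 50)
  truth <- debounced_truth(run, hysteresis = 50)
  expect_equal(nrow(ev), nrow(truth))
  expect_equal(ev$time, truth$time)
  expect_equal(ev$direction, truth$direction)
  expect_equal(ev$monomer, truth$monomer)
  matched <- !is.na(truth$channel)
  expect_equal(ev$channel[matched], truth$channel[matched])
})

test_that("entries minus exits equals the occupancy change (conservation audit)", {
  run <- cavity_run()
  region <- cavity_region_of(run)
  gt <- run$ground_truth$crossings
  b <- run$topology$beads
  hr <- which(b$is_headgroup)
  hr <- hr[!duplicated(b$molecule_id[hr])]
  count_inside <- function(f) {
    xy <- run$trajectory$coords[hr, 1:2, f]
    box <- run$trajectory$box[f, ]
    sum(sqrt((xy[, 1] - region$centers[1, 1])^2 +
               (xy[, 2] - region$centers[1, 2])^2) <= region$radius) +
      sum(sqrt((xy[, 1] - region$centers[2, 1])^2 +
                 (xy[, 2] - region$centers[2, 2])^2) <= region$radius)
  }
  delta <- count_inside(n_frames(run$trajectory)) - count_inside(1)
  expect_equal(sum(gt$direction == "entry") - sum(gt$direction == "exit"),
               delta)
  # entry/exit alternation per lipid is exact in the truth log
  for (lip in unique(gt$lipid_id)) {
    dirs <- gt$direction[gt$lipid_id == lip][order(gt$time[gt$lipid_id == lip])]
    expect_true(all(dirs[-1] != dirs[-length(dirs)]))
  }
})

test_that("with closed channels the cavity composition never changes", {
  cav <- cavity_config(channels = list(
    I = list(angle = pi / 2, radius = 0.3, open_probability = 0),
    III = list(angle = 11 * pi / 6, radius = 0.3, open_probability = 0)))
  cfg <- synthetic_config(total_lipids = 300, n_frames = 400, dt_frame = 2,
                          cavity = cav, seed = 41)
  run <- generate_trajectory(cfg)
  expect_equal(nrow(run$ground_truth$crossings), 0L)
  region <- cavity_region_of(run)
  comp <- cavity_composition_timeseries(run$trajectory, run$topology,
                                        region, window = 200)
  expect_equal(comp$net_change_per_cavity, 0)
  expect_true(all(abs(comp$final_mean - comp$initial) < 1e-12))
})

test_that("mobility classes follow displacement and detect replacement", {
  # static lipid
  still <- path_traj(cbind(rep(5, 30), rep(5, 30)), dt = 100)
  m <- classify_cocryst_mobility(still, lipid_topology(1), 1)
  expect_equal(m$class, "none")
  expect_lt(m$max_displacement, 0.01)

  # escape with a same-species replacement moving in
  n <- 60
  lip1 <- rbind(cbind(rep(5, 10), rep(5, 10)),
                cbind(seq(5, 12, length.out = n - 10), rep(5, n - 10)))
  lip2 <- rbind(cbind(rep(9, 20), rep(5, 20)),
                cbind(rep(5.2, n - 20), rep(5, n - 20)))
  frames <- lapply(seq_len(n), function(i) {
    rbind(c(lip1[i, ], 7), c(lip1[i, ], 5.2),
          c(lip2[i, ], 7), c(lip2[i, ], 5.2))
  })
  traj <- make_traj(frames, box = c(30, 30, 10), dt = 100)
  m2 <- classify_cocryst_mobility(traj, lipid_topology(2), 1,
                                  initial_site_position = c(5, 5))
  expect_equal(m2$class, "exchange")
  expect_equal(m2$replaced_by, 2L)
  # without the replacement it is a plain escape
  frames_alone <- lapply(seq_len(n), function(i) {
    rbind(c(lip1[i, ], 7), c(lip1[i, ], 5.2),
          c(20, 20, 7), c(20, 20, 5.2))
  })
  m3 <- classify_cocryst_mobility(make_traj(frames_alone,
                                            box = c(30, 30, 10), dt = 100),
                                  lipid_topology(2), 1,
                                  initial_site_position = c(5, 5))
  expect_equal(m3$class, "escape")
  expect_error(classify_cocryst_mobility(still, lipid_topology(1), 99),
               "not found")
})

test_that("mobility class is monotone under displacement scaling", {
  rank_of <- c(none = 1, limited = 2, large = 3, escape = 4, exchange = 4)
  set.seed(27)
  for (rep in 1:20) {
    steps <- matrix(rnorm(2 * 40, sd = 0.3), ncol = 2)
    base <- apply(steps, 2, cumsum)
    cls <- vapply(c(0.5, 1, 2, 4), function(s) {
      path <- sweep(base * s, 2, c(10, 10), "+")
      classify_cocryst_mobility(path_traj(path, box = c(60, 60, 10),
                                          dt = 100),
                                lipid_topology(1), 1,
                                initial_site_position = c(10, 10))$class
    }, character(1))
    expect_true(all(diff(rank_of[cls]) >= 0))
  }
})
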