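test_that("GRO writing and reading round-trips coordinates at format precision", {
  topo <- lipid_topology(2)
  xyz <- matrix(c(1.2345, 2.3456, 3.4567,
                  4.5678, 5.6789, 6.7891,
                  0.1111, 9.9999, 5.5555,
                  2.2222, 3.3333, 4.4444), ncol = 3, byrow = TRUE)
  box <- c(10, 10, 10)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(topo, xyz, box, path)
  g <- read_gro(path)
  expect_equal(nrow(g$atoms), 4L)
  expect_equal(g$xyz, xyz, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(g$box, box)
})

test_that("a toy GRO with one flagged MGDG yields a one-headgroup topology", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("toy", "    4",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "MGDG", "GL1",
                       1L, 1.0, 1.0, 2.0),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "MGDG", "C1A",
                       2L, 1.0, 1.0, 1.5),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "MGDG", "C4A",
                       3L, 1.0, 1.0, 1.0),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 2L, "W", "W",
                       4L, 3.0, 3.0, 3.0),
               "   5.00000   5.00000   5.00000"), path)
  sys <- read_system(path)
  b <- sys$topology$beads
  expect_equal(sum(b$is_headgroup), 1L)
  expect_equal(b$name[b$is_headgroup], "GL1")
  expect_equal(b$species, c("MGDG", "MGDG", "MGDG", "SOLVENT"))
  expect_equal(n_frames(sys$trajectory), 1L)
})

test_that("bead-count mismatch between structure and trajectory names both counts", {
  topo5 <- lipid_topology(2)  # 4 beads
  traj5 <- make_traj(list(matrix(runif(15), 5, 3)))
  path <- withr::local_tempfile(fileext = ".trj")
  write_fixture_trajectory(traj5, path)
  expect_error(read_fixture_trajectory(path, n_beads = 4),
               "5 vs 4")
})

test_that("unknown residues error unless allow_unknown", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("toy", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "XXX", "A1",
                       1L, 1.0, 1.0, 1.0),
               "   5.00000   5.00000   5.00000"), path)
  expect_error(read_system(path), "XXX")
  sys <- read_system(path, allow_unknown = TRUE)
  expect_equal(sys$topology$beads$species, "SOLVENT")
})

test_that("triclinic GRO boxes are rejected", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("toy", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "MGDG", "GL1",
                       1L, 1.0, 1.0, 1.0),
               "   5.0   5.0   5.0   0.0   0.0   1.2   0.0   0.0   0.0"),
             path)
  expect_error(read_gro(path), "triclinic")
})

test_that("synthetic run round-trips through GRO and fixture trajectory", {
  cfg <- synthetic_config(total_lipids = 40, n_frames = 3, dt_frame = 1,
                          protein = NULL, seed = 1)
  run <- generate_trajectory(cfg)
  prefix <- file.path(withr::local_tempdir(), "run")
  paths <- write_synthetic_run(run, prefix)
  g <- read_gro(paths[["gro"]])
  f1 <- get_frame(run$trajectory, 1)
  expect_equal(g$xyz, f1$xyz, tolerance = 1e-3, ignore_attr = TRUE)
  tr <- read_fixture_trajectory(paths[["trj"]], n_beads(run$topology))
  expect_equal(tr$coords, run$trajectory$coords, tolerance = 1e-4)
  expect_equal(tr$times, run$trajectory$times)
})

test_that("min_image_vector handles identity, wrapping and beats the naive difference", {
  box <- c(10, 10, 10)
  expect_equal(min_image_vector(c(0, 0, 0), c(0, 0, 0), box), c(0, 0, 0))
  v <- min_image_vector(c(0.5, 0, 0), c(9.5, 0, 0), box)
  expect_equal(v, c(-1, 0, 0))
  expect_equal(sqrt(sum(v^2)), 1.0)
  expect_error(min_image_vector(c(0, 0, 0), c(1, 1, 1), c(10, 0, 10)),
               "box")
  set.seed(42)
  for (i in 1:1000) {
    a <- runif(3, -20, 20); b <- runif(3, -20, 20)
    box <- runif(3, 1, 15)
    mi <- min_image_vector(a, b, box)
    expect_lte(sqrt(sum(mi^2)), sqrt(sum((b - a)^2)) + 1e-12)
    # antisymmetry
    expect_equal(mi, -min_image_vector(b, a, box), tolerance = 1e-12)
    # components in [-edge/2, edge/2)
    expect_true(all(mi >= -box / 2 & mi < box / 2))
  }
})

test_that("leaflet assignment labels sides, matches construction, warns when unbalanced", {
  topo <- lipid_topology(2)
  xyz <- rbind(c(1, 1, 2), c(1, 1, 0.5),    # head above midplane
               c(2, 2, -2), c(2, 2, -0.5))  # head below
  fr <- list(time = 0, xyz = xyz, box = c(5, 5, 10))
  expect_warning(lab <- assign_leaflets(fr, topo), "fewer than 10")
  expect_equal(unname(lab), c("stromal", "lumenal"))

  run <- sites_run()
  fr_run <- get_frame(run$trajectory, 1)
  lab_run <- assign_leaflets(fr_run, run$topology)
  truth <- run$ground_truth$leaflet
  expect_equal(lab_run[names(truth)], truth)

  # all lipids in one leaflet: same label everywhere plus a warning
  xyz1 <- rbind(c(1, 1, 2), c(1, 1, 1.2), c(2, 2, 2.5), c(2, 2, 1.1))
  expect_warning(lab1 <- assign_leaflets(list(time = 0, xyz = xyz1,
                                              box = c(5, 5, 10)), topo),
                 "fewer than 10")
  expect_equal(length(unique(lab1)), 1L)

  # labels invariant under rigid in-plane translation
  xyz_shift <- sweep(xyz, 2, c(3.3, -1.7, 0), "+")
  expect_warning(lab2 <- assign_leaflets(list(time = 0, xyz = xyz_shift,
                                              box = c(5, 5, 10)), topo))
  expect_equal(lab2, lab)
})

test_that("rigid fit recovers constructed transforms and is idempotent", {
  set.seed(1)
  ref_xyz <- matrix(runif(60, 0, 5), 20, 3)
  ref <- list(time = 0, xyz = ref_xyz, box = c(10, 10, 10))

  # identity
  fit0 <- fit_frame(ref, ref, selection = 1:20)
  expect_equal(fit0$xyz, ref_xyz, tolerance = 1e-10)

  # 90 degrees about z plus translation
  th <- pi / 2
  R <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  moved <- list(time = 0, xyz = sweep(ref_xyz %*% R, 2, c(1, 2, 3), "+"),
                box = c(10, 10, 10))
  back <- fit_frame(moved, ref, selection = 1:20)
  expect_lt(rmsd(back$xyz, ref_xyz), 1e-6)

  # idempotence
  again <- fit_frame(back, ref, selection = 1:20)
  expect_lt(max(abs(again$xyz - back$xyz)), 1e-9)

  # RMSD after fit never exceeds RMSD before
  noisy <- list(time = 0, xyz = ref_xyz + rnorm(60, sd = 0.3),
                box = c(10, 10, 10))
  fitted <- fit_frame(noisy, ref, selection = 1:20)
  expect_lte(rmsd(fitted$xyz, ref_xyz), rmsd(noisy$xyz, ref_xyz) + 1e-12)
})

test_that("post-fit RMSD of a noisy copy matches the sigma*sqrt(3) expectation", {
  set.seed(7)
  ref_xyz <- matrix(runif(150, 0, 5), 50, 3)
  ref <- list(time = 0, xyz = ref_xyz, box = c(10, 10, 10))
  sigma <- 0.05
  rmsds <- replicate(100, {
    noisy <- list(time = 0, xyz = ref_xyz + rnorm(150, sd = sigma),
                  box = c(10, 10, 10))
    rmsd(fit_frame(noisy, ref, selection = 1:50)$xyz, ref_xyz)
  })
  expect_equal(mean(rmsds), sigma * sqrt(3), tolerance = 0.2)
})

test_that("degenerate fit selections error", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  fr <- list(time = 0, xyz = line, box = c(100, 100, 100))
  expect_error(fit_frame(fr, fr, selection = 1:10), "collinear")
  two <- list(time = 0, xyz = line[1:2, ], box = c(100, 100, 100))
  expect_error(fit_frame(two, two, selection = 1:2), "at least 3")
})

test_that("full-3D and in-plane fits agree for an in-plane rotation", {
  set.seed(3)
  ref_xyz <- matrix(runif(90, 0, 5), 30, 3)
  ref <- list(time = 0, xyz = ref_xyz, box = c(10, 10, 10))
  th <- 0.7
  R <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  moved <- list(time = 0, xyz = ref_xyz %*% R, box = c(10, 10, 10))
  full <- fit_frame(moved, ref, selection = 1:30, in_plane = FALSE)
  flat <- fit_frame(moved, ref, selection = 1:30, in_plane = TRUE)
  expect_lt(rmsd(full$xyz, ref_xyz), 1e-8)
  expect_lt(rmsd(flat$xyz, ref_xyz), 1e-8)
})

test_that("Kabsch solution matches the bio3d superposition RMSD", {
  set.seed(9)
  P <- matrix(rnorm(60), 20, 3)
  Q <- matrix(rnorm(60), 20, 3)
  ours <- kabsch_fit(P, Q)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(Q)), as.numeric(t(P)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 decimals
})
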