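test_that("phrase membership is inclusive at the cutoff and enforces the length floor", {
  # 5 residues just inside 0.8 nm, a 6th just outside
  n_prot <- 6
  topo <- protein_lipid_topology(n_prot, 1,
                                 res_names = c("ARG", "LYS", "TYR", "ASN",
                                               "GLY", "SER"))
  prot_xyz <- rbind(
    c(5.79, 5, 5), c(5, 5.78, 5), c(4.21, 5, 5), c(5, 4.22, 5),
    c(5.55, 5.55, 5), c(5.81, 5, 5))
  lipid_xyz <- rbind(c(5, 5, 5), c(5, 5, 4.5))
  xyz <- rbind(prot_xyz, lipid_xyz)
  traj <- make_traj(list(xyz), box = c(10, 10, 10), dt = 10)
  ph <- build_phrases(traj, topo, cutoff = 0.8, interval = 10, min_len = 5)
  expect_equal(nrow(ph), 1L)
  expect_equal(length(ph$residues[[1]]), 5L)
  expect_false(any(grepl("SER", ph$residues[[1]])))

  # exactly at the cutoff counts (<=)
  prot_xyz2 <- prot_xyz; prot_xyz2[6, ] <- c(5.80, 5, 5)
  traj2 <- make_traj(list(rbind(prot_xyz2, lipid_xyz)), box = c(10, 10, 10),
                     dt = 10)
  ph2 <- build_phrases(traj2, topo, cutoff = 0.8, interval = 10, min_len = 5)
  expect_equal(length(ph2$residues[[1]]), 6L)

  # lipid far from the protein: no phrases at all
  traj3 <- make_traj(list(rbind(prot_xyz, lipid_xyz + 4)),
                     box = c(20, 20, 20), dt = 10)
  expect_equal(nrow(build_phrases(traj3, topo)), 0L)

  expect_error(build_phrases(make_traj(list(xyz, xyz), dt = 10), topo,
                             interval = 5),
               "interval")
})

test_that("phrases match a brute-force all-pairs recount on a toy trajectory", {
  set.seed(6)
  n_prot <- 8; n_lip <- 4; nf <- 20
  topo <- protein_lipid_topology(n_prot, n_lip)
  frames <- replicate(nf, {
    prot <- matrix(runif(n_prot * 3, 0, 6), n_prot, 3)
    lip_xy <- matrix(runif(n_lip * 3, 0, 6), n_lip, 3)
    out <- matrix(0, n_prot + 2 * n_lip, 3)
    out[seq_len(n_prot), ] <- prot
    out[n_prot + seq(1, 2 * n_lip, 2), ] <- lip_xy
    out[n_prot + seq(2, 2 * n_lip, 2), ] <- lip_xy + 0.1
    out
  }, simplify = FALSE)
  traj <- make_traj(frames, box = c(6, 6, 6), dt = 10)
  ph <- build_phrases(traj, topo, cutoff = 1.2, interval = 10, min_len = 2)
  b <- topo$beads
  res_key <- paste(b$subunit, b$residue_id, b$residue_name, sep = "|")
  expected <- list()
  for (f in seq_len(nf)) {
    for (li in seq_len(n_lip)) {
      head_row <- n_prot + 2 * (li - 1) + 1
      res <- character()
      for (p in seq_len(n_prot)) {
        v <- min_image_vector(frames[[f]][head_row, ], frames[[f]][p, ],
                              c(6, 6, 6))
        if (sqrt(sum(v^2)) <= 1.2) res <- c(res, res_key[p])
      }
      if (length(res) >= 2) {
        expected[[length(expected) + 1L]] <-
          list(lipid = b$molecule_id[head_row], time = (f - 1) * 10,
               res = sort(res))
      }
    }
  }
  expect_equal(nrow(ph), length(expected))
  for (k in seq_len(nrow(ph))) {
    expect_equal(sort(ph$residues[[k]]), expected[[k]]$res)
    expect_equal(ph$lipid_id[k], expected[[k]]$lipid)
    expect_equal(ph$time[k], expected[[k]]$time)
  }
})

test_that("clustering reproduces the hand-computed worked example", {
  phrases <- list(c("A", "B", "C", "D", "E"),
                  c("A", "B", "C", "D", "F"),
                  c("G", "H", "I", "J", "K"))
  cl <- cluster_phrases(phrases, overlap_fraction = 0.70)
  expect_equal(length(cl), 2L)
  expect_setequal(cl[[1]]$members, c(1L, 2L))
  expect_setequal(cl[[2]]$members, 3L)
  cs <- consensus_site(cl[[1]], presence_fraction = 0.80)
  expect_setequal(cs$residue, c("A", "B", "C", "D"))

  # n identical phrases: one cluster, consensus = the phrase
  same <- replicate(7, c("X", "Y", "Z", "W", "V"), simplify = FALSE)
  cl2 <- cluster_phrases(same)
  expect_equal(length(cl2), 1L)
  expect_equal(cl2[[1]]$size, 7L)
  expect_setequal(consensus_site(cl2[[1]])$residue, same[[1]])
})

test_that("clustering agrees with the exhaustive greedy oracle on random pools", {
  set.seed(8)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    pool <- replicate(n, sample(LETTERS[1:12], sample(3:8, 1)),
                      simplify = FALSE)
    cl <- cluster_phrases(pool, overlap_fraction = 0.70)
    oracle <- oracle_gromos(pool, overlap = 0.70)
    expect_equal(length(cl), length(oracle))
    expect_setequal(lapply(cl, function(x) sort(x$members)), oracle)
  }
})

test_that("clusters partition the pool exactly", {
  run <- sites_run()
  ph <- build_phrases(run$trajectory, run$topology, interval = 40)
  cl <- cluster_phrases(ph)
  members <- sort(unlist(lapply(cl, `[[`, "members")))
  expect_equal(members, seq_len(nrow(ph)))
})

test_that("cluster count is monotone non-increasing as the overlap fraction decreases", {
  set.seed(15)
  pool <- replicate(40, sample(LETTERS[1:10], sample(4:7, 1)),
                    simplify = FALSE)
  counts <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(fr) {
    length(cluster_phrases(pool, overlap_fraction = fr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("consensus presence is inclusive at the threshold and exclusions are recorded", {
  # 10 phrases; residue Q in 8 of them (kept), R in 7 (dropped)
  phrases <- lapply(1:10, function(i) {
    r <- c("A", "B", "C", "D", "E")
    if (i <= 8) r <- c(r, "Q")
    if (i <= 7) r <- c(r, "R")
    r
  })
  cl <- cluster_phrases(phrases, overlap_fraction = 0.5)
  expect_equal(length(cl), 1L)
  cs <- consensus_site(cl[[1]], presence_fraction = 0.80)
  expect_true("Q" %in% cs$residue)
  expect_false("R" %in% cs$residue)
  cs2 <- consensus_site(cl[[1]], manual_exclusions = "Q")
  expect_true(cs2$excluded[cs2$residue == "Q"])
  expect_false(any(cs2$excluded[cs2$residue != "Q"]))
})

test_that("monomer consensus sets combine by union", {
  a <- data.frame(residue = c("Arg", "Lys", "Tyr"), presence = 1,
                  excluded = FALSE)
  b <- data.frame(residue = c("Lys", "Tyr", "Asn"), presence = 1,
                  excluded = FALSE)
  expect_setequal(combine_monomer_consensus(a, b),
                  c("Arg", "Lys", "Tyr", "Asn"))
})

test_that("composition percentages and normalization behave as specified", {
  # one residue of a type among 81 -> 1.2%; among 39 -> 2.6%
  site81 <- c(paste0("P|", 1:80, "|LEU"), "P|81|TRP")
  bg <- c(paste0("P|", 1:200, "|LEU"), paste0("P|", 201:210, "|TRP"))
  prof <- composition_profile(site81, bg)
  expect_equal(prof$percent[prof$residue_type == "TRP"], 100 / 81,
               tolerance = 1e-12)
  expect_equal(round(prof$percent[prof$residue_type == "TRP"], 1), 1.2)
  site39 <- c(paste0("P|", 1:38, "|LEU"), "P|39|TRP")
  prof39 <- composition_profile(site39, bg)
  expect_equal(round(prof39$percent[prof39$residue_type == "TRP"], 1), 2.6)
  expect_equal(sum(prof$percent), 100, tolerance = 1e-9)

  # identical composition to background -> all normalized exactly 1
  prof_eq <- composition_profile(bg, bg)
  expect_equal(prof_eq$normalized, rep(1, nrow(prof_eq)))

  # site residue type absent from background -> +Inf with warning
  expect_warning(
    prof_inf <- composition_profile(c("P|1|HIS", "P|2|LEU"),
                                    c("P|2|LEU", "P|3|LEU")),
    "HIS")
  expect_equal(prof_inf$normalized[prof_inf$residue_type == "HIS"], Inf)

  # uncertainty: six quasi-independent samples give a per-type sd
  samples <- replicate(6, sample(bg, 50), simplify = FALSE)
  prof_u <- composition_profile(site81, bg, uncertainty = samples)
  expect_true(all(is.finite(prof_u$percent_sd)))
})

test_that("detected site consensus covers at least 80% of the planted residues", {
  run <- sites_run()
  ph <- build_phrases(run$trajectory, run$topology, interval = 20)
  cl <- cluster_phrases(ph)
  b <- run$topology$beads
  gt <- run$ground_truth$sites
  consensus <- lapply(cl, consensus_site)
  for (s in which(gt$pair_id <= 3)) {
    rows <- gt$site_bead_rows[[s]]
    keys <- paste(b$subunit[rows], b$residue_id[rows], b$residue_name[rows],
                  sep = "|")
    cover <- max(vapply(consensus, function(cs) {
      length(intersect(cs$residue, keys)) / length(keys)
    }, numeric(1)))
    expect_gte(cover, 0.8)
  }
})
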