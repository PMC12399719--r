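# Trajectory RMSD series, occupancy, clustering, windowed reports.

make_static_traj <- function(n_frames = 10, seed = 1) {
  rec <- gen_receptor_with_pocket(1, 0, seed = seed)
  lig <- gen_toy_ligand("isoindoline_dione")
  gen_trajectory(trajectory_spec(n_frames = n_frames, sigma = 0,
                                 planted = list(list(resno = 314L,
                                                     occupancy = 1)),
                                 seed = seed),
                 rec$protein, lig)
}

test_that("a static trajectory has an all-zero RMSD series", {
  traj <- make_static_traj()
  rp <- rmsd_series(traj, "protein_alpha_carbons")
  rl <- rmsd_series(traj, "ligand_heavy_atoms")
  expect_lt(max(rp$rmsd), 1e-9)
  expect_lt(max(rl$rmsd), 1e-9)
  expect_equal(rp$rmsd[1L], 0)
})

test_that("rigid per-frame transforms are removed by the alpha-carbon fit", {
  traj <- make_static_traj()
  set.seed(6)
  traj$frames <- lapply(traj$frames, function(f) {
    rot <- random_rotation_matrix()
    f %*% t(rot) + matrix(runif(3, -5, 5), nrow(f), 3, byrow = TRUE)
  })
  expect_lt(max(rmsd_series(traj, "protein_alpha_carbons")$rmsd), 1e-6)
  expect_lt(max(rmsd_series(traj, "ligand_heavy_atoms")$rmsd), 1e-6)
})

test_that("a ligand drifting 1 A per frame with the protein fixed reads 0,1,2,...", {
  traj <- make_static_traj(n_frames = 5)
  np <- nrow(traj$protein$atoms)
  nl <- n_atoms(traj$ligand)
  for (k in seq_along(traj$frames))
    traj$frames[[k]][np + seq_len(nl), 1] <-
      traj$frames[[k]][np + seq_len(nl), 1] + (k - 1)
  rl <- rmsd_series(traj, "ligand_heavy_atoms")
  expect_equal(rl$rmsd, 0:4, tolerance = 1e-9)
  expect_lt(max(rmsd_series(traj, "protein_alpha_carbons")$rmsd), 1e-9)
})

test_that("rmsd_series rejects trajectories without alpha-carbons", {
  traj <- make_static_traj(n_frames = 3)
  traj$protein$atoms$name[traj$protein$atoms$name == "CA"] <- "CX"
  expect_error(rmsd_series(traj), "alpha-carbon")
})

test_that("occupancy is exact for deterministic planting", {
  rec <- gen_receptor_with_pocket(1, 0, seed = 2)
  lig <- gen_toy_ligand("isoindoline_dione")
  # planted every frame -> 1.0
  t1 <- gen_trajectory(trajectory_spec(50, list(list(resno = 314L,
                                                     occupancy = 1)),
                                       sigma = 0.02, seed = 3),
                       rec$protein, lig)
  o1 <- occupancy(t1, residue_scope = list("A:314"))
  expect_equal(o1$fraction[o1$key == "hbond:A:314"], 1.0)
  # planted on exactly 40% of 500 frames -> 0.40 exactly
  t2 <- gen_trajectory(trajectory_spec(500, list(list(resno = 314L,
                                                      occupancy = 0.4)),
                                       sigma = 0.02, seed = 4),
                       rec$protein, lig)
  o2 <- occupancy(t2, residue_scope = list("A:314"))
  expect_equal(o2$fraction[o2$key == "hbond:A:314"], 0.40)
  expect_equal(attr(o2, "n_frames"), 500L)
})

test_that("stochastic planting recovers the rate within three standard errors", {
  rec <- gen_receptor_with_pocket(1, 0, seed = 12)
  lig <- gen_toy_ligand("isoindoline_dione")
  tr <- gen_trajectory(trajectory_spec(
    500, list(list(resno = 314L, occupancy = 0.4, stochastic = TRUE)),
    sigma = 0.02, seed = 13), rec$protein, lig)
  o <- occupancy(tr, residue_scope = list("A:314"))
  got <- o$fraction[o$key == "hbond:A:314"]
  expect_lt(abs(got - 0.4), 3 * sqrt(0.4 * 0.6 / 500))
  # and it matches the planted mask exactly
  expect_equal(got, mean(attr(tr, "truth")$masks[[1L]]))
})

test_that("occupancy keys with zero frames are omitted", {
  tr <- make_static_traj(n_frames = 5, seed = 31)
  o <- occupancy(tr)
  expect_false(any(o$fraction == 0))
})

test_that("a planted 80/20 two-state trajectory yields a majority-state representative", {
  rec <- gen_receptor_with_pocket(1, 0, seed = 22)
  lig <- gen_toy_ligand("isoindoline_dione")
  tr <- gen_trajectory(trajectory_spec(
    100, sigma = 0.02, seed = 23,
    two_state = list(major_fraction = 0.8, offset = c(6, 0, 0))),
    rec$protein, lig)
  ct <- cluster_trajectory(tr, stride = 2, max_clusters = 5, cutoff = 1.0)
  truth <- attr(tr, "truth")$two_state
  expect_true(truth[ct$representative_frame])
  # the two states are found with the right populations
  major <- ct$assignments[truth[ct$frame_indices]]
  expect_equal(length(unique(major)), 1L)
  expect_equal(sort(as.integer(ct$sizes), decreasing = TRUE)[1:2],
               c(sum(truth[ct$frame_indices]),
                 sum(!truth[ct$frame_indices])))
})

test_that("a static trajectory forms one cluster with the first frame as representative", {
  tr <- make_static_traj(n_frames = 8)
  ct <- cluster_trajectory(tr, stride = 1, max_clusters = 5, cutoff = 0.5)
  expect_equal(length(ct$sizes), 1L)
  expect_equal(ct$representative_frame, 1L)
})

test_that("an over-large stride is rejected, as is a missing cutoff", {
  tr <- make_static_traj(n_frames = 5)
  expect_error(cluster_trajectory(tr, stride = 10, max_clusters = 5,
                                  cutoff = 1), "fewer than 2")
  expect_error(cluster_trajectory(tr, stride = 1, max_clusters = 5),
               "cutoff")
})

test_that("excess clusters are pooled as unclustered and the representative stays real", {
  rec <- gen_receptor_with_pocket(1, 0, seed = 61)
  lig <- gen_toy_ligand("isoindoline_dione")
  tr <- make_static_traj(n_frames = 12, seed = 61)
  # scatter frames 9..12 far apart so each is its own cluster
  np <- nrow(tr$protein$atoms); nl <- n_atoms(tr$ligand)
  for (k in 9:12)
    tr$frames[[k]][np + seq_len(nl), ] <-
      tr$frames[[k]][np + seq_len(nl), ] + 10 * k
  ct <- cluster_trajectory(tr, stride = 1, max_clusters = 2, cutoff = 1.0)
  expect_lte(length(ct$sizes), 2L)
  expect_true(any(ct$assignments == 0L))
  expect_true(ct$representative_frame %in%
                ct$frame_indices[ct$assignments == 1L])
})

test_that("windowed reports recompute metrics independently and exactly", {
  rec <- gen_receptor_with_pocket(1, 0, seed = 71)
  lig <- gen_toy_ligand("isoindoline_dione")
  # 0.8 occupancy in the first half, absent in the second
  mask <- c(consdock:::spread_mask(50, 0.8), rep(FALSE, 50))
  tr <- gen_trajectory(trajectory_spec(100, list(list(resno = 314L,
                                                      mask = mask)),
                                       sigma = 0.02, seed = 72),
                       rec$protein, lig)
  sr <- split_report(tr, list(c(1, 50), c(51, 100)),
                     residue_scope = list("A:314"))
  first <- sr[["frames 1-50"]]
  second <- sr[["frames 51-100"]]
  expect_equal(first$fraction[first$key == "hbond:A:314"], 0.8)
  expect_false("hbond:A:314" %in% second$key)
  # single full-range window equals the unwindowed report
  full <- split_report(tr, list(c(1, 100)), residue_scope = list("A:314"))
  whole <- occupancy(tr, residue_scope = list("A:314"))
  expect_equal(full[[1L]]$fraction, whole$fraction)
  # union occupancy is the weighted mean of window occupancies
  f1 <- first$fraction[first$key == "hbond:A:314"]
  f2 <- 0
  expect_equal(whole$fraction[whole$key == "hbond:A:314"],
               (50 * f1 + 50 * f2) / 100)
  expect_error(split_report(tr, list(c(90, 120))), "outside")
  expect_error(split_report(tr, list(c(30, 10))), "empty")
})
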