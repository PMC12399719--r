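# Geometric interaction detectors and the hierarchical stage driver.

# minimal one-residue "serine-like" protein with a tunable O-H donor
ser_protein <- function(o = c(0, 0, 0), h = c(0.97, 0, 0)) {
  protein_structure(data.frame(
    chain = "A", resno = 100L, resid = "SER",
    name = c("CA", "OG", "HG"), element = c("C", "O", "H"),
    x = c(-1.5, o[1], h[1]), y = c(0, o[2], h[2]), z = c(0, o[3], h[3])))
}

# aldehyde-like carbonyl-oxygen acceptor ligand with the O at position p
acceptor_ligand <- function(p) {
  molecular_graph("acc", data.frame(
    element = c("C", "O", "H"), x = c(p[1] + 1.23, p[1], p[1] + 1.9),
    y = c(p[2], p[2], p[2] + 0.9), z = p[3]),
    data.frame(i = c(1, 1), j = c(2, 3), order = c("2", "1")))
}

test_that("H-bond detection honours the distance cap and angle floor", {
  crit <- hbond_criteria()
  # O-H pointing straight at the acceptor: d = 2.8, angle 180 - some
  prot <- ser_protein()
  near <- detect_hbonds(acceptor_ligand(c(2.8, 0, 0)), prot, crit)
  expect_equal(nrow(near), 1L)
  expect_equal(near$distance, 2.8)
  expect_gt(near$angle, 120)
  expect_identical(near$geometry, "protein_donor")
  # stretched past the cap
  expect_equal(nrow(detect_hbonds(acceptor_ligand(c(3.6, 0, 0)), prot, crit)),
               0L)
  # boundary inclusive on distance
  expect_equal(nrow(detect_hbonds(acceptor_ligand(c(3.5, 0, 0)), prot, crit)),
               1L)
  # good distance, bad angle: acceptor perpendicular at the hydrogen side
  bad_angle <- acceptor_ligand(c(0.97, 2.62, 0))  # d(O...O) 2.8, angle ~70
  expect_equal(nrow(detect_hbonds(bad_angle, prot, crit)), 0L)
})

test_that("ligand donors are found and H-less donors are skipped, with one warning for H-free structures", {
  # ligand O-H donating to the protein OG acceptor
  lig <- molecular_graph("don", data.frame(
    element = c("O", "H"), x = c(2.8, 1.83), y = 0, z = 0),
    data.frame(i = 1, j = 2, order = "1"))
  prot <- ser_protein()
  recs <- detect_hbonds(lig, prot)
  expect_true(any(recs$geometry == "ligand_donor"))
  # same ligand stripped of hydrogens: no donation, one logged message
  bare <- molecular_graph("bare", data.frame(element = "O", x = 2.8, y = 0,
                                             z = 0))
  expect_message(r2 <- detect_hbonds(bare, prot), "no explicit hydrogens")
  expect_true(all(r2$geometry != "ligand_donor"))
})

test_that("detected records match an exhaustive double-loop oracle on random geometry", {
  set.seed(202)
  crit <- hbond_criteria()
  for (rep in 1:5) {
    # 10 protein O-H donors/acceptors + ligand with 5 acceptors and 5 O-H
    n <- 10L
    og <- matrix(runif(3 * n, 0, 8), ncol = 3)
    hg <- og + t(vapply(seq_len(n), function(i) {
      v <- rnorm(3); 0.97 * v / sqrt(sum(v^2))
    }, numeric(3)))
    prot <- protein_structure(data.frame(
      chain = "A", resno = rep(seq_len(n), each = 2L), resid = "SER",
      name = rep(c("OG", "HG"), n), element = rep(c("O", "H"), n),
      x = as.vector(rbind(og[, 1], hg[, 1])),
      y = as.vector(rbind(og[, 2], hg[, 2])),
      z = as.vector(rbind(og[, 3], hg[, 3]))))
    la <- matrix(runif(3 * 10, 0, 8), ncol = 3)
    lh <- la[6:10, ] + t(vapply(1:5, function(i) {
      v <- rnorm(3); 0.97 * v / sqrt(sum(v^2))
    }, numeric(3)))
    lig <- molecular_graph("rand", data.frame(
      element = c(rep("O", 10), rep("H", 5)),
      x = c(la[, 1], lh[, 1]), y = c(la[, 2], lh[, 2]),
      z = c(la[, 3], lh[, 3])),
      data.frame(i = 6:10, j = 11:15, order = "1"))
    got <- detect_hbonds(lig, prot, crit)
    gotkey <- sort(paste(got$geometry, got$resno, got$lig_atoms))
    # oracle: plain double loops over every donor/acceptor pair
    ang <- function(a, b, c) {
      u <- a - b; v <- c - b
      acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    }
    want <- character()
    for (r in seq_len(n)) {            # protein donor -> ligand acceptor
      for (j in 1:10) {
        dd <- sqrt(sum((og[r, ] - la[j, ])^2))
        if (dd <= 3.5 && ang(og[r, ], hg[r, ], la[j, ]) > 120)
          want <- c(want, paste("protein_donor", r, j))
      }
    }
    for (j in 1:5) {                   # ligand donor -> protein acceptor
      for (r in seq_len(n)) {
        dd <- sqrt(sum((la[5 + j, ] - og[r, ])^2))
        if (dd <= 3.5 && ang(la[5 + j, ], lh[j, ], og[r, ]) > 120)
          want <- c(want, paste("ligand_donor", r,
                                paste0(5 + j, ",", 10 + j)))
      }
    }
    expect_identical(gotkey, sort(want), label = sprintf("rep %d", rep))
  }
})

test_that("residue filters restrict the protein side", {
  rec <- gen_receptor_with_pocket(4, 0, seed = 3)
  p1 <- rec$poses[[1L]]
  all_res <- detect_hbonds(p1, rec$protein)
  only313 <- detect_hbonds(p1, rec$protein, residue_filter = list("A:313"))
  expect_true(all(only313$resno == 313L))
  expect_lte(nrow(only313), nrow(all_res))
})

ring_at <- function(center, normal = c(0, 0, 1), resid = "PHE",
                    chain = "A", resno = 10L) {
  # protein phenyl ring: six carbons on a 1.39-A circle in the plane
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  ang <- (0:5) * pi / 3
  xyz <- t(vapply(ang, function(a)
    center + 1.39 * (cos(a) * u + sin(a) * v), numeric(3)))
  data.frame(chain = chain, resno = resno, resid = resid,
             name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
             element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

test_that("pi-stacking classifies face-to-face and edge-to-face and obeys the distance cap", {
  lig <- benzene_graph()
  face <- protein_structure(ring_at(c(0, 0, 3.8)))
  r1 <- detect_pi_stack(lig, face)
  expect_equal(nrow(r1), 1L)
  expect_identical(r1$geometry, "face")
  edge <- protein_structure(ring_at(c(0, 0, 4.9), normal = c(1, 0, 0)))
  r2 <- detect_pi_stack(lig, edge)
  expect_equal(nrow(r2), 1L)
  expect_identical(r2$geometry, "edge")
  far <- protein_structure(ring_at(c(0, 0, 7.0)))
  expect_equal(nrow(detect_pi_stack(lig, far)), 0L)
})

test_that("hydrophobic contacts aggregate per apolar residue within the cap", {
  lig <- benzene_graph()
  side <- data.frame(chain = "A", resno = 50L, resid = "LEU",
                     name = c("CB", "CG", "CD1", "CD2"), element = "C",
                     x = c(3.0, 4.0, 5.0, 4.5), y = 0, z = c(2, 2, 2, 3))
  backbone <- data.frame(chain = "A", resno = 50L, resid = "LEU",
                         name = c("N", "CA", "C", "O"),
                         element = c("N", "C", "C", "O"),
                         x = c(2, 2.5, 3, 3), y = -2, z = 0)
  prot <- protein_structure(rbind(side, backbone))
  recs <- detect_hydrophobic(lig, prot)
  expect_equal(nrow(recs), 1L)           # one record per residue
  expect_identical(recs$resid, "LEU")
  # oracle: min over all ligand-C x side-chain-C distances
  lc <- graph_coords(lig)[1:6, ]
  d <- as.matrix(dist(rbind(lc, as.matrix(side[, c("x", "y", "z")]))))
  want <- min(d[1:6, 7:10])
  expect_equal(recs$distance, want, tolerance = 1e-12)
  far <- prot
  far$atoms$z <- far$atoms$z + 10
  expect_equal(nrow(detect_hydrophobic(lig, far)), 0L)
})

test_that("halogen bonds need both the distance and the C-X...A angle", {
  # C-Cl pointing along +x, acceptor on the axis (angle 180)
  lig <- molecular_graph("arcl", data.frame(
    element = c("C", "Cl"), x = c(0, 1.8), y = 0, z = 0),
    data.frame(i = 1, j = 2, order = "1"))
  ok <- protein_structure(data.frame(chain = "A", resno = 139L,
                                     resid = "ARG", name = "NH1",
                                     element = "N", x = 5.0, y = 0, z = 0))
  r <- detect_halogen(lig, ok)
  expect_equal(nrow(r), 1L)
  expect_equal(r$angle, 180)
  # same distance but bent to ~100 degrees
  bent <- protein_structure(data.frame(chain = "A", resno = 139L,
                                       resid = "ARG", name = "NH1",
                                       element = "N", x = 1.24, y = 3.15,
                                       z = 0))
  expect_equal(nrow(detect_halogen(lig, bent)), 0L)
  # beyond the cap
  farp <- protein_structure(data.frame(chain = "A", resno = 139L,
                                       resid = "ARG", name = "NH1",
                                       element = "N", x = 5.5, y = 0, z = 0))
  expect_equal(nrow(detect_halogen(lig, farp)), 0L)
})

test_that("all detectors are invariant under a common rigid transform", {
  set.seed(55)
  rec <- gen_receptor_with_pocket(2, 0, seed = 21)
  p <- rec$poses[[1L]]
  rot <- random_rotation_matrix()
  moved <- transform_complex(rec$protein, p, rot, c(11, -4, 7))
  before <- detect_hbonds(p, rec$protein)
  after <- detect_hbonds(moved$pose, moved$protein)
  expect_identical(before[, c("kind", "lig_atoms", "resno", "prot_atom")],
                   after[, c("kind", "lig_atoms", "resno", "prot_atom")])
  expect_lt(max(abs(before$distance - after$distance)), 1e-6)
  expect_lt(max(abs(before$angle - after$angle)), 1e-6)
})

test_that("every emitted record's stored geometry satisfies its admitting criteria", {
  rec <- gen_receptor_with_pocket(6, 0, seed = 17)
  for (p in rec$poses) {
    r <- detect_hbonds(p, rec$protein)
    if (nrow(r)) {
      expect_true(all(r$distance <= 3.5))
      expect_true(all(r$angle > 120))
    }
  }
})

test_that("hierarchical filtering reports residual percentages against the first stage", {
  rec <- gen_receptor_with_pocket(7, 13, seed = 41)
  res <- hierarchical_filter(list(glide = rec$poses), rec$protein)
  expect_equal(res$reports$n_out, 7L)
  expect_setequal(res$survivors$glide, names(rec$poses)[rec$labels])
  expect_equal(res$reports$residual_pct, residual_percentage(7, 20))
  # a second stage restricted to survivors keeps them (same poses)
  stage2 <- rec$poses[res$survivors$glide]
  res2 <- hierarchical_filter(list(glide = rec$poses, gold = stage2),
                              rec$protein)
  expect_equal(res2$reports$n_out, c(7L, 7L))
  expect_equal(res2$reports$residual_pct[2L], residual_percentage(7, 20))
  # survivor sets are monotone non-increasing
  expect_true(all(diff(res2$reports$n_out) <= 0))
})

test_that("a stage with an unseen compound violates pipeline ordering", {
  rec <- gen_receptor_with_pocket(2, 2, seed = 43)
  bad <- list(glide = rec$poses[1:2], gold = rec$poses[3:4])
  expect_error(hierarchical_filter(bad, rec$protein), "without surviving")
})

test_that("a stage where no pose qualifies reports zero survivors", {
  rec <- gen_receptor_with_pocket(0, 8, seed = 45)
  res <- hierarchical_filter(list(glide = rec$poses), rec$protein)
  expect_equal(res$reports$n_out, 0L)
  expect_equal(res$reports$residual_pct, 0)
})
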