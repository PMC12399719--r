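# Synthetic-data generators.
#
# These produce inputs with the statistical structure each pipeline stage
# assumes -- multi-program pose ensembles with a planted dominant cluster,
# receptors with a planted thiol pocket at residues 313/314, and
# trajectories with planted per-interaction occupancies -- so the full
# pipeline is testable with no downloads and no docking/MD engines.  Every
# generator takes an explicit seed and uses one seeded stream per call.
#
# Planted hydrogen-bond geometry uses d(D...A) = 2.8 A with a D-H...A angle
# of 160 deg (comfortably inside the 3.5 A / 120 deg criteria); violations
# place the ligand far from every polar protein atom, so recovery does not
# sit on a threshold.

DOCKING_PROGRAMS <- c("Glide SP", "Glide XP", "Gold ASP", "Gold ChemScore",
                      "Gold GoldScore", "Gold PLP", "PLANTS", "AutoDock",
                      "AutoDock Vina", "DOCK", "Glamdock", "rDock")

unit3 <- function(v) v / sqrt(sum(v^2))

rotation_about <- function(axis, theta) {
  a <- unit3(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_rotation <- function(theta_max) {
  rotation_about(stats::rnorm(3), stats::runif(1, 0, theta_max))
}

# ---- toy ligands ----------------------------------------------------------

hexagon <- function(r = 1.395, phase = 0) {
  ang <- phase + (0:5) * pi / 3
  cbind(r * cos(ang), r * sin(ang), 0)
}

#' Deterministic toy ligands with 3-D coordinates and explicit hydrogens
#'
#' Small, chemically sensible planar/zig-zag geometries carrying the motifs
#' the screening pipeline keys on: a carboxylic acid, the
#' isoindoline-1,3-dione (phthalimide) scaffold, an N-butylated
#' phthalimide-benzoic acid hybrid, and a retinoid-like polyene acid.
#'
#' @param name one of `"benzoic_acid"`, `"isoindoline_dione"`,
#'   `"n_butyl_isoindoline_benzoate"`, `"retinoid_like"`.
#' @return a `molecular_graph` with coordinates on every atom.
#' @export
gen_toy_ligand <- function(name = c("benzoic_acid", "isoindoline_dione",
                                    "n_butyl_isoindoline_benzoate",
                                    "retinoid_like")) {
  name <- match.arg(name)
  switch(name,
         benzoic_acid = toy_benzoic_acid(),
         isoindoline_dione = toy_phthalimide(),
         n_butyl_isoindoline_benzoate = toy_butyl_phthalimide_acid(),
         retinoid_like = toy_retinoid())
}

toy_atoms <- function() {
  data.frame(element = character(), x = numeric(), y = numeric(),
             z = numeric(), name = character(), stringsAsFactors = FALSE)
}

add_atom <- function(at, element, xyz, name = NULL) {
  rbind(at, data.frame(element = element, x = xyz[1], y = xyz[2], z = xyz[3],
                       name = name %||% paste0(element, nrow(at) + 1L),
                       stringsAsFactors = FALSE))
}

# carboxylic acid on `anchor`, extending along `dir` (unit, in plane)
add_cooh <- function(at, bonds, anchor_idx, anchor_xyz, dir) {
  perp <- unit3(c(-dir[2], dir[1], 0))
  c7 <- anchor_xyz + 1.48 * dir
  od <- c7 + 1.23 * unit3(dir + 1.2 * perp)
  oh <- c7 + 1.36 * unit3(dir - 1.2 * perp)
  h <- oh + 0.97 * unit3(dir + 0.3 * perp)
  at <- add_atom(at, "C", c7); ic <- nrow(at)
  at <- add_atom(at, "O", od); iod <- nrow(at)
  at <- add_atom(at, "O", oh); ioh <- nrow(at)
  at <- add_atom(at, "H", h); ih <- nrow(at)
  bonds <- rbind(bonds,
                 data.frame(i = c(anchor_idx, ic, ic, ioh),
                            j = c(ic, iod, ioh, ih),
                            order = c("1", "2", "1", "1")))
  list(at = at, bonds = bonds)
}

toy_benzoic_acid <- function() {
  ring <- hexagon()
  at <- toy_atoms()
  for (k in 1:6) at <- add_atom(at, "C", ring[k, ])
  bonds <- data.frame(i = 1:6, j = c(2:6, 1L), order = "ar",
                      stringsAsFactors = FALSE)
  res <- add_cooh(at, bonds, 1L, ring[1L, ], c(1, 0, 0))
  at <- res$at; bonds <- res$bonds
  for (k in 2:6) {
    at <- add_atom(at, "H", ring[k, ] * (1.395 + 1.09) / 1.395)
    bonds <- rbind(bonds, data.frame(i = k, j = nrow(at), order = "1"))
  }
  molecular_graph("benzoic_acid", at, bonds)
}

# phthalimide core; returns graph pieces so derivatives can extend it
phthalimide_core <- function() {
  ring <- hexagon(phase = pi / 6)  # fusion carbons at +-30 deg
  at <- toy_atoms()
  for (k in 1:6) at <- add_atom(at, "C", ring[k, ])  # 1 = 30deg, 6 = 330deg
  bonds <- data.frame(i = 1:6, j = c(2:6, 1L), order = "ar",
                      stringsAsFactors = FALSE)
  c7a <- ring[1L, ]; c3a <- ring[6L, ]
  cc1 <- c(2.59, 1.14, 0); cc2 <- c(2.59, -1.14, 0); nn <- c(3.42, 0, 0)
  at <- add_atom(at, "C", cc1); i_cc1 <- nrow(at)
  at <- add_atom(at, "C", cc2); i_cc2 <- nrow(at)
  at <- add_atom(at, "N", nn); i_n <- nrow(at)
  o1 <- cc1 + 1.21 * unit3(cc1 - (c7a + nn) / 2)
  o2 <- cc2 + 1.21 * unit3(cc2 - (c3a + nn) / 2)
  at <- add_atom(at, "O", o1); i_o1 <- nrow(at)
  at <- add_atom(at, "O", o2); i_o2 <- nrow(at)
  bonds <- rbind(bonds, data.frame(
    i = c(1L, i_cc1, i_n, i_cc2, i_cc1, i_cc2),
    j = c(i_cc1, i_n, i_cc2, 6L, i_o1, i_o2),
    order = c("1", "1", "1", "1", "2", "2")))
  # aromatic H on the four non-fusion ring carbons (positions 2..5)
  for (k in 2:5) {
    at <- add_atom(at, "H", ring[k, ] * (1.395 + 1.09) / 1.395)
    bonds <- rbind(bonds, data.frame(i = k, j = nrow(at), order = "1"))
  }
  list(at = at, bonds = bonds, i_n = i_n, nn = nn, ring = ring)
}

toy_phthalimide <- function() {
  core <- phthalimide_core()
  at <- add_atom(core$at, "H", core$nn + c(1.01, 0, 0))
  bonds <- rbind(core$bonds,
                 data.frame(i = core$i_n, j = nrow(at), order = "1"))
  molecular_graph("isoindoline_dione", at, bonds)
}

# n-butyl chain from `start_xyz` along +x, zig-zag in z, with hydrogens
add_butyl <- function(at, bonds, anchor_idx, start_xyz) {
  prev <- anchor_idx
  pos <- start_xyz
  for (k in 1:4) {
    pos <- pos + c(1.29, 0, if (k %% 2L) 0.74 else -0.74)
    at <- add_atom(at, "C", pos); ic <- nrow(at)
    bonds <- rbind(bonds, data.frame(i = prev, j = ic, order = "1"))
    nh <- if (k == 4L) 3L else 2L
    hoff <- list(c(0, 0.9, 0.45), c(0, -0.9, 0.45), c(1.0, 0, -0.45))
    for (m in seq_len(nh)) {
      at <- add_atom(at, "H", pos + hoff[[m]])
      bonds <- rbind(bonds, data.frame(i = ic, j = nrow(at), order = "1"))
    }
    prev <- ic
  }
  list(at = at, bonds = bonds)
}

toy_butyl_phthalimide_acid <- function() {
  core <- phthalimide_core()
  res <- add_butyl(core$at, core$bonds, core$i_n, core$nn)
  # carboxylic acid on ring position 3 (150 deg), pointing outward
  dir <- unit3(c(core$ring[3L, 1L], core$ring[3L, 2L], 0))
  res <- add_cooh(res$at, res$bonds, 3L, core$ring[3L, ], dir)
  # drop the aromatic H that add_cooh's anchor carbon carried
  g <- molecular_graph("n_butyl_isoindoline_benzoate", res$at, res$bonds)
  drop_h_on(g, 3L)
}

# remove one hydrogen bonded to atom i (used when substituting a ring H)
drop_h_on <- function(g, i) {
  hs <- attached_hydrogens(g, i)
  if (!length(hs)) return(g)
  drop <- hs[1L]
  keep <- setdiff(seq_len(n_atoms(g)), drop)
  remap <- match(seq_len(n_atoms(g)), keep)
  b <- g$bonds[g$bonds$i != drop & g$bonds$j != drop, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  molecular_graph(g$id, g$atoms[keep, , drop = FALSE], b, g$properties)
}

toy_retinoid <- function() {
  # conjugated zig-zag C10 chain, two methyl branches, terminal COOH
  at <- toy_atoms()
  bonds <- data.frame(i = integer(), j = integer(), order = character(),
                      stringsAsFactors = FALSE)
  pos <- c(0, 0, 0)
  idx <- integer(10)
  for (k in 1:10) {
    at <- add_atom(at, "C", pos); idx[k] <- nrow(at)
    if (k > 1L)
      bonds <- rbind(bonds, data.frame(i = idx[k - 1L], j = idx[k],
                                       order = if (k %% 2L) "1" else "2"))
    pos <- pos + c(1.25, if (k %% 2L) 0.65 else -0.65, 0)
  }
  for (k in c(3L, 7L)) {  # methyl branches
    base <- as.numeric(at[idx[k], c("x", "y", "z")])
    at <- add_atom(at, "C", base + c(0, 1.2, 0.8)); im <- nrow(at)
    bonds <- rbind(bonds, data.frame(i = idx[k], j = im, order = "1"))
    for (m in 1:3) {
      at <- add_atom(at, "H", base + c(0, 1.2, 0.8) +
                       c(0.5 * cos(2 * pi * m / 3), 0.6,
                         0.5 * sin(2 * pi * m / 3)))
      bonds <- rbind(bonds, data.frame(i = im, j = nrow(at), order = "1"))
    }
  }
  # vinylic H on chain carbons 2,4,5,6,8,9 and terminal CH3-like H on C1
  for (k in c(2L, 4L, 5L, 6L, 8L, 9L)) {
    base <- as.numeric(at[idx[k], c("x", "y", "z")])
    at <- add_atom(at, "H", base + c(0, if (k %% 2L) -1.0 else 1.0, 0.3))
    bonds <- rbind(bonds, data.frame(i = idx[k], j = nrow(at), order = "1"))
  }
  for (m in 1:3) {
    at <- add_atom(at, "H", c(-0.6 * cos(2 * pi * m / 3), -0.6,
                              0.6 * sin(2 * pi * m / 3)))
    bonds <- rbind(bonds, data.frame(i = idx[1L], j = nrow(at), order = "1"))
  }
  res <- add_cooh(at, bonds, idx[10L],
                  as.numeric(at[idx[10L], c("x", "y", "z")]), c(1, 0, 0))
  molecular_graph("retinoid_like", res$at, res$bonds)
}

# ---- pose ensembles -------------------------------------------------------

#' Specification of a synthetic multi-program pose ensemble
#'
#' @param n_programs number of docking programs (max 12, realistic labels).
#' @param n_consensus poses planted inside one tight cluster.
#' @param cluster_radius maximum pairwise heavy-atom displacement within the
#'   planted cluster, in Angstrom (must be below the clustering cutoff that
#'   will be used).
#' @param outlier_offset minimum displacement of each outlier pose from the
#'   cluster and from every other outlier, in Angstrom.
#' @param seed integer seed (required).
#' @export
ensemble_spec <- function(n_programs = 12, n_consensus = 9,
                          cluster_radius = 1.0, outlier_offset = 8.0, seed) {
  stopifnot(n_consensus >= 1, n_consensus <= n_programs,
            n_programs <= length(DOCKING_PROGRAMS),
            cluster_radius < outlier_offset, !missing(seed))
  structure(list(n_programs = n_programs, n_consensus = n_consensus,
                 cluster_radius = cluster_radius,
                 outlier_offset = outlier_offset, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a pose ensemble with a planted consensus cluster
#'
#' `n_consensus` poses are the base pose under random rigid jitter with
#' maximum heavy-atom displacement at most `cluster_radius / 2` (so every
#' within-cluster pairwise RMSD is at most `cluster_radius`); the remaining
#' poses are displaced by translations whose magnitudes differ by at least
#' `outlier_offset`, so outliers are mutually remote and remote from the
#' cluster by construction.  The planted consensus level is attached as
#' attribute `truth`.
#'
#' @param spec an [ensemble_spec()].
#' @param base_pose a `pose` (or `molecular_graph`) giving the base
#'   conformation.
#' @return a `pose_ensemble` with attribute `truth` (list: `level`,
#'   `consensus_programs`).
#' @export
gen_pose_ensemble <- function(spec, base_pose) {
  stopifnot(inherits(spec, "ensemble_spec"))
  g <- if (inherits(base_pose, "pose")) base_pose$ligand else base_pose
  set.seed(spec$seed)
  progs <- DOCKING_PROGRAMS[seq_len(spec$n_programs)]
  members <- sort(sample(spec$n_programs, spec$n_consensus))
  xyz <- graph_coords(g)
  hv <- heavy_atoms(g)
  ctr <- colMeans(xyz[hv, , drop = FALSE])
  rmax <- max(sqrt(rowSums(sweep(xyz[hv, , drop = FALSE], 2L, ctr)^2)))
  theta_max <- (spec$cluster_radius / 4) / max(rmax, 1e-6)
  poses <- vector("list", spec$n_programs)
  k_out <- 0L
  for (p in seq_len(spec$n_programs)) {
    if (p %in% members) {
      rot <- random_rotation(theta_max)
      shift <- stats::runif(1, 0, spec$cluster_radius / 4) *
        unit3(stats::rnorm(3))
      new <- sweep(sweep(xyz, 2L, ctr) %*% t(rot), 2L, -(ctr + shift))
    } else {
      k_out <- k_out + 1L
      shift <- (spec$outlier_offset * (k_out + 1L)) * unit3(stats::rnorm(3))
      # outlier translation magnitudes differ by >= outlier_offset, so any
      # two outliers stay >= outlier_offset - 2 A apart provided the rigid
      # jitter displaces atoms by at most ~1 A -- cap the angle accordingly
      rot <- random_rotation(min(pi / 8, 1 / max(rmax, 1e-6)))
      new <- sweep(sweep(xyz, 2L, ctr) %*% t(rot), 2L, -(ctr + shift))
    }
    poses[[p]] <- pose(set_graph_coords(g, new), program = progs[p])
  }
  structure(pose_ensemble(poses, ligand_id = g$id),
            truth = list(level = spec$n_consensus,
                         consensus_programs = progs[members]))
}

# ---- receptor with a planted thiol pocket ---------------------------------

BACKBONE_TEMPLATE <- list(
  N  = c(-1.20, -0.80, 0.00),
  H  = c(-1.85, -1.55, 0.00),
  CA = c(0.00, 0.00, 0.00),
  C  = c(1.20, -0.80, 0.00),
  O  = c(1.20, -2.03, 0.00)
)

SIDECHAIN_TEMPLATES <- list(
  GLY = list(),
  ALA = list(CB = c(0.0, 1.2, 0.9)),
  CYS = list(CB = c(0.0, 1.2, 0.9), SG = c(0.0, 2.30, 0.0),
             HG = c(0.0, 3.64, 0.0)),
  THR = list(CB = c(0.0, 1.2, 0.9), OG1 = c(0.0, 2.40, 0.6),
             HG1 = c(0.0, 3.30, 0.9), CG2 = c(1.2, 1.8, 1.5))
)

#' Generate a minimal receptor with a planted catalytic-cysteine pocket
#'
#' Builds a six-residue chain A (G311-A312-C313-C314-T315-G316) whose
#' cysteine thiols point into an open pocket, plus ligand poses that either
#' do or do not hydrogen-bond to the catalytic cysteines, labelled by
#' construction.  Contact poses place the ligand's first carbonyl oxygen at
#' 2.8 A from a catalytic SG with an S-H...O angle of 160 deg; non-contact
#' poses put every ligand atom beyond hydrogen-bonding range of every polar
#' protein atom.
#'
#' @param n_contact,n_noncontact number of poses of each label.
#' @param ligand toy ligand to pose (default the phthalimide, whose carbonyl
#'   is the acceptor the campaign keys on).
#' @param seed integer seed (required).
#' @return list with `protein`, `poses` (named list, ids `cmpd001`...),
#'   `labels` (logical vector: TRUE = planted contact).
#' @export
gen_receptor_with_pocket <- function(n_contact = 10, n_noncontact = 10,
                                     ligand = gen_toy_ligand("isoindoline_dione"),
                                     seed) {
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  resdefs <- data.frame(resno = 311:316,
                        resid = c("GLY", "ALA", "CYS", "CYS", "THR", "GLY"),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (r in seq_len(nrow(resdefs))) {
    # wiggly CA trace (non-collinear and non-coplanar, so rigid
    # superposition is fully determined)
    ca <- c((resdefs$resno[r] - 313) * 3.5, 0.35 * ((r * 2L) %% 3L - 1L),
            0.6 * (r %% 2L))
    tmpl <- c(BACKBONE_TEMPLATE, SIDECHAIN_TEMPLATES[[resdefs$resid[r]]])
    for (nm in names(tmpl)) {
      xyz <- ca + tmpl[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resno = resdefs$resno[r], resid = resdefs$resid[r],
        name = nm, element = substr(nm, 1L, 1L),
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
  }
  protein <- protein_structure(do.call(rbind, rows), source = "synthetic")
  acceptor <- planted_acceptor_atom(ligand)
  polar_ymax <- max(protein$atoms$y[protein$atoms$element %in%
                                      c("N", "O", "S", "H")])
  lig_radius <- max(sqrt(rowSums(
    sweep(graph_coords(ligand), 2L,
          colMeans(graph_coords(ligand)))^2)))
  poses <- list(); labels <- logical()
  for (k in seq_len(n_contact + n_noncontact)) {
    contact <- k <= n_contact
    resno <- if (contact && k %% 2L) 313L else 314L
    if (contact) {
      lg <- place_at_hbond(ligand, protein, resno, acceptor,
                           d = 2.8, angle = 160)
    } else {
      ctr <- colMeans(graph_coords(ligand))
      target_y <- polar_ymax + 3.7 + lig_radius + stats::runif(1, 0, 2)
      shift <- c(stats::runif(1, -3, 3), target_y - ctr[2],
                 stats::runif(1, -3, 3))
      lg <- set_graph_coords(ligand, sweep(graph_coords(ligand), 2L, -shift))
    }
    poses[[sprintf("cmpd%03d", k)]] <- pose(lg, program = "Glide SP")
    labels <- c(labels, contact)
  }
  ord <- sample(length(poses))  # shuffle so labels are not positional
  list(protein = protein, poses = poses[ord], labels = labels[ord])
}

# first carbonyl oxygen (O double-bonded to C), else first O, else first N
planted_acceptor_atom <- function(lig) {
  b <- lig$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != "2") next
    pair <- c(b$i[k], b$j[k])
    o <- pair[lig$atoms$element[pair] == "O"]
    if (length(o)) return(o[1L])
  }
  o <- which(lig$atoms$element == "O")
  if (length(o)) return(o[1L])
  n <- which(lig$atoms$element == "N")
  if (length(n)) return(n[1L])
  stop("ligand has no acceptor atom")
}

# translate the ligand so `acceptor` sits at the planted H-bond position
# relative to residue `resno`'s S-H (or O-H) donor
place_at_hbond <- function(ligand, protein, resno, acceptor, d = 2.8,
                           angle = 160) {
  res <- residue_atoms(protein, "A", resno)
  dn <- res[res$name %in% c("SG", "OG1"), ][1L, ]
  hy <- res[res$name %in% c("HG", "HG1"), ][1L, ]
  s <- c(dn$x, dn$y, dn$z); h <- c(hy$x, hy$y, hy$z)
  u <- unit3(h - s)
  bond_len <- sqrt(sum((h - s)^2))
  # acceptor along a direction tilted (180 - angle) deg off the S-H axis
  tilt <- (180 - angle) * pi / 180
  perp <- unit3(c(u[2], -u[1], 0.3))
  perp <- unit3(perp - sum(perp * u) * u)
  w <- cos(tilt) * u + sin(tilt) * perp
  # solve |s - (h + t w)| = d for t > 0
  b2 <- 2 * bond_len * sum(u * w)
  t <- (-b2 + sqrt(b2^2 - 4 * (bond_len^2 - d^2))) / 2
  target <- h + t * w
  xyz <- graph_coords(ligand)
  set_graph_coords(ligand, sweep(xyz, 2L, xyz[acceptor, ] - target))
}

# ---- trajectories ---------------------------------------------------------

#' Specification of a synthetic trajectory
#'
#' @param n_frames number of frames.
#' @param planted list of planted interactions, each
#'   `list(resno =, occupancy =)` or `list(resno =, mask = logical)`;
#'   occupancies use a deterministic evenly-spread frame mask, masks are
#'   taken verbatim.  Use `stochastic = TRUE` inside an entry for Bernoulli
#'   planting at rate `occupancy`.
#' @param sigma Gaussian coordinate noise, A (applied to every atom).
#' @param seed integer seed (required).
#' @param frame_interval ps per frame.
#' @param two_state optional `list(major_fraction =, offset =)`: instead of
#'   planted interactions, frames alternate (deterministically, evenly
#'   spread) between the bound pose and a displaced pose.
#' @export
trajectory_spec <- function(n_frames, planted = list(), sigma = 0.03, seed,
                            frame_interval = 200, two_state = NULL) {
  stopifnot(n_frames >= 2, sigma >= 0, !missing(seed))
  for (p in planted)
    if (!is.null(p$occupancy))
      stopifnot(p$occupancy >= 0, p$occupancy <= 1)
  structure(list(n_frames = as.integer(n_frames), planted = planted,
                 sigma = sigma, seed = as.integer(seed),
                 frame_interval = frame_interval, two_state = two_state),
            class = "trajectory_spec")
}

# evenly-spread deterministic mask with exactly round(n * f) TRUE entries
spread_mask <- function(n, f) {
  k <- seq_len(n)
  floor(k * f) > floor((k - 1) * f)
}

#' Generate a trajectory with planted interaction occupancies
#'
#' Frames carry Gaussian coordinate noise; on each planted frame the ligand
#' is rigidly translated so its acceptor oxygen satisfies the hydrogen-bond
#' criteria against the planted residue exactly (d = 2.8 A, angle 160 deg,
#' computed against that frame's noisy donor), and on all other frames every
#' ligand atom is beyond hydrogen-bonding range of every polar protein atom.
#' Reproducible by seed.
#'
#' @param spec a [trajectory_spec()].
#' @param protein receptor topology (e.g. from
#'   [gen_receptor_with_pocket()]).
#' @param ligand ligand topology/base conformation.
#' @return a `trajectory`; planted masks are attached as attribute `truth`.
#' @export
gen_trajectory <- function(spec, protein, ligand) {
  stopifnot(inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  np <- nrow(protein$atoms)
  nl <- n_atoms(ligand)
  base_prot <- as.matrix(protein$atoms[, c("x", "y", "z")])
  acceptor <- planted_acceptor_atom(ligand)
  polar_ymax <- max(protein$atoms$y[protein$atoms$element %in%
                                      c("N", "O", "S", "H")])
  ligxyz <- graph_coords(ligand)
  lig_radius <- max(sqrt(rowSums(sweep(ligxyz, 2L, colMeans(ligxyz))^2)))
  far_y <- polar_ymax + 4.2 + lig_radius
  masks <- lapply(spec$planted, function(p) {
    if (!is.null(p$mask)) p$mask
    else if (isTRUE(p$stochastic)) stats::runif(spec$n_frames) < p$occupancy
    else spread_mask(spec$n_frames, p$occupancy)
  })
  two_state_mask <- if (!is.null(spec$two_state))
    spread_mask(spec$n_frames, spec$two_state$major_fraction) else NULL
  frames <- vector("list", spec$n_frames)
  hrows <- which(protein$atoms$element == "H")  # each H follows its heavy atom
  for (k in seq_len(spec$n_frames)) {
    noise <- matrix(stats::rnorm(3L * np, sd = spec$sigma), np, 3L)
    # hydrogens ride with their parent heavy atom so bond geometry (and
    # hence donor-H attachment) is never perturbed across a criterion
    noise[hrows, ] <- noise[hrows - 1L, , drop = FALSE]
    prot_k <- base_prot + noise
    prot_view <- protein
    prot_view$atoms[, c("x", "y", "z")] <- prot_k
    planted_here <- which(vapply(masks, function(m) m[k], TRUE))
    if (!is.null(two_state_mask)) {
      lg <- place_at_hbond(ligand, prot_view, 314L, acceptor)
      lig_k <- graph_coords(lg)
      if (!two_state_mask[k])
        lig_k <- sweep(lig_k, 2L, -spec$two_state$offset)
    } else if (length(planted_here)) {
      lg <- place_at_hbond(ligand, prot_view,
                           spec$planted[[planted_here[1L]]]$resno, acceptor)
      lig_k <- graph_coords(lg)
    } else {
      ctr <- colMeans(ligxyz)
      lig_k <- sweep(ligxyz, 2L, -c(0, far_y - ctr[2], 0))
    }
    lig_k <- lig_k + matrix(stats::rnorm(3L * nl, sd = spec$sigma), nl, 3L)
    # noise must not push the planted geometry across a criterion; the
    # planted margins (0.7 A, 40 deg) dwarf any sensible sigma, but restore
    # the acceptor exactly on bound/planted frames for determinism
    bound_here <- length(planted_here) > 0L ||
      (!is.null(two_state_mask) && two_state_mask[k])
    if (bound_here) {
      lig_k <- lig_k + matrix(graph_coords(lg)[acceptor, ] - lig_k[acceptor, ],
                              nl, 3L, byrow = TRUE)
    }
    frames[[k]] <- rbind(prot_k, lig_k)
  }
  structure(trajectory(protein, ligand, frames,
                       frame_interval = spec$frame_interval),
            truth = list(masks = masks, two_state = two_state_mask))
}
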