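# Geometric protein-ligand interaction detectors.
#
# Conventions (all config-exposed):
#  * H-bond: donor-acceptor heavy-atom distance <= d_max (default 3.5 A,
#    inclusive) AND D-H...A angle measured at the hydrogen > angle_min
#    (default 120 deg, exclusive).  Donors are N/O/S with an attached
#    explicit hydrogen (thiol S included, so the catalytic cysteines can
#    donate); acceptors are N/O/S.  Donors lacking an attached H are skipped
#    with a warning; no distance-only fallback.
#  * pi stack: ring-centroid distance <= 5.5 A with inter-normal (acute)
#    angle <= 30 deg (face-to-face) or >= 60 deg (edge-to-face).
#  * hydrophobic: ligand-C to apolar-side-chain-C contacts <= 4.5 A,
#    aggregated per residue.
#  * halogen: C-X...acceptor with X...A <= 3.6 A and the angle at X >= 140.

#' Geometric hydrogen-bond criteria
#' @param d_max donor-acceptor heavy-atom distance cap in Angstrom.
#' @param angle_min D-H...A angle floor in degrees (exclusive).
#' @export
hbond_criteria <- function(d_max = 3.5, angle_min = 120) {
  stopifnot(d_max > 0, angle_min > 0, angle_min < 180)
  structure(list(d_max = d_max, angle_min = angle_min),
            class = "hbond_criteria")
}

DONOR_ELEMENTS <- c("N", "O", "S")
ACCEPTOR_ELEMENTS <- c("N", "O", "S")

interaction_record <- function(kind, lig_atoms, chain, resno, resid,
                               prot_atom, distance, angle = NA_real_,
                               geometry = "") {
  data.frame(kind = kind, lig_atoms = paste(lig_atoms, collapse = ","),
             chain = chain, resno = as.integer(resno), resid = resid,
             prot_atom = prot_atom, distance = distance, angle = angle,
             geometry = geometry, stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(kind = character(), lig_atoms = character(), chain = character(),
             resno = integer(), resid = character(), prot_atom = character(),
             distance = numeric(), angle = numeric(), geometry = character(),
             stringsAsFactors = FALSE)
}

angle_deg <- function(a, b, c) {
  # angle at b between a and c
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# protein donors/acceptors/H positions as plain tables
protein_polar_atoms <- function(protein, residue_filter = NULL) {
  at <- protein$atoms
  if (!is.null(residue_filter)) {
    keep <- paste(at$chain, at$resno) %in%
      vapply(residue_filter, function(r) paste(r[[1L]], r[[2L]]), "")
    at <- at[keep, , drop = FALSE]
  }
  at
}

# hydrogens attached to protein atom row i (same residue, <= 1.45 A, which
# covers O-H ~0.97, N-H ~1.01 and S-H ~1.34 without reaching C-H neighbours)
protein_attached_h <- function(at, full, i) {
  same <- which(full$chain == at$chain[i] & full$resno == at$resno[i] &
                  full$element == "H")
  if (!length(same)) return(integer())
  d <- sqrt((full$x[same] - at$x[i])^2 + (full$y[same] - at$y[i])^2 +
              (full$z[same] - at$z[i])^2)
  same[d <= 1.45]
}

#' Detect hydrogen bonds between a ligand pose and a protein
#'
#' Both directions are evaluated (ligand donor to protein acceptor and
#' protein donor to ligand acceptor).  Requires explicit hydrogens on donors.
#'
#' @param pose a `pose` (or `molecular_graph`) with coordinates.
#' @param protein a `protein_structure`.
#' @param criteria an [hbond_criteria()].
#' @param residue_filter optional list of `c(chain, resno)` pairs (or strings
#'   `"A:313"`) restricting the protein side.
#' @return data.frame of interaction records (kind `"hbond"`); each row's
#'   stored geometry satisfies the criteria that admitted it.
#' @export
detect_hbonds <- function(pose, protein, criteria = hbond_criteria(),
                          residue_filter = NULL) {
  lig <- if (inherits(pose, "pose")) pose$ligand else pose
  residue_filter <- parse_residue_filter(residue_filter)
  at <- protein_polar_atoms(protein, residue_filter)
  full <- protein$atoms
  lx <- graph_coords(lig)
  recs <- list()
  d_max <- criteria$d_max; angle_min <- criteria$angle_min
  prot_xyz <- as.matrix(at[, c("x", "y", "z")])
  # donor candidates without an attached explicit hydrogen are not donors
  # (a carbonyl oxygen, say); but a structure carrying no hydrogens at all
  # cannot satisfy the donor precondition, which deserves one warning per
  # side -- there is no distance-only fallback
  if (!any(lig$atoms$element == "H") &&
      any(lig$atoms$element %in% DONOR_ELEMENTS))
    message("ligand has no explicit hydrogens; its donors are skipped")
  if (!any(full$element == "H") && any(at$element %in% DONOR_ELEMENTS))
    message("protein has no explicit hydrogens; its donors are skipped")
  # ligand donors -> protein acceptors
  lig_donors <- which(lig$atoms$element %in% DONOR_ELEMENTS)
  prot_acc <- which(at$element %in% ACCEPTOR_ELEMENTS)
  for (d in lig_donors) {
    hs <- attached_hydrogens(lig, d)
    if (!length(hs)) next
    for (a in prot_acc) {
      dist <- sqrt(sum((lx[d, ] - prot_xyz[a, ])^2))
      if (dist > d_max) next
      for (h in hs) {
        ang <- angle_deg(lx[d, ], lx[h, ], prot_xyz[a, ])
        if (ang > angle_min) {
          recs[[length(recs) + 1L]] <- interaction_record(
            "hbond", c(d, h), at$chain[a], at$resno[a], at$resid[a],
            at$name[a], dist, ang, "ligand_donor")
          break
        }
      }
    }
  }
  # protein donors -> ligand acceptors
  prot_don <- which(at$element %in% DONOR_ELEMENTS)
  lig_acc <- which(lig$atoms$element %in% ACCEPTOR_ELEMENTS)
  for (d in prot_don) {
    hs <- protein_attached_h(at, full, d)
    if (!length(hs)) next
    for (a in lig_acc) {
      dist <- sqrt(sum((prot_xyz[d, ] - lx[a, ])^2))
      if (dist > d_max) next
      for (h in hs) {
        hxyz <- c(full$x[h], full$y[h], full$z[h])
        ang <- angle_deg(prot_xyz[d, ], hxyz, lx[a, ])
        if (ang > angle_min) {
          recs[[length(recs) + 1L]] <- interaction_record(
            "hbond", a, at$chain[d], at$resno[d], at$resid[d],
            at$name[d], dist, ang, "protein_donor")
          break
        }
      }
    }
  }
  if (!length(recs)) return(empty_records())
  do.call(rbind, recs)
}

parse_residue_filter <- function(rf) {
  if (is.null(rf)) return(NULL)
  lapply(rf, function(r) {
    if (is.character(r) && length(r) == 1L && grepl(":", r)) {
      parts <- strsplit(r, ":")[[1L]]
      list(parts[1L], as.integer(parts[2L]))
    } else list(r[[1L]], as.integer(r[[2L]]))
  })
}

# ---- aromatic rings -------------------------------------------------------

# rings in the ligand's aromatic-bond subgraph (simple cycles, length 5-7)
ligand_aromatic_rings <- function(lig) {
  b <- lig$bonds[lig$bonds$order == "ar", , drop = FALSE]
  if (!nrow(b)) return(list())
  adj <- list()
  for (k in seq_len(nrow(b))) {
    i <- as.character(b$i[k]); j <- as.character(b$j[k])
    adj[[i]] <- c(adj[[i]], b$j[k]); adj[[j]] <- c(adj[[j]], b$i[k])
  }
  rings <- list()
  seen <- character()
  verts <- sort(unique(c(b$i, b$j)))
  path <- integer()
  dfs <- function(v, start, depth) {
    path[depth] <<- v
    for (w in adj[[as.character(v)]]) {
      if (w == start && depth >= 5L) {
        ring <- path[seq_len(depth)]
        key <- paste(sort(ring), collapse = ",")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- ring
        }
      } else if (depth < 7L && !w %in% path[seq_len(depth)] && w > start) {
        dfs(w, start, depth + 1L)
      }
    }
  }
  for (v in verts) dfs(v, v, 1L)
  rings
}

PROTEIN_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

ring_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2L, ctr)
  sv <- svd(x)
  list(centroid = ctr, normal = sv$v[, 3L])
}

#' Detect aromatic pi-stacking contacts
#'
#' Ring pairs with centroid distance <= `d_max`; the acute inter-normal angle
#' classifies the geometry: <= `angle_tol` face-to-face, >= 90 - `angle_tol`
#' edge-to-face.
#'
#' @param pose ligand pose with aromatic bond flags.
#' @param protein a `protein_structure` (rings perceived for PHE/TYR/HIS/TRP
#'   by atom name).
#' @param d_max centroid-centroid cap in Angstrom.
#' @param angle_tol angular tolerance in degrees.
#' @return data.frame of records (kind `"pi_stack"`), `geometry` column
#'   `"face"` or `"edge"`.
#' @export
detect_pi_stack <- function(pose, protein, d_max = 5.5, angle_tol = 30) {
  lig <- if (inherits(pose, "pose")) pose$ligand else pose
  lrings <- ligand_aromatic_rings(lig)
  if (!length(lrings)) return(empty_records())
  lx <- graph_coords(lig)
  at <- protein$atoms
  recs <- list()
  res <- unique(at[at$resid %in% names(PROTEIN_RINGS), c("chain", "resno",
                                                         "resid")])
  for (r in seq_len(nrow(res))) {
    ra <- residue_atoms(protein, res$chain[r], res$resno[r])
    for (names_set in PROTEIN_RINGS[[res$resid[r]]]) {
      rows <- match(names_set, ra$name)
      if (any(is.na(rows))) next
      pp <- ring_plane(as.matrix(ra[rows, c("x", "y", "z")]))
      for (lr in lrings) {
        lp <- ring_plane(lx[lr, , drop = FALSE])
        dist <- sqrt(sum((pp$centroid - lp$centroid)^2))
        if (dist > d_max) next
        cosang <- abs(sum(pp$normal * lp$normal))
        phi <- acos(max(-1, min(1, cosang))) * 180 / pi  # acute, in [0, 90]
        geom <- if (phi <= angle_tol) "face"
                else if (phi >= 90 - angle_tol) "edge" else NA_character_
        if (is.na(geom)) next
        recs[[length(recs) + 1L]] <- interaction_record(
          "pi_stack", lr, res$chain[r], res$resno[r], res$resid[r],
          "ring", dist, phi, geom)
      }
    }
  }
  if (!length(recs)) return(empty_records())
  do.call(rbind, recs)
}

APOLAR_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")
BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HA")

#' Detect hydrophobic (carbon-carbon) contacts
#'
#' Ligand carbons against side-chain carbons of apolar residues within
#' `d_max`, aggregated to one record per residue (minimum distance, contact
#' count in `geometry`).
#'
#' @param pose ligand pose.
#' @param protein a `protein_structure`.
#' @param d_max contact distance cap in Angstrom.
#' @export
detect_hydrophobic <- function(pose, protein, d_max = 4.5) {
  lig <- if (inherits(pose, "pose")) pose$ligand else pose
  lc <- which(lig$atoms$element == "C")
  if (!length(lc)) return(empty_records())
  lx <- graph_coords(lig)[lc, , drop = FALSE]
  at <- protein$atoms
  sel <- at$resid %in% APOLAR_RESIDUES & at$element == "C" &
    !(at$name %in% BACKBONE_NAMES)
  if (!any(sel)) return(empty_records())
  at <- at[sel, , drop = FALSE]
  px <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(lx^2), rowSums(px^2), "+") - 2 * lx %*% t(px)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  recs <- list()
  for (key in unique(paste(at$chain, at$resno))) {
    cols <- which(paste(at$chain, at$resno) == key)
    sub <- d[, cols, drop = FALSE]
    hits <- which(sub <= d_max, arr.ind = TRUE)
    if (!nrow(hits)) next
    jmin <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    recs[[length(recs) + 1L]] <- interaction_record(
      "hydrophobic", lc[unique(hits[, 1L])], at$chain[cols[1L]],
      at$resno[cols[1L]], at$resid[cols[1L]], at$name[cols[jmin[2L]]],
      min(sub), NA_real_, sprintf("%d contacts", nrow(hits)))
  }
  if (!length(recs)) return(empty_records())
  do.call(rbind, recs)
}

#' Detect halogen bonds
#'
#' Ligand Cl/Br/I bound to carbon, against protein N/O/S acceptors:
#' X...A distance <= `d_max` and C-X...A angle (at the halogen) >= `angle_min`.
#'
#' @param pose ligand pose (needs bonds to locate the C-X axis).
#' @param protein a `protein_structure`.
#' @param d_max distance cap in Angstrom.
#' @param angle_min angle floor in degrees (inclusive).
#' @export
detect_halogen <- function(pose, protein, d_max = 3.6, angle_min = 140) {
  lig <- if (inherits(pose, "pose")) pose$ligand else pose
  xi <- which(lig$atoms$element %in% c("Cl", "Br", "I"))
  if (!length(xi)) return(empty_records())
  lx <- graph_coords(lig)
  at <- protein$atoms
  acc <- which(at$element %in% ACCEPTOR_ELEMENTS)
  if (!length(acc)) return(empty_records())
  recs <- list()
  for (x in xi) {
    nb <- c(lig$bonds$j[lig$bonds$i == x], lig$bonds$i[lig$bonds$j == x])
    cnb <- nb[lig$atoms$element[nb] == "C"]
    if (!length(cnb)) next
    for (a in acc) {
      axyz <- c(at$x[a], at$y[a], at$z[a])
      dist <- sqrt(sum((lx[x, ] - axyz)^2))
      if (dist > d_max) next
      ang <- angle_deg(lx[cnb[1L], ], lx[x, ], axyz)
      if (ang >= angle_min) {
        recs[[length(recs) + 1L]] <- interaction_record(
          "halogen", c(cnb[1L], x), at$chain[a], at$resno[a], at$resid[a],
          at$name[a], dist, ang)
      }
    }
  }
  if (!length(recs)) return(empty_records())
  do.call(rbind, recs)
}
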