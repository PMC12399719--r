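# Gaussian shape overlap and shape-Tanimoto similarity.
#
# Each heavy atom is a spherical Gaussian p * exp(-alpha * r^2) with a
# uniform radius (default 1.70 A) and amplitude p = 2*sqrt(2).  With the
# width fixed so that a single Gaussian integrates to the volume of a hard
# sphere of that radius, this amplitude also makes the self-overlap of an
# isolated atom equal that hard-sphere volume.  Overlap between two
# molecules is the integral of the product of their total densities, which
# for sums of Gaussians is an exact pairwise sum (first order; no multi-body
# corrections are applied).

GAUSS_P <- 2 * sqrt(2)

gauss_alpha <- function(radius) {
  pi * (3 * GAUSS_P / (4 * pi * radius^3))^(2 / 3)
}

#' Gaussian overlap volume between two molecules
#'
#' @param molA,molB `molecular_graph`s (or poses) with heavy-atom
#'   coordinates.  Heavy atoms only are used.
#' @param radius uniform atomic radius in Angstrom.
#' @return overlap volume in cubic Angstrom (symmetric, non-negative).
#' @export
gaussian_overlap_volume <- function(molA, molB, radius = 1.70) {
  a <- shape_coords(molA)
  b <- shape_coords(molB)
  alpha <- gauss_alpha(radius)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sum(GAUSS_P^2 * (pi / (2 * alpha))^1.5 * exp(-alpha * d2 / 2))
}

shape_coords <- function(mol) {
  if (inherits(mol, "pose")) mol <- mol$ligand
  xyz <- graph_coords(mol, heavy_only = TRUE)
  if (nrow(xyz) == 0L) stop("molecule has no heavy atoms")
  if (any(!is.finite(xyz))) stop("heavy-atom coordinates required")
  xyz
}

#' Shape-Tanimoto similarity between two molecules
#'
#' T = O_AB / (O_AA + O_BB - O_AB) over Gaussian overlap volumes.  With
#' `align = "principal_axes"` both molecules are centred on their heavy-atom
#' centroid and rotated into their principal axes; the four proper axis-flip
#' orientations of B are tried and the best Tanimoto returned.  No gradient
#' refinement is performed.
#'
#' @param molA,molB `molecular_graph`s (or poses).
#' @param align `"none"` (compare in the given frame) or `"principal_axes"`.
#' @param radius uniform atomic radius in Angstrom.
#' @return object of class `shape_overlap_result` with fields `overlap_ab`,
#'   `self_a`, `self_b`, `tanimoto`.
#' @export
shape_tanimoto <- function(molA, molB, align = c("none", "principal_axes"),
                           radius = 1.70) {
  align <- match.arg(align)
  a <- shape_coords(molA)
  b <- shape_coords(molB)
  alpha <- gauss_alpha(radius)
  ov <- function(x, y) {
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y)
    d2[d2 < 0] <- 0
    sum(GAUSS_P^2 * (pi / (2 * alpha))^1.5 * exp(-alpha * d2 / 2))
  }
  self_a <- ov(a, a); self_b <- ov(b, b)
  if (align == "principal_axes") {
    a <- principal_frame(a)
    b0 <- principal_frame(b)
    flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
                  diag(c(-1, -1, 1)))
    best <- -Inf; best_ab <- NA_real_
    for (fl in flips) {
      oab <- ov(a, b0 %*% fl)
      tan <- oab / (self_a + self_b - oab)
      if (tan > best) { best <- tan; best_ab <- oab }
    }
    overlap_ab <- best_ab
  } else {
    overlap_ab <- ov(a, b)
  }
  tanimoto <- overlap_ab / (self_a + self_b - overlap_ab)
  structure(list(overlap_ab = overlap_ab, self_a = self_a, self_b = self_b,
                 tanimoto = tanimoto, align = align),
            class = "shape_overlap_result")
}

#' @export
print.shape_overlap_result <- function(x, ...) {
  cat(sprintf("<shape_overlap> T=%.4f (O_AB=%.2f, O_AA=%.2f, O_BB=%.2f, %s)\n",
              x$tanimoto, x$overlap_ab, x$self_a, x$self_b, x$align))
  invisible(x)
}

# centre on centroid, rotate into principal axes with a deterministic sign
# convention (largest-magnitude component of each axis positive, det = +1)
principal_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2L, ctr)
  if (nrow(x) == 1L) return(x)
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  v <- ev$vectors
  for (k in 1:3) {
    lead <- which.max(abs(v[, k]))
    if (v[lead, k] < 0) v[, k] <- -v[, k]
  }
  if (det(v) < 0) v[, 3L] <- -v[, 3L]
  x %*% v
}

#' Filter a library by shape similarity to a query
#'
#' Survivors are exactly the molecules whose shape Tanimoto against the query
#' is at or above the threshold.
#'
#' @param library named list of `molecular_graph`s (names used as ids; falls
#'   back to each graph's `id`).
#' @param query `molecular_graph` query (e.g. the endogenous ligand).
#' @param threshold Tanimoto cutoff in `[0, 1]`.
#' @param align passed to [shape_tanimoto()].
#' @param radius uniform atomic radius.
#' @return list with `survivors` (ids), `tanimoto` (named vector) and
#'   `report` (a one-row stage report data.frame).
#' @export
filter_by_shape <- function(library, query, threshold = 0.65,
                            align = "principal_axes", radius = 1.70) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]")
  ids <- names(library)
  if (is.null(ids)) ids <- vapply(library, function(g) g$id, "")
  tan <- vapply(library, function(g)
    shape_tanimoto(g, query, align = align, radius = radius)$tanimoto, 0)
  names(tan) <- ids
  keep <- tan >= threshold
  list(survivors = ids[keep], tanimoto = tan,
       report = stage_table("shape_tanimoto", length(library), sum(keep),
                            n_initial = length(library)))
}
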