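# Complete-linkage consensus clustering of multi-program pose ensembles.
#
# Agglomerative max-linkage merging with a dendrogram cut at merge height
# <= cutoff (inclusive), which guarantees that every within-cluster pairwise
# RMSD is at or below the cutoff.  All tie-breaks are deterministic
# (smallest pose index); there is no randomness in this module.  This is the
# package's own implementation; stats::hclust serves only as an independent
# cross-check in the test suite.

#' Complete-linkage clustering of an RMSD matrix
#'
#' Clusters are grown by repeatedly merging the pair of clusters with the
#' smallest complete-linkage (maximum pairwise) distance; merging stops when
#' that minimum exceeds the cutoff.  Ties are broken by the smallest member
#' index, making the result invariant to pose reordering.
#'
#' @param matrix an `rmsd_matrix` or a plain symmetric non-negative matrix
#'   with zero diagonal.
#' @param cutoff within-cluster maximum pairwise RMSD, in Angstrom.
#' @return object of class `cluster_result`: `assignments` (cluster id per
#'   pose, ids numbered by decreasing cluster size, ties by smallest member),
#'   `sizes`, `programs` (per-cluster program label sets when available),
#'   `cutoff`.
#' @export
complete_linkage <- function(matrix, cutoff = 2.0) {
  labels <- NULL
  if (inherits(matrix, "rmsd_matrix")) {
    labels <- matrix$labels
    matrix <- matrix$values
  }
  n <- nrow(matrix)
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-8)) ||
      any(matrix < 0) || any(diag(matrix) != 0))
    stop("need a symmetric non-negative matrix with zero diagonal")
  stopifnot(cutoff >= 0)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL
    best_d <- Inf
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        d <- max(matrix[clusters[[a]], clusters[[b]]])
        key <- c(d, min(clusters[[a]]), min(clusters[[b]]))
        if (is.null(best) || d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 &&
             (key[2L] < best$key[2L] ||
              (key[2L] == best$key[2L] && key[3L] < best$key[3L])))) {
          best <- list(a = a, b = b, key = key)
          best_d <- d
        }
      }
    }
    if (best_d > cutoff) break
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters <- clusters[-c(best$a, best$b)]
    clusters[[length(clusters) + 1L]] <- merged
  }
  # number clusters by decreasing size, ties by smallest member index
  ord <- order(-vapply(clusters, length, 0L),
               vapply(clusters, min, 0L))
  clusters <- clusters[ord]
  assignments <- integer(n)
  for (k in seq_along(clusters)) assignments[clusters[[k]]] <- k
  programs <- if (!is.null(labels))
    lapply(clusters, function(m) unique(labels[m])) else NULL
  structure(list(assignments = assignments,
                 sizes = vapply(clusters, length, 0L),
                 members = clusters,
                 programs = programs,
                 cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d poses in %d clusters (cutoff %.2f A): %s\n",
              length(x$assignments), length(x$sizes),
              x$cutoff, paste(x$sizes, collapse = "+")))
  invisible(x)
}

#' Consensus level of a clustered pose ensemble
#'
#' The level counts the distinct docking programs represented in the largest
#' cluster (a duplicate pose from one program counts once).  Cluster-size
#' ties are broken in favour of the cluster with more distinct programs, then
#' by the smallest member index.
#'
#' @param cluster a `cluster_result`.
#' @param programs program label per pose, aligned with the matrix ordering
#'   (defaults to the labels captured in the cluster result).
#' @return object of class `consensus_score`: `level`, `largest_cluster_size`,
#'   `cluster` (index of the winning cluster), `programs` (its label set).
#' @export
consensus_level <- function(cluster, programs = NULL) {
  stopifnot(inherits(cluster, "cluster_result"))
  if (is.null(programs)) {
    if (is.null(cluster$programs))
      stop("no program labels available; pass `programs`")
    progsets <- cluster$programs
  } else {
    stopifnot(length(programs) == length(cluster$assignments))
    progsets <- lapply(cluster$members, function(m) unique(programs[m]))
  }
  sizes <- cluster$sizes
  nprog <- vapply(progsets, length, 0L)
  firsts <- vapply(cluster$members, min, 0L)
  win <- order(-sizes, -nprog, firsts)[1L]
  structure(list(level = nprog[win],
                 largest_cluster_size = sizes[win],
                 cluster = win,
                 programs = progsets[[win]]),
            class = "consensus_score")
}

#' @export
print.consensus_score <- function(x, ...) {
  cat(sprintf("<consensus_score> level %d (largest cluster: %d poses)\n",
              x$level, x$largest_cluster_size))
  invisible(x)
}

#' Select ligands by consensus level
#'
#' @param scores named integer vector of per-ligand consensus levels, or a
#'   data.frame with columns `ligand` and `level`.
#' @param min_level minimum level to keep (>= 1).
#' @param n_programs optional number of docking programs; a warning is
#'   emitted when `min_level` exceeds it (the selection is then empty by
#'   construction).
#' @return list with `selected` (ligand ids), `table` (ligand, level,
#'   selected flag) and `histogram` (level counts, for a Table-2-style
#'   report).
#' @export
select_by_consensus <- function(scores, min_level = 9, n_programs = NULL) {
  stopifnot(min_level >= 1)
  if (is.data.frame(scores)) {
    ligand <- as.character(scores$ligand)
    level <- as.integer(scores$level)
  } else {
    ligand <- names(scores)
    level <- as.integer(scores)
  }
  if (!is.null(n_programs) && min_level > n_programs)
    warning("min_level ", min_level, " exceeds the number of programs (",
            n_programs, "); nothing can be selected", call. = FALSE)
  sel <- level >= min_level
  hist <- as.data.frame(table(level = factor(level,
                                             levels = sort(unique(level),
                                                           decreasing = TRUE))),
                        stringsAsFactors = FALSE)
  names(hist) <- c("level", "n_compounds")
  hist$level <- as.integer(hist$level)
  list(selected = ligand[sel],
       table = data.frame(ligand = ligand, level = level, selected = sel,
                          stringsAsFactors = FALSE),
       histogram = hist)
}

#' Combine component energies into a binding free energy
#'
#' dG_bind = E_complex - E_ligand - E_receptor, in kcal/mol.  The component
#' energies come from an external end-state calculation (e.g. MM-GBSA); only
#' the combination is performed here.
#'
#' @param e_complex,e_ligand,e_receptor finite component energies, kcal/mol.
#' @export
delta_g_combine <- function(e_complex, e_ligand, e_receptor) {
  stopifnot(is.finite(e_complex), is.finite(e_ligand), is.finite(e_receptor))
  e_complex - e_ligand - e_receptor
}
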