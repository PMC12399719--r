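# Symmetry-aware heavy-atom RMSD between poses of one ligand.
#
# Chemical symmetry is handled through automorphisms of the heavy-atom
# multigraph with element labels on atoms and bond orders on edges (aromatic
# is its own order).  Docking-pose RMSD is in-place by default (poses share
# the receptor frame); optimal rigid superposition (Kabsch, via bio3d) is
# available per automorphism with `superpose = TRUE`.  Hydrogens are always
# excluded.

#' Automorphisms of a ligand's heavy-atom graph
#'
#' Exactly the permutations of heavy atoms preserving element labels and the
#' bond structure (orders included), found by backtracking over a
#' degree/label refinement.  The identity is always present.
#'
#' @param graph a `molecular_graph` whose heavy-atom subgraph is connected.
#' @param max_count abort (with an error suggesting a larger cap) when more
#'   than this many automorphisms are found.
#' @return object of class `automorphism_set`: a list with `perms` (a matrix,
#'   one row per permutation of heavy-atom positions) and `heavy` (the heavy
#'   atom indices the positions refer to).
#' @export
find_automorphisms <- function(graph, max_count = 10000) {
  hv <- heavy_atoms(graph)
  nh <- length(hv)
  if (nh == 0L) stop("no heavy atoms")
  if (!is_connected_heavy(graph)) stop("heavy-atom graph must be connected")
  pos <- integer(n_atoms(graph)); pos[hv] <- seq_len(nh)
  el <- graph$atoms$element[hv]
  # heavy-heavy adjacency with bond-order labels
  adj <- rep(list(integer()), nh)
  ord <- matrix("", nh, nh)
  b <- graph$bonds
  for (k in seq_len(nrow(b))) {
    i <- pos[b$i[k]]; j <- pos[b$j[k]]
    if (i == 0L || j == 0L) next
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    ord[i, j] <- ord[j, i] <- b$order[k]
  }
  # iterative refinement: colour = element + multiset of neighbour colours
  colour <- el
  repeat {
    sig <- vapply(seq_len(nh), function(i) {
      nb <- sort(paste(ord[i, adj[[i]]], colour[adj[[i]]]))
      paste(colour[i], paste(nb, collapse = "|"))
    }, "")
    new_colour <- match(sig, unique(sig))
    if (identical(as.integer(new_colour),
                  as.integer(match(colour, unique(colour))))) break
    colour <- as.character(new_colour)
  }
  colour <- match(sig, unique(sig))
  perms <- list()
  map <- rep(NA_integer_, nh)
  used <- rep(FALSE, nh)
  recurse <- function(k) {
    if (length(perms) > max_count)
      stop("more than ", max_count,
           " automorphisms; raise max_count if this is intended")
    if (k > nh) {
      perms[[length(perms) + 1L]] <<- map
      return(invisible())
    }
    for (t in which(colour == colour[k] & !used)) {
      ok <- TRUE
      # adjacency AND non-adjacency (ord "" = no bond) against every atom
      # already placed; atoms are placed in index order, so 1..k-1 is mapped
      for (m in seq_len(k - 1L)) {
        if (ord[t, map[m]] != ord[k, m]) { ok <- FALSE; break }
      }
      if (ok) {
        map[k] <<- t; used[t] <<- TRUE
        recurse(k + 1L)
        map[k] <<- NA_integer_; used[t] <<- FALSE
      }
    }
  }
  recurse(1L)
  structure(list(perms = do.call(rbind, perms), heavy = hv),
            class = "automorphism_set")
}

#' @export
print.automorphism_set <- function(x, ...) {
  cat(sprintf("<automorphism_set> %d permutations of %d heavy atoms\n",
              nrow(x$perms), ncol(x$perms)))
  invisible(x)
}

same_ligand_graph <- function(ga, gb) {
  ha <- heavy_atoms(ga); hb <- heavy_atoms(gb)
  if (length(ha) != length(hb)) return(FALSE)
  if (!identical(ga$atoms$element[ha], gb$atoms$element[hb])) return(FALSE)
  hkey <- function(g, hv) {
    pos <- integer(n_atoms(g)); pos[hv] <- seq_along(hv)
    b <- g$bonds
    keep <- pos[b$i] > 0L & pos[b$j] > 0L
    sort(paste(pmin(pos[b$i[keep]], pos[b$j[keep]]),
               pmax(pos[b$i[keep]], pos[b$j[keep]]), b$order[keep]))
  }
  identical(hkey(ga, ha), hkey(gb, hb))
}

#' Symmetry-aware RMSD between two poses of the same ligand
#'
#' @param poseA,poseB `pose` objects (or `molecular_graph`s) of the same
#'   ligand, with identical heavy-atom ordering.
#' @param symmetry minimize over heavy-atom graph automorphisms.
#' @param superpose apply an optimal rigid (Kabsch) superposition of B onto A
#'   per automorphism before computing the RMSD; the default keeps the poses
#'   in place, the convention for docking-pose comparison.
#' @param auto optional precomputed `automorphism_set` (e.g. from
#'   [find_automorphisms()]) to avoid recomputation across many pairs.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(poseA, poseB, symmetry = TRUE, superpose = FALSE,
                      auto = NULL) {
  ga <- if (inherits(poseA, "pose")) poseA$ligand else poseA
  gb <- if (inherits(poseB, "pose")) poseB$ligand else poseB
  if (!same_ligand_graph(ga, gb))
    stop("poses are not the same ligand (heavy-atom graphs differ)")
  xa <- graph_coords(ga, heavy_only = TRUE)
  xb <- graph_coords(gb, heavy_only = TRUE)
  perms <- if (symmetry) {
    if (is.null(auto)) auto <- find_automorphisms(ga)
    auto$perms
  } else {
    matrix(seq_len(nrow(xa)), nrow = 1L)
  }
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    xbp <- xb[perms[r, ], , drop = FALSE]
    if (superpose) xbp <- kabsch_fit(xa, xbp)
    v <- sqrt(mean(rowSums((xa - xbp)^2)))
    if (v < best) best <- v
  }
  best
}

# superpose mobile onto fixed (n x 3 matrices) via bio3d's Kabsch fit
kabsch_fit <- function(fixed, mobile) {
  n3 <- 3L * nrow(fixed)
  ft <- bio3d::fit.xyz(as.vector(t(fixed)), as.vector(t(mobile)),
                       fixed.inds = seq_len(n3), mobile.inds = seq_len(n3))
  matrix(ft, ncol = 3L, byrow = TRUE)
}

#' Pairwise symmetry-aware RMSD matrix of a pose ensemble
#'
#' @param ensemble a `pose_ensemble` (>= 2 poses of one ligand).
#' @param symmetry,superpose as in [pose_rmsd()] (defaults match the
#'   consensus-docking convention: symmetry on, in place).
#' @return object of class `rmsd_matrix`: list with `values` (symmetric
#'   matrix, zero diagonal) and `labels` (program names).
#' @export
rmsd_matrix <- function(ensemble, symmetry = TRUE, superpose = FALSE) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  poses <- ensemble$poses
  n <- length(poses)
  if (n < 2L) stop("need at least 2 poses")
  auto <- if (symmetry) find_automorphisms(poses[[1L]]$ligand) else NULL
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- pose_rmsd(poses[[i]], poses[[j]],
                                      symmetry = symmetry,
                                      superpose = superpose, auto = auto)
    }
  }
  labels <- vapply(poses, function(p) p$program, "")
  dimnames(m) <- list(labels, labels)
  structure(list(values = m, labels = labels), class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat(sprintf("<rmsd_matrix> %d x %d poses\n", nrow(x$values), ncol(x$values)))
  print(round(x$values, 2))
  invisible(x)
}

#' Write an RMSD matrix as TSV with program-name header row/column
#' @param m an `rmsd_matrix`.
#' @param path output path.
#' @export
write_rmsd_matrix <- function(m, path) {
  df <- data.frame(program = m$labels, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Redocking acceptance test
#'
#' TRUE iff the symmetry-aware in-place RMSD between a predicted and a
#' reference pose is at or below the threshold (boundary inclusive).
#'
#' @param predicted,reference poses of the same ligand.
#' @param threshold acceptance RMSD in Angstrom.
#' @export
redock_pass <- function(predicted, reference, threshold = 3.0) {
  pose_rmsd(predicted, reference) <= threshold
}
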