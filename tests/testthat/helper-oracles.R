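# Independent oracles and fixture builders used across the suite.
# These deliberately take the dumbest correct route (exhaustive enumeration,
# grid quadrature, double loops) and never share code with the functions
# they check.

# benzene with explicit hydrogens, planar
benzene_graph <- function() {
  ang <- (0:5) * pi / 3
  at <- data.frame(element = c(rep("C", 6), rep("H", 6)),
                   x = c(1.395 * cos(ang), 2.485 * cos(ang)),
                   y = c(1.395 * sin(ang), 2.485 * sin(ang)),
                   z = 0)
  bonds <- data.frame(i = c(1:6, 1:6), j = c(2:6, 1L, 7:12),
                      order = c(rep("ar", 6), rep("1", 6)))
  molecular_graph("benzene", at, bonds)
}

# phthalic acid: benzene with two adjacent COOH groups (heavy atoms only
# matter for matching; hydroxyl H included for the H1 primitive)
phthalic_acid_graph <- function() {
  ang <- (0:5) * pi / 3
  at <- data.frame(element = rep("C", 6),
                   x = 1.395 * cos(ang), y = 1.395 * sin(ang), z = 0)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1L), order = "ar")
  add <- function(at, bonds, anchor) {
    dir <- c(cos(ang[anchor]), sin(ang[anchor]), 0)
    perp <- c(-dir[2], dir[1], 0)
    c7 <- 1.395 * dir + 1.48 * dir
    at <- rbind(at, data.frame(element = c("C", "O", "O", "H"),
                               x = c(c7[1], c7[1] + 1.0, c7[1] + 0.6,
                                     c7[1] + 1.3),
                               y = c(c7[2], c7[2] + 0.9, c7[2] - 1.1,
                                     c7[2] - 1.5),
                               z = 0))
    n <- nrow(at)
    bonds <- rbind(bonds, data.frame(i = c(anchor, n - 3L, n - 3L, n - 1L),
                                     j = c(n - 3L, n - 2L, n - 1L, n),
                                     order = c("1", "2", "1", "1")))
    list(at = at, bonds = bonds)
  }
  r <- add(at, bonds, 1L)
  r <- add(r$at, r$bonds, 2L)
  molecular_graph("phthalic_acid", r$at, r$bonds)
}

# --- brute-force automorphisms --------------------------------------------
# enumerate label-preserving permutations as the cartesian product of
# within-element permutations, then test bond preservation directly

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    for (p in all_perms(v[-k]))
      out[[length(out) + 1L]] <- c(v[k], p)
  out
}

brute_automorphisms <- function(graph) {
  hv <- heavy_atoms(graph)
  nh <- length(hv)
  el <- graph$atoms$element[hv]
  pos <- integer(n_atoms(graph)); pos[hv] <- seq_len(nh)
  b <- graph$bonds
  keep <- pos[b$i] > 0L & pos[b$j] > 0L
  bkey <- function(i, j, o) paste(pmin(i, j), pmax(i, j), o)
  edges <- bkey(pos[b$i[keep]], pos[b$j[keep]], b$order[keep])
  classes <- split(seq_len(nh), el)
  class_perms <- lapply(classes, all_perms)
  grids <- do.call(expand.grid,
                   c(lapply(class_perms, seq_along), KEEP.OUT.ATTRS = FALSE))
  res <- list()
  for (g in seq_len(nrow(grids))) {
    perm <- integer(nh)
    for (ci in seq_along(classes))
      perm[classes[[ci]]] <- class_perms[[ci]][[grids[g, ci]]]
    mapped <- bkey(perm[pos[b$i[keep]]], perm[pos[b$j[keep]]], b$order[keep])
    if (setequal(mapped, edges) && length(mapped) == length(edges))
      res[[length(res) + 1L]] <- perm
  }
  res
}

# --- brute-force SMARTS-style embedding enumeration -----------------------
# exhaustively tries every injective assignment of pattern atoms to heavy
# atoms and validates every constraint at the end (no pruning)

brute_match <- function(graph, pattern) {
  q <- consdock:::parse_smarts(pattern)
  t <- consdock:::smarts_target(graph)
  nq <- length(q$atoms)
  res <- list()
  assign_next <- function(map) {
    if (length(map) == nq) {
      for (k in seq_len(nq))
        if (!consdock:::atom_matches(q$atoms[[k]], t, map[k])) return(invisible())
      for (b in q$bonds) {
        ord <- t$bond_order[[paste(min(map[b$i], map[b$j]),
                                   max(map[b$i], map[b$j]))]]
        if (is.null(ord) || !consdock:::bond_matches(b$spec, ord))
          return(invisible())
      }
      res[[length(res) + 1L]] <<- map
      return(invisible())
    }
    for (cand in setdiff(t$heavy, map)) assign_next(c(map, cand))
  }
  assign_next(integer())
  res
}

# --- grid quadrature for the Gaussian overlap ------------------------------

grid_overlap <- function(molA, molB, radius = 1.70, h = 0.05, margin = 4) {
  p <- 2 * sqrt(2)
  alpha <- pi * (3 * p / (4 * pi * radius^3))^(2 / 3)
  a <- graph_coords(molA, heavy_only = TRUE)
  b <- graph_coords(molB, heavy_only = TRUE)
  all <- rbind(a, b)
  gx <- seq(min(all[, 1]) - margin, max(all[, 1]) + margin, by = h)
  gy <- seq(min(all[, 2]) - margin, max(all[, 2]) + margin, by = h)
  gz <- seq(min(all[, 3]) - margin, max(all[, 3]) + margin, by = h)
  density <- function(xyz) {
    rho <- 0
    for (i in seq_len(nrow(xyz))) {
      ex <- exp(-alpha * (gx - xyz[i, 1])^2)
      ey <- exp(-alpha * (gy - xyz[i, 2])^2)
      ez <- exp(-alpha * (gz - xyz[i, 3])^2)
      rho <- rho + p * as.vector(outer(outer(ex, ey), ez))
    }
    rho
  }
  sum(density(a) * density(b)) * h^3
}

# single atoms / small systems as graphs for shape tests
atoms_graph <- function(xyz, elements = NULL) {
  xyz <- matrix(xyz, ncol = 3L)
  molecular_graph("pts", data.frame(
    element = elements %||% rep("C", nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_rotation_matrix <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply one rigid transform to a protein + pose pair
transform_complex <- function(protein, pose_obj, rot, shift) {
  pa <- as.matrix(protein$atoms[, c("x", "y", "z")])
  protein$atoms[, c("x", "y", "z")] <- pa %*% t(rot) +
    matrix(shift, nrow(pa), 3, byrow = TRUE)
  lig <- pose_obj$ligand
  lx <- graph_coords(lig) %*% t(rot) +
    matrix(shift, n_atoms(lig), 3, byrow = TRUE)
  list(protein = protein, pose = pose(set_graph_coords(lig, lx),
                                      pose_obj$program))
}

# random symmetric RMSD-like matrix with zero diagonal
random_dist_matrix <- function(n, scale = 5) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, scale)
  m + t(m)
}

# independent complete-linkage clustering via stats::hclust
hclust_partition <- function(m, cutoff) {
  cl <- stats::cutree(stats::hclust(stats::as.dist(m), method = "complete"),
                      h = cutoff)
  unname(split(seq_len(nrow(m)), cl))
}

partition_sets <- function(assignments) {
  unname(split(seq_along(assignments), assignments))
}

same_partition <- function(a, b) {
  norm <- function(p) sort(vapply(p, function(x)
    paste(sort(x), collapse = ","), ""))
  identical(norm(a), norm(b))
}
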