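# Core chemical containers shared by every stage of the pipeline.
#
# All coordinates are in Angstrom.  Atom indexing is 1-based everywhere a
# user sees it (reports, match tuples); internal loops use the same 1-based
# convention since this is R.  Hydrogens are carried when the input has them
# and are never added implicitly.

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Fe", "Zn", "Se", "Br", "I"
)

.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998, P = 30.974,
  S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904, B = 10.81, Si = 28.085,
  Se = 78.971, Na = 22.99, K = 39.098, Ca = 40.078, Mg = 24.305,
  Fe = 55.845, Zn = 65.38
)

#' Build a molecular graph
#'
#' The ligand identity object: an ordered atom list with optional 3-D
#' coordinates, a bond list with orders, and a free-form property map.
#'
#' @param id character identifier.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (may be NA),
#'   and optionally `formal_charge` (integer, default 0) and `name`
#'   (text label, e.g. a PDB atom name).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order`, one of `"1"`, `"2"`, `"3"`, `"ar"` (numeric 1/2/3/4 accepted;
#'   4 maps to aromatic).
#' @param properties named character vector or list of record-level
#'   properties (an SDF data block).
#' @return object of class `molecular_graph`.
#' @export
molecular_graph <- function(id, atoms, bonds = NULL, properties = list()) {
  stopifnot(is.character(id), length(id) == 1L)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!all(c("element", "x", "y", "z") %in% names(atoms)))
    stop("atoms needs columns element, x, y, z")
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$name)) atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  atoms$element <- as.character(atoms$element)
  bad <- setdiff(unique(atoms$element), .ELEMENTS)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.na(xyz) & !is.finite(xyz)))
    stop("non-finite coordinates")
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    bonds$order <- normalize_bond_order(bonds$order)
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    n <- nrow(atoms)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond index out of range")
    if (any(bonds$i == bonds$j)) stop("self-bond")
  }
  structure(
    list(id = id,
         atoms = atoms[, c("element", "x", "y", "z", "formal_charge", "name")],
         bonds = bonds[, c("i", "j", "order")],
         properties = as.list(properties)),
    class = "molecular_graph")
}

normalize_bond_order <- function(order) {
  order <- as.character(order)
  order[order %in% c("4", "ar", "am", "aromatic")] <- "ar"
  bad <- setdiff(unique(order), c("1", "2", "3", "ar"))
  if (length(bad)) stop("unsupported bond order(s): ", paste(bad, collapse = ", "))
  order
}

#' @export
print.molecular_graph <- function(x, ...) {
  nh <- sum(x$atoms$element != "H")
  cat(sprintf("<molecular_graph> %s: %d atoms (%d heavy), %d bonds\n",
              x$id, nrow(x$atoms), nh, nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a graph
#' @param graph a `molecular_graph`.
#' @export
n_atoms <- function(graph) nrow(graph$atoms)

#' Indices of heavy (non-hydrogen) atoms
#' @param graph a `molecular_graph`.
#' @export
heavy_atoms <- function(graph) which(graph$atoms$element != "H")

#' Coordinate matrix of a graph
#' @param graph a `molecular_graph`.
#' @param heavy_only keep non-hydrogen atoms only.
#' @return numeric matrix, one row per atom, columns x/y/z.
#' @export
graph_coords <- function(graph, heavy_only = FALSE) {
  m <- as.matrix(graph$atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  if (heavy_only) m <- m[heavy_atoms(graph), , drop = FALSE]
  m
}

#' Replace the coordinates of a graph
#' @param graph a `molecular_graph`.
#' @param xyz numeric matrix (n_atoms x 3).
#' @export
set_graph_coords <- function(graph, xyz) {
  stopifnot(nrow(xyz) == n_atoms(graph), ncol(xyz) == 3L)
  graph$atoms$x <- xyz[, 1]
  graph$atoms$y <- xyz[, 2]
  graph$atoms$z <- xyz[, 3]
  graph
}

# adjacency list over all atoms (list of integer vectors)
adjacency_list <- function(graph) {
  adj <- vector("list", n_atoms(graph))
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# connectivity of the heavy-atom subgraph (BFS)
is_connected_heavy <- function(graph) {
  hv <- heavy_atoms(graph)
  if (length(hv) <= 1L) return(TRUE)
  adj <- adjacency_list(graph)
  seen <- rep(FALSE, n_atoms(graph))
  queue <- hv[1L]; seen[hv[1L]] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w] && graph$atoms$element[w] != "H") {
        seen[w] <- TRUE; queue <- c(queue, w)
      }
    }
  }
  all(seen[hv])
}

# hydrogens bonded to atom i; falls back to a 1.25-A distance criterion when
# the graph carries no bonds (e.g. a ligand read back from PDB records)
attached_hydrogens <- function(graph, i) {
  if (nrow(graph$bonds)) {
    nb <- c(graph$bonds$j[graph$bonds$i == i], graph$bonds$i[graph$bonds$j == i])
    return(nb[graph$atoms$element[nb] == "H"])
  }
  hs <- which(graph$atoms$element == "H")
  if (!length(hs)) return(integer())
  xyz <- graph_coords(graph)
  d <- sqrt(colSums((t(xyz[hs, , drop = FALSE]) - xyz[i, ])^2))
  hs[d <= 1.25]
}

#' Construct a docked pose
#'
#' One conformation of a ligand in the receptor frame, tagged with the
#' docking method that produced it.
#'
#' @param ligand `molecular_graph` with coordinates on all atoms (heavy atoms
#'   must have finite coordinates).
#' @param program non-empty label of the generating docking method.
#' @param score optional docking score.
#' @export
pose <- function(ligand, program, score = NA_real_) {
  stopifnot(inherits(ligand, "molecular_graph"),
            is.character(program), length(program) == 1L, nzchar(program))
  hv <- heavy_atoms(ligand)
  xyz <- graph_coords(ligand)[hv, , drop = FALSE]
  if (any(!is.finite(xyz))) stop("all heavy atoms of a pose need coordinates")
  structure(list(ligand = ligand, program = program, score = score),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> %s [%s]%s\n", x$ligand$id, x$program,
              if (is.na(x$score)) "" else sprintf(" score=%.2f", x$score)))
  invisible(x)
}

#' Bundle poses of one ligand into an ensemble
#' @param poses list of `pose` objects of the same ligand.
#' @param ligand_id optional id; defaults to the first pose's ligand id.
#' @export
pose_ensemble <- function(poses, ligand_id = NULL) {
  stopifnot(length(poses) >= 1L, all(vapply(poses, inherits, TRUE, "pose")))
  if (is.null(ligand_id)) ligand_id <- poses[[1L]]$ligand$id
  structure(list(ligand_id = ligand_id, poses = poses), class = "pose_ensemble")
}

#' Construct a protein structure
#'
#' A flat atom table with a chain/residue hierarchy; residues are addressed
#' by (chain, residue number) using the file's author numbering verbatim.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `name`,
#'   `element`, `x`, `y`, `z` (and optionally `occupancy`).
#' @param source text provenance label.
#' @export
protein_structure <- function(atoms, source = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "resid", "name", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("protein atoms need columns ", paste(need, collapse = ", "))
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  atoms$resno <- as.integer(atoms$resno)
  structure(list(atoms = atoms[, c(need, "occupancy")], source = source),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  rt <- unique(x$atoms[, c("chain", "resno")])
  cat(sprintf("<protein_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), nrow(rt),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Atoms of one residue
#' @param protein a `protein_structure`.
#' @param chain chain identifier.
#' @param resno residue number (author numbering).
#' @export
residue_atoms <- function(protein, chain, resno) {
  protein$atoms[protein$atoms$chain == chain & protein$atoms$resno == resno, ,
                drop = FALSE]
}

#' Construct an MD trajectory
#'
#' Shared topology (protein plus ligand) with per-frame coordinates for every
#' topology atom.  Frame coordinates are stacked protein-then-ligand, matching
#' the row order of `rbind(protein$atoms, ligand$atoms)`.
#'
#' @param protein `protein_structure` topology.
#' @param ligand `molecular_graph` topology for the ligand.
#' @param frames list of numeric matrices (n_protein + n_ligand rows, 3 cols).
#' @param frame_interval time per frame in ps (> 0).
#' @export
trajectory <- function(protein, ligand, frames, frame_interval = 200) {
  stopifnot(inherits(protein, "protein_structure"),
            inherits(ligand, "molecular_graph"),
            frame_interval > 0, length(frames) >= 1L)
  ntot <- nrow(protein$atoms) + n_atoms(ligand)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == ntot &&
                 ncol(f) == 3L && all(is.finite(f)), TRUE)
  if (!all(ok)) stop("every frame needs finite coordinates for every topology atom")
  structure(list(protein = protein, ligand = ligand, frames = frames,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, %.0f ps/frame\n",
              length(x$frames), nrow(x$frames[[1L]]), x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Materialize one frame as a protein + pose pair
#'
#' @param traj a `trajectory`.
#' @param k frame index (1-based).
#' @return list with elements `protein` and `pose` carrying frame-k
#'   coordinates.
#' @export
frame_complex <- function(traj, k) {
  stopifnot(k >= 1L, k <= n_frames(traj))
  np <- nrow(traj$protein$atoms)
  f <- traj$frames[[k]]
  prot <- traj$protein
  prot$atoms[, c("x", "y", "z")] <- f[seq_len(np), , drop = FALSE]
  lig <- set_graph_coords(traj$ligand, f[np + seq_len(n_atoms(traj$ligand)), ,
                                         drop = FALSE])
  list(protein = prot, pose = pose(lig, program = sprintf("frame %d", k)))
}

#' Subset a trajectory to a window of frames
#' @param traj a `trajectory`.
#' @param idx integer frame indices to keep, in order.
#' @export
subset_trajectory <- function(traj, idx) {
  stopifnot(length(idx) >= 1L, all(idx >= 1L), all(idx <= n_frames(traj)))
  traj$frames <- traj$frames[idx]
  traj
}
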