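# PDB reading/writing, backed by bio3d.
#
# Residue numbering is taken verbatim from the file (author numbering).
# Altloc duplicates keep the highest-occupancy copy and say so in a message.
# Multi-MODEL files map to trajectories.

#' Read a PDB file into a protein structure
#'
#' @param path file path.
#' @param het how to treat HETATM records: `"ligand"` returns them as a
#'   bondless `molecular_graph` alongside the protein, `"keep"` leaves them in
#'   the protein table, `"drop"` discards them.
#' @return a `protein_structure`; with `het = "ligand"` and HETATM present, a
#'   list with elements `protein` and `ligands` (one graph per HET residue).
#' @export
read_pdb <- function(path, het = c("ligand", "keep", "drop")) {
  het <- match.arg(het)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb_atom_table(pdb$atom)
  at <- resolve_altloc(at)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("missing coordinates in ", path)
  is_het <- at$type == "HETATM" & at$resid != "HOH"
  prot <- protein_structure(at[!is_het | het == "keep", , drop = FALSE],
                            source = path)
  if (het != "ligand" || !any(is_het)) return(prot)
  ligs <- lapply(split(at[is_het, , drop = FALSE],
                       paste(at$chain[is_het], at$resno[is_het])),
                 hetatm_graph)
  list(protein = prot, ligands = unname(ligs))
}

pdb_atom_table <- function(atom) {
  data.frame(chain = atom$chain, resno = atom$resno, resid = atom$resid,
             name = atom$elety, element = pdb_element(atom),
             x = atom$x, y = atom$y, z = atom$z,
             occupancy = ifelse(is.na(atom$o), 1, atom$o),
             alt = ifelse(is.na(atom$alt), "", atom$alt),
             type = atom$type, stringsAsFactors = FALSE)
}

pdb_element <- function(atom) {
  el <- atom$elesy
  miss <- is.na(el) | !nzchar(trimws(el))
  # fall back to the leading letter(s) of the atom name
  el[miss] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atom$elety[miss])
  el <- trimws(el)
  substr(el, 2L, nchar(el)) <- tolower(substr(el, 2L, nchar(el)))
  el
}

resolve_altloc <- function(at) {
  key <- paste(at$chain, at$resno, at$name)
  dup <- key[duplicated(key) & nzchar(at$alt)]
  if (!length(dup)) return(at)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(dup)) {
    rows <- which(key == k)
    best <- rows[which.max(at$occupancy[rows])]
    keep[setdiff(rows, best)] <- FALSE
    message(sprintf("altloc at %s: kept copy '%s' (occupancy %.2f)",
                    k, at$alt[best], at$occupancy[best]))
  }
  at[keep, , drop = FALSE]
}

hetatm_graph <- function(rows) {
  molecular_graph(
    id = sprintf("%s_%s%d", rows$resid[1L], rows$chain[1L], rows$resno[1L]),
    atoms = data.frame(element = rows$element, x = rows$x, y = rows$y,
                       z = rows$z, name = rows$name, stringsAsFactors = FALSE))
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' @param path file path with MODEL/ENDMDL records and a consistent atom list.
#' @param ligand_resname residue name of the ligand HETATM records.
#' @param ligand_template optional `molecular_graph` whose atom names match
#'   the ligand records; its bonds (and elements) are grafted onto the
#'   coordinates so that detectors needing connectivity work on the frames.
#' @param frame_interval ps per frame.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, ligand_resname = "LIG",
                            ligand_template = NULL, frame_interval = 200) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb_atom_table(pdb$atom)
  nfr <- nrow(pdb$xyz)
  is_lig <- at$resid == ligand_resname
  if (!any(is_lig)) stop("no residue named ", ligand_resname, " in ", path)
  prot <- protein_structure(at[!is_lig, , drop = FALSE], source = path)
  lig_rows <- at[is_lig, , drop = FALSE]
  if (is.null(ligand_template)) {
    lig <- hetatm_graph(lig_rows)
  } else {
    idx <- match(lig_rows$name, ligand_template$atoms$name)
    if (any(is.na(idx)) || length(idx) != n_atoms(ligand_template))
      stop("ligand template atom names do not match the trajectory records")
    # reorder file atoms into template order, keep template bonds
    lig_rows <- lig_rows[order(idx), , drop = FALSE]
    lig <- set_graph_coords(ligand_template,
                            as.matrix(lig_rows[, c("x", "y", "z")]))
  }
  ord <- c(which(!is_lig), which(is_lig)[order(match(at$name[is_lig],
                                                    lig$atoms$name))])
  frames <- lapply(seq_len(nfr), function(k) {
    m <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)
    m[ord, , drop = FALSE]
  })
  trajectory(prot, lig, frames, frame_interval = frame_interval)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @param ligand_resname residue name for the ligand records.
#' @export
write_trajectory_pdb <- function(traj, path, ligand_resname = "LIG") {
  con <- file(path, "w")
  on.exit(close(con))
  pa <- traj$protein$atoms
  la <- traj$ligand$atoms
  for (k in seq_len(n_frames(traj))) {
    f <- traj$frames[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    for (i in seq_len(nrow(pa))) {
      writeLines(pdb_atom_line("ATOM", i, pa$name[i], pa$resid[i], pa$chain[i],
                               pa$resno[i], f[i, ], pa$element[i]), con)
    }
    for (i in seq_len(nrow(la))) {
      writeLines(pdb_atom_line("HETATM", nrow(pa) + i, la$name[i],
                               ligand_resname, "L", 1L, f[nrow(pa) + i, ],
                               la$element[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

pdb_atom_line <- function(type, serial, name, resid, chain, resno, xyz, element) {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else substr(name, 1L, 4L)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          type, serial %% 100000L, name4, substr(resid, 1L, 3L), chain, resno,
          xyz[1L], xyz[2L], xyz[3L], toupper(element))
}

#' Read a TRIPOS MOL2 file
#'
#' @param path file path (TRIPOS dialect only).
#' @return a `molecular_graph`; aromatic ("ar"/"am") bond flags are trusted
#'   from the input.
#' @export
read_mol2 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- bio3d::read.mol2(path)
  atoms <- data.frame(
    element = sub("\\..*$", "", m$atom$elety),
    x = m$atom$x, y = m$atom$y, z = m$atom$z,
    name = m$atom$elena, stringsAsFactors = FALSE)
  bonds <- NULL
  if (!is.null(m$bond) && nrow(m$bond)) {
    bonds <- data.frame(i = as.integer(m$bond$origin),
                        j = as.integer(m$bond$target),
                        order = normalize_bond_order(m$bond$type))
  }
  nm <- if (!is.null(m$info) && is.character(m$info) && nzchar(m$info[1L]))
    m$info[1L] else basename(path)
  molecular_graph(id = nm, atoms = atoms, bonds = bonds)
}
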