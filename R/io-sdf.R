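# SDF (V2000) reading and writing.
#
# Parsing of the counts/atom/bond/data blocks is delegated to ChemmineR;
# formal charges are supplemented from the raw "M  CHG" lines, which
# ChemmineR's reader drops.  The writer is a small fixed-format formatter so
# that charges and the property block round-trip losslessly.  Aromatic bonds
# use SDF bond type 4 and are trusted from the input flags (no re-perception).

#' Read an SDF (V2000) file
#'
#' @param path file path.
#' @return list of `molecular_graph`, one per record; coordinates are kept to
#'   input precision and the property (data) block is retained in
#'   `$properties`.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  raw_records <- split_sdf_records(lines)
  counts_all <- lapply(seq_along(raw_records), function(r) {
    tryCatch(sdf_counts_line(raw_records[[r]]),
             error = function(e)
               stop(sprintf("malformed counts line in SDF record %d", r),
                    call. = FALSE))
  })
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  out <- vector("list", length(sdfset))
  for (r in seq_along(sdfset)) {
    sdf <- sdfset[[r]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    counts <- counts_all[[r]]
    if (nrow(ab) != counts[1L] || nrow(as.data.frame(bb)) != counts[2L])
      stop(sprintf("malformed counts line in SDF record %d", r))
    element <- sub("_\\d+$", "", rownames(ab))
    atoms <- data.frame(element = element,
                        x = ab[, 1L], y = ab[, 2L], z = ab[, 3L],
                        formal_charge = sdf_charges(raw_records[[r]], nrow(ab)),
                        stringsAsFactors = FALSE)
    bonds <- NULL
    if (counts[2L] > 0L) {
      bb <- as.data.frame(bb)
      bonds <- data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                          order = normalize_bond_order(bb[, 3L]))
    }
    props <- as.list(ChemmineR::datablock(sdf))
    id <- trimws(ChemmineR::header(sdf)[["Molecule_Name"]])
    if (!nzchar(id)) id <- sprintf("record_%d", r)
    out[[r]] <- molecular_graph(id, atoms, bonds, props)
  }
  out
}

split_sdf_records <- function(lines) {
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

sdf_counts_line <- function(record) {
  line <- record[4L]
  na <- suppressWarnings(as.integer(substr(line, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(line, 4L, 6L)))
  if (is.na(na) || is.na(nb)) stop("malformed counts line")
  c(na, nb)
}

# formal charges from "M  CHG" lines (count, then index/charge pairs)
sdf_charges <- function(record, n_atoms) {
  charge <- rep(0L, n_atoms)
  for (line in grep("^M  CHG", record, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substring(line, 7L)), "\\s+")[[1L]])
    nent <- toks[1L]
    for (k in seq_len(nent)) {
      charge[toks[2L * k]] <- toks[2L * k + 1L]
    }
  }
  charge
}

#' Write molecular graphs to an SDF (V2000) file
#'
#' @param graphs a `molecular_graph` or list of them.
#' @param path output file path.
#' @export
write_sdf <- function(graphs, path) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in graphs) {
    writeLines(c(g$id, "  consdock", ""), con)
    na <- n_atoms(g); nb <- nrow(g$bonds)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    xyz <- graph_coords(g)
    xyz[is.na(xyz)] <- 0
    for (i in seq_len(na)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         xyz[i, 1L], xyz[i, 2L], xyz[i, 3L], g$atoms$element[i]),
                 con)
    }
    ordnum <- vapply(g$bonds$order,
                     function(o) if (o == "ar") 4L else as.integer(o), 0L)
    for (k in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0", g$bonds$i[k], g$bonds$j[k], ordnum[k]),
                 con)
    }
    chg <- which(g$atoms$formal_charge != 0L)
    for (s in split(chg, ceiling(seq_along(chg) / 8))) {
      writeLines(paste0(sprintf("M  CHG%3d", length(s)),
                        paste0(sprintf("%4d%4d", s, g$atoms$formal_charge[s]),
                               collapse = "")), con)
    }
    writeLines("M  END", con)
    for (nm in names(g$properties)) {
      writeLines(c(sprintf(">  <%s>", nm), as.character(g$properties[[nm]]), ""),
                 con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Write a pose ensemble to SDF with per-record program tags
#'
#' Each record carries its generating method in a `program` property (and a
#' `score` property when present), the exchange convention used by the
#' consensus stage.
#'
#' @param ensemble a `pose_ensemble`.
#' @param path output file path.
#' @export
write_ensemble_sdf <- function(ensemble, path) {
  graphs <- lapply(ensemble$poses, function(p) {
    g <- p$ligand
    g$properties$program <- p$program
    if (!is.na(p$score)) g$properties$score <- format(p$score)
    g
  })
  write_sdf(graphs, path)
}

#' Read a pose ensemble from a multi-record SDF
#'
#' @param path SDF written with one `program` property per record.
#' @export
read_ensemble_sdf <- function(path) {
  graphs <- read_sdf(path)
  poses <- lapply(graphs, function(g) {
    prog <- g$properties$program
    if (is.null(prog)) stop("record without a program property: ", g$id)
    score <- if (is.null(g$properties$score)) NA_real_ else
      as.numeric(g$properties$score)
    g$properties$program <- NULL
    g$properties$score <- NULL
    pose(g, program = as.character(prog), score = score)
  })
  pose_ensemble(poses)
}
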