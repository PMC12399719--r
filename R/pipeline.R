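# Pipeline configuration and the end-to-end driver chaining the screening
# stages: substructure prescreen -> shape filter -> hierarchical H-bond
# filter -> consensus clustering/selection.  Defaults mirror the published
# campaign's values (0.65 shape Tanimoto, 3.5 A / 120 deg hydrogen bonds,
# 2.0 A cluster cutoff, consensus level 9, stride 10, max 5 clusters).

PIPELINE_DEFAULTS <- list(
  smarts = "C(=O)[O;H1,-]",
  shape_threshold = 0.65,
  shape_align = "principal_axes",
  hbond_dmax = 3.5,
  hbond_amin = 120,
  required_residues = "A:313,A:314",
  cluster_cutoff = 2.0,
  min_level = 9,
  stride = 10,
  max_clusters = 5,
  seed = 1
)

#' Build a pipeline configuration
#'
#' Defaults follow the screening campaign's stated values; overrides come
#' from a plain `key = value` text file and/or named arguments (arguments
#' win).  Unknown keys are rejected before anything runs.
#'
#' @param path optional config file (`key = value` lines, `#` comments).
#' @param ... named overrides of the same keys.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- PIPELINE_DEFAULTS
  apply_over <- function(cfg, over) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (k in names(over)) {
      v <- over[[k]]
      if (is.character(cfg[[k]])) cfg[[k]] <- as.character(v)
      else cfg[[k]] <- as.numeric(v)
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines)]
    kv <- lapply(strsplit(lines, "=", fixed = TRUE), trimws)
    over <- stats::setNames(lapply(kv, function(x)
      paste(x[-1L], collapse = "=")), vapply(kv, `[[`, "", 1L))
    cfg <- apply_over(cfg, over)
  }
  cfg <- apply_over(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}

config_residues <- function(cfg) {
  as.list(strsplit(cfg$required_residues, ",")[[1L]])
}

#' Run the screening pipeline
#'
#' Executes, in order, the stages for which inputs are supplied: SMARTS
#' substructure prescreen and shape filter (needs `library` and `query`),
#' hierarchical H-bond filter (needs `stage_poses` and `protein`), and
#' consensus clustering/selection (needs `ensembles`).  Residual percentages
#' are reported against the first stage's input.  Reports are written as TSV
#' under `out_dir` along with the resolved configuration.
#'
#' @param config a [pipeline_config()].
#' @param library named list of `molecular_graph`s to screen.
#' @param query query molecule for the shape filter.
#' @param stage_poses named list of stages for [hierarchical_filter()].
#' @param protein receptor for the H-bond filter.
#' @param ensembles named list of `pose_ensemble`s for consensus analysis.
#' @param out_dir output directory (created); `NULL` writes nothing.
#' @return list with `stage_reports`, `survivors`, `consensus` (per-ligand
#'   level table + histogram + selection), and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), library = NULL,
                         query = NULL, stage_poses = NULL, protein = NULL,
                         ensembles = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  reports <- NULL
  survivors <- list()
  n_initial <- NULL
  note_stage <- function(stage, n_in, n_out) {
    if (is.null(n_initial)) n_initial <<- n_in
    reports <<- rbind(reports, stage_table(stage, n_in, n_out,
                                           max(n_initial, 1L)))
  }
  if (!is.null(library)) {
    ids <- names(library)
    if (is.null(ids))
      ids <- vapply(library, function(g) g$id, "")
    names(library) <- ids
    hits <- vapply(library, function(g)
      length(match_substructure(g, config$smarts)) > 0L, TRUE)
    note_stage("substructure", length(library), sum(hits))
    survivors$substructure <- ids[hits]
    library <- library[hits]
    if (!is.null(query) && length(library)) {
      fs <- filter_by_shape(library, query, threshold = config$shape_threshold,
                            align = config$shape_align)
      note_stage("shape_tanimoto", length(library), length(fs$survivors))
      survivors$shape <- fs$survivors
    } else if (!is.null(query)) {
      note_stage("shape_tanimoto", 0L, 0L)
      survivors$shape <- character()
    }
  }
  if (!is.null(stage_poses) && !is.null(protein)) {
    hf <- hierarchical_filter(
      stage_poses, protein, required_residues = config_residues(config),
      criteria = hbond_criteria(config$hbond_dmax, config$hbond_amin))
    if (is.null(n_initial)) n_initial <- hf$reports$n_in[1L]
    hf$reports$residual_pct <- residual_percentage(hf$reports$n_out, n_initial)
    reports <- rbind(reports, hf$reports)
    survivors <- c(survivors, hf$survivors)
  }
  consensus <- NULL
  if (!is.null(ensembles) && length(ensembles)) {
    levels <- vapply(ensembles, function(e) {
      cl <- complete_linkage(rmsd_matrix(e), cutoff = config$cluster_cutoff)
      consensus_level(cl)$level
    }, 0L)
    nprog <- max(vapply(ensembles, function(e) length(e$poses), 0L))
    consensus <- select_by_consensus(levels, min_level = config$min_level,
                                     n_programs = nprog)
    note_stage("consensus", length(ensembles), length(consensus$selected))
    survivors$consensus <- consensus$selected
  }
  out <- list(stage_reports = reports, survivors = survivors,
              consensus = consensus, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(utils::capture.output(print(config)),
               file.path(out_dir, "config.txt"))
    if (!is.null(reports))
      utils::write.table(reports, file.path(out_dir, "stage_reports.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(consensus)) {
      utils::write.table(consensus$table,
                         file.path(out_dir, "consensus_levels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(consensus$histogram,
                         file.path(out_dir, "consensus_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
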