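# Hierarchical post-docking filtering: stage bookkeeping and the driver that
# retains compounds whose top-ranked pose hydrogen-bonds to required
# catalytic residues (C313/C314 in the ALDH1A3 campaign).

#' One row of a stage report
#'
#' The residual percentage is computed against the pipeline's first-stage
#' input (`n_initial`), not the stage's own input, and is rounded to two
#' decimals with round-half-even.
#'
#' @param stage stage name.
#' @param n_in compounds entering the stage.
#' @param n_out compounds surviving the stage.
#' @param n_initial first-stage input size.
#' @export
stage_table <- function(stage, n_in, n_out, n_initial) {
  stopifnot(length(stage) == length(n_in), length(n_in) == length(n_out),
            all(n_out >= 0), all(n_out <= n_in), all(n_initial > 0))
  data.frame(stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
             residual_pct = residual_percentage(n_out, n_initial),
             stringsAsFactors = FALSE)
}

#' Residual percentage of a filtering stage
#'
#' `100 * n_out / n_initial`, rounded to two decimals (round-half-even).
#'
#' @param n_out surviving count.
#' @param n_initial first-stage input count.
#' @export
residual_percentage <- function(n_out, n_initial) {
  round(100 * n_out / n_initial, 2)
}

#' Hierarchical H-bond pose filter across docking stages
#'
#' Each stage supplies one top-ranked pose per compound still alive.  A
#' compound survives a stage iff its pose forms at least one hydrogen bond
#' with any required residue.  Stages must be nested: a compound appearing in
#' stage k+1 must have survived stage k.
#'
#' @param stage_poses named list of stages; each stage is a named list of
#'   `pose` objects keyed by compound id.
#' @param protein a `protein_structure`.
#' @param required_residues residues any one of which must accept/donate,
#'   as `"A:313"` strings or `c(chain, resno)` pairs.
#' @param criteria an [hbond_criteria()].
#' @return list with `reports` (stage report data.frame) and `survivors`
#'   (named list of surviving compound ids per stage).
#' @export
hierarchical_filter <- function(stage_poses, protein,
                                required_residues = list("A:313", "A:314"),
                                criteria = hbond_criteria()) {
  stopifnot(is.list(stage_poses), length(stage_poses) >= 1L)
  stage_names <- names(stage_poses)
  if (is.null(stage_names))
    stage_names <- paste0("stage", seq_along(stage_poses))
  n_initial <- length(stage_poses[[1L]])
  survivors <- vector("list", length(stage_poses))
  names(survivors) <- stage_names
  reports <- NULL
  prev <- NULL
  for (s in seq_along(stage_poses)) {
    poses <- stage_poses[[s]]
    ids <- names(poses)
    if (is.null(ids)) stop("stage ", stage_names[s], " poses must be named")
    if (!is.null(prev)) {
      orphan <- setdiff(ids, prev)
      if (length(orphan))
        stop("compound(s) ", paste(orphan, collapse = ", "), " enter stage ",
             stage_names[s], " without surviving the previous stage")
    }
    ok <- vapply(poses, function(p) {
      nrow(detect_hbonds(p, protein, criteria,
                         residue_filter = required_residues)) > 0L
    }, TRUE)
    survivors[[s]] <- ids[ok]
    reports <- rbind(reports, stage_table(stage_names[s], length(ids),
                                          sum(ok), n_initial))
    prev <- survivors[[s]]
  }
  list(reports = reports, survivors = survivors)
}
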