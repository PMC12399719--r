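# Rule-based drug-likeness range checks (Lipinski Rule of Five by default).

#' Default Rule-of-Five rule set
#'
#' MW <= 500, logP <= 5, H-bond donors <= 5, H-bond acceptors <= 10.
#'
#' @return data.frame with columns `descriptor`, `min`, `max`.
#' @export
ro5_rules <- function() {
  data.frame(descriptor = c("mw", "logp", "hbd", "hba"),
             min = c(0, -Inf, 0, 0),
             max = c(500, 5, 5, 10),
             stringsAsFactors = FALSE)
}

#' Build a custom drug-likeness rule
#' @param descriptor descriptor column name.
#' @param min,max inclusive range (min <= max).
#' @export
druglike_rule <- function(descriptor, min = -Inf, max = Inf) {
  stopifnot(min <= max)
  data.frame(descriptor = descriptor, min = min, max = max,
             stringsAsFactors = FALSE)
}

#' Check compounds against drug-likeness rules
#'
#' A compound passes iff every rule's descriptor lies inside the rule's
#' (inclusive) range.  Descriptor values are user-supplied (e.g. from a
#' property-prediction tool) or computed with [basic_descriptors()].
#'
#' @param descriptors data.frame with a `compound` column plus one numeric
#'   column per descriptor named in the rules.
#' @param rules data.frame as returned by [ro5_rules()].
#' @return data.frame with columns `compound`, `pass`, `violations` (comma
#'   separated rule descriptors, empty when passing).
#' @export
druglike_check <- function(descriptors, rules = ro5_rules()) {
  descriptors <- as.data.frame(descriptors, stringsAsFactors = FALSE)
  if (!"compound" %in% names(descriptors))
    stop("descriptor table needs a 'compound' column")
  missing_cols <- setdiff(rules$descriptor, names(descriptors))
  if (length(missing_cols))
    stop("missing descriptor(s) ", paste(missing_cols, collapse = ", "),
         " for all compounds")
  out <- data.frame(compound = descriptors$compound, pass = TRUE,
                    violations = "", stringsAsFactors = FALSE)
  for (r in seq_len(nrow(rules))) {
    d <- rules$descriptor[r]
    v <- descriptors[[d]]
    if (any(is.na(v)))
      stop(sprintf("missing descriptor '%s' for compound %s", d,
                   paste(descriptors$compound[is.na(v)], collapse = ", ")))
    bad <- v < rules$min[r] | v > rules$max[r]
    out$pass[bad] <- FALSE
    out$violations[bad] <- ifelse(nzchar(out$violations[bad]),
                                  paste0(out$violations[bad], ",", d), d)
  }
  out
}

# crude atom-additive logP increments; a toy estimate, not a prediction model
.LOGP_INC <- c(C = 0.27, N = -0.55, O = -0.25, S = 0.35, P = -0.4,
               F = 0.22, Cl = 0.65, Br = 0.86, I = 1.1, H = 0, B = 0.1)

#' Basic descriptors computed from a molecular graph
#'
#' Molecular weight, explicit H-bond donor count (N/O/S bearing at least one
#' explicit hydrogen), acceptor count (N + O), and a crude atom-additive logP
#' estimate.  The logP value is a screening-grade estimate only; supply
#' externally computed values to [druglike_check()] when available.
#'
#' @param graph a `molecular_graph` (or list of them).
#' @param compound id used in the output (defaults to the graph id).
#' @return one-row data.frame with columns `compound`, `mw`, `logp`, `hbd`,
#'   `hba`.
#' @export
basic_descriptors <- function(graph, compound = NULL) {
  if (is.list(graph) && !inherits(graph, "molecular_graph"))
    return(do.call(rbind, lapply(graph, basic_descriptors)))
  el <- graph$atoms$element
  mw <- sum(.ATOMIC_MASS[el])
  donors <- sum(vapply(which(el %in% c("N", "O", "S")),
                       function(i) length(attached_hydrogens(graph, i)) > 0L,
                       TRUE))
  data.frame(compound = compound %||% graph$id,
             mw = unname(mw),
             logp = unname(sum(.LOGP_INC[el], na.rm = TRUE)),
             hbd = donors,
             hba = sum(el %in% c("N", "O")),
             stringsAsFactors = FALSE)
}
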