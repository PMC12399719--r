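# Substructure matching with a restricted SMARTS dialect.
#
# Supported: organic-subset atoms (B C N O P S F Cl Br I, uppercase =
# aliphatic), aromatic lowercase (c n o p s), wildcard *, bracket atoms with
# element / aromatic / Hn (explicit-hydrogen count) / +n / -n primitives
# combined with ',' (OR, binds tighter) and ';' or '&' (AND), bonds
# - = # : ~ (default: single-or-aromatic), branches, and ring closures 1-9.
# Query atoms match heavy atoms only; hydrogen counts refer to explicit
# hydrogens since the package never adds hydrogens implicitly.
#
# An atom is considered aromatic iff it participates in at least one bond
# flagged aromatic in the input (no re-perception).

#' Find all embeddings of a SMARTS pattern in a molecular graph
#'
#' @param graph a `molecular_graph`.
#' @param pattern SMARTS string (restricted dialect, see Details).
#' @return list of integer vectors, one per distinct embedding; each vector
#'   gives the (1-based) target atom index matched by each pattern atom, in
#'   pattern order.  Empty list when there is no match.
#' @export
match_substructure <- function(graph, pattern) {
  q <- parse_smarts(pattern)
  target <- smarts_target(graph)
  if (length(q$atoms) == 0L) return(list())
  embed_query(q, target)
}

smarts_target <- function(graph) {
  hv <- heavy_atoms(graph)
  aromatic <- rep(FALSE, n_atoms(graph))
  b <- graph$bonds
  if (nrow(b)) {
    ar <- b$order == "ar"
    aromatic[unique(c(b$i[ar], b$j[ar]))] <- TRUE
  }
  hcount <- vapply(seq_len(n_atoms(graph)),
                   function(i) length(attached_hydrogens(graph, i)), 0L)
  # heavy-atom adjacency with bond orders
  adj <- rep(list(integer()), n_atoms(graph))
  bond_order <- list()
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (graph$atoms$element[i] == "H" || graph$atoms$element[j] == "H") next
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    bond_order[[paste(min(i, j), max(i, j))]] <- b$order[k]
  }
  list(element = graph$atoms$element, charge = graph$atoms$formal_charge,
       aromatic = aromatic, hcount = hcount, heavy = hv, adj = adj,
       bond_order = bond_order)
}

# ---- parser ---------------------------------------------------------------

parse_smarts <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  chars <- strsplit(pattern, "")[[1L]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()  # list of (i, j, spec)
  stack <- integer()
  prev <- NA_integer_
  pending_bond <- NULL
  ring_open <- list()
  pos <- 1L
  err <- function(msg) stop(sprintf("invalid SMARTS '%s': %s", pattern, msg))
  add_atom <- function(spec) {
    atoms[[length(atoms) + 1L]] <<- spec
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx,
                                           spec = pending_bond %||% "default")
    }
    pending_bond <<- NULL
    prev <<- idx
  }
  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "(") {
      if (is.na(prev)) err("branch before any atom")
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) err("unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending_bond <- ch; pos <- pos + 1L
    } else if (grepl("[1-9]", ch)) {
      if (is.na(prev)) err("ring closure before any atom")
      if (!is.null(ring_open[[ch]])) {
        op <- ring_open[[ch]]
        spec <- op$bond %||% pending_bond %||% "default"
        bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev, spec = spec)
        ring_open[[ch]] <- NULL
      } else {
        ring_open[[ch]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- NULL; pos <- pos + 1L
    } else if (ch == "[") {
      close <- pos
      while (close <= n && chars[close] != "]") close <- close + 1L
      if (close > n) err("unterminated bracket atom")
      add_atom(parse_bracket(paste(chars[(pos + 1L):(close - 1L)],
                                   collapse = ""), err))
      pos <- close + 1L
    } else if (ch == "*") {
      add_atom(list(list(list(kind = "any"))))
      pos <- pos + 1L
    } else {
      two <- if (pos < n) paste0(ch, chars[pos + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(atom_spec_element(two, aromatic = FALSE))
        pos <- pos + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(atom_spec_element(ch, aromatic = FALSE))
        pos <- pos + 1L
      } else if (ch %in% c("c", "n", "o", "p", "s")) {
        add_atom(atom_spec_element(toupper(ch), aromatic = TRUE))
        pos <- pos + 1L
      } else {
        err(sprintf("unsupported token '%s' at position %d", ch, pos))
      }
    }
  }
  if (length(stack)) err("unbalanced '('")
  if (length(ring_open) && any(!vapply(ring_open, is.null, TRUE)))
    err("unclosed ring bond")
  if (!length(atoms)) err("empty pattern")
  list(atoms = atoms, bonds = bonds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atom_spec_element <- function(el, aromatic) {
  # one AND-term with one alternative
  list(list(list(kind = "element", value = el, aromatic = aromatic)))
}

# bracket body -> list of AND-terms, each a list of OR-alternatives
parse_bracket <- function(body, err) {
  if (!nzchar(body)) err("empty bracket atom")
  terms <- strsplit(body, "[;&]")[[1L]]
  lapply(terms, function(term) {
    alts <- strsplit(term, ",")[[1L]]
    lapply(alts, function(a) parse_primitive(a, err))
  })
}

parse_primitive <- function(tok, err) {
  if (tok == "*") return(list(kind = "any"))
  if (grepl("^H[0-9]?$", tok)) {
    return(list(kind = "hcount",
                value = if (nchar(tok) == 1L) 1L else
                  as.integer(substring(tok, 2L))))
  }
  if (grepl("^[+-][0-9]?$", tok)) {
    mag <- if (nchar(tok) == 1L) 1L else as.integer(substring(tok, 2L))
    return(list(kind = "charge",
                value = if (substring(tok, 1L, 1L) == "+") mag else -mag))
  }
  if (grepl("^[A-Z][a-z]?$", tok) && tok %in% .ELEMENTS)
    return(list(kind = "element", value = tok, aromatic = FALSE))
  if (grepl("^[a-z]$", tok) && toupper(tok) %in% .ELEMENTS)
    return(list(kind = "element", value = toupper(tok), aromatic = TRUE))
  err(sprintf("unsupported primitive '%s'", tok))
}

# ---- matcher --------------------------------------------------------------

atom_matches <- function(spec, target, i) {
  for (term in spec) {
    ok <- FALSE
    for (alt in term) {
      ok <- switch(alt$kind,
        any     = TRUE,
        element = target$element[i] == alt$value &&
                  target$aromatic[i] == alt$aromatic,
        hcount  = target$hcount[i] == alt$value,
        charge  = target$charge[i] == alt$value)
      if (ok) break
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

bond_matches <- function(spec, order) {
  switch(spec,
         default = order %in% c("1", "ar"),
         "-" = order == "1",
         "=" = order == "2",
         "#" = order == "3",
         ":" = order == "ar",
         "~" = TRUE)
}

embed_query <- function(q, target) {
  nq <- length(q$atoms)
  # adjacency of the query, with bond specs
  qadj <- rep(list(integer()), nq)
  qbond <- list()
  for (b in q$bonds) {
    qadj[[b$i]] <- c(qadj[[b$i]], b$j); qadj[[b$j]] <- c(qadj[[b$j]], b$i)
    qbond[[paste(min(b$i, b$j), max(b$i, b$j))]] <- b$spec
  }
  results <- list()
  map <- rep(NA_integer_, nq)
  used <- rep(FALSE, length(target$element))
  consistent <- function(qi, ti) {
    if (!atom_matches(q$atoms[[qi]], target, ti)) return(FALSE)
    for (qn in qadj[[qi]]) {
      tn <- map[qn]
      if (is.na(tn)) next
      ord <- target$bond_order[[paste(min(ti, tn), max(ti, tn))]]
      if (is.null(ord)) return(FALSE)
      if (!bond_matches(qbond[[paste(min(qi, qn), max(qi, qn))]], ord))
        return(FALSE)
    }
    TRUE
  }
  recurse <- function(k) {
    if (k > nq) {
      results[[length(results) + 1L]] <<- map
      return(invisible())
    }
    # candidates: neighbors of an already-mapped query neighbor, else all
    mapped_nb <- qadj[[k]][!is.na(map[qadj[[k]]])]
    cand <- if (length(mapped_nb)) target$adj[[map[mapped_nb[1L]]]]
            else target$heavy
    for (ti in cand) {
      if (used[ti] || target$element[ti] == "H") next
      if (!consistent(k, ti)) next
      map[k] <<- ti; used[ti] <<- TRUE
      recurse(k + 1L)
      map[k] <<- NA_integer_; used[ti] <<- FALSE
    }
  }
  recurse(1L)
  results
}
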