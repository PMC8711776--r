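#' Parse an OBO 1.2 ontology
#'
#' Minimal reader for the Gene Ontology OBO flat file: records every `[Term]`
#' stanza's identifier, name, namespace, `is_a` and `relationship: part_of`
#' parents, obsolescence flag and `alt_id`s. Both `is_a` and `part_of` are
#' treated as subsumption edges for ancestor propagation, the convention of
#' information-content based similarity measures.
#'
#' @param path Path to an OBO file.
#' @return An `ontology_dag`: list with
#'   * `terms`: tibble (`term`, `name`, `namespace`, `obsolete`),
#'   * `parents`: named list term -> character vector of parent terms,
#'   * `alt_id`: named character vector mapping alternate to primary ids.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) abort(sprintf("No [Term] stanzas in %s", path))
  bounds <- c(starts, length(lines) + 1L)
  stanza_field <- function(block, key) {
    hit <- grepl(paste0("^", key, ":"), block)
    trimws(sub("!.*$", "", sub(paste0("^", key, ":\\s*"), "", block[hit])))
  }
  recs <- lapply(seq_along(starts), function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    stop_at <- grep("^\\[", block)  # next non-Term stanza, e.g. [Typedef]
    if (length(stop_at)) block <- block[seq_len(stop_at[1] - 1L)]
    id <- stanza_field(block, "id")[1]
    obsolete <- any(stanza_field(block, "is_obsolete") == "true")
    isa <- sub("\\s.*$", "", stanza_field(block, "is_a"))
    rel <- stanza_field(block, "relationship")
    partof <- sub("^part_of\\s+", "",
                  rel[grepl("^part_of\\s", rel)])
    partof <- sub("\\s.*$", "", partof)
    list(
      term = id,
      name = stanza_field(block, "name")[1] %||% NA_character_,
      namespace = stanza_field(block, "namespace")[1] %||% NA_character_,
      obsolete = obsolete,
      parents = if (obsolete) character() else unique(c(isa, partof)),
      alt_id = stanza_field(block, "alt_id")
    )
  })
  terms <- tibble(
    term = vapply(recs, `[[`, character(1), "term"),
    name = vapply(recs, function(r) r$name %||% NA_character_, character(1)),
    namespace = vapply(recs, function(r) r$namespace %||% NA_character_,
                       character(1)),
    obsolete = vapply(recs, `[[`, logical(1), "obsolete")
  )
  if (anyDuplicated(terms$term)) {
    abort("Duplicate term ids in OBO file.")
  }
  parents <- setNames(lapply(recs, `[[`, "parents"), terms$term)
  alt_pairs <- lapply(recs, function(r) {
    if (length(r$alt_id)) setNames(rep(r$term, length(r$alt_id)), r$alt_id)
  })
  alt_id <- unlist(alt_pairs) %||% setNames(character(), character())
  unknown <- setdiff(unique(unlist(parents)), terms$term)
  if (length(unknown)) {
    abort(sprintf("OBO references unknown parent term(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  dag <- structure(list(terms = terms, parents = parents, alt_id = alt_id),
                   class = "ontology_dag")
  validate_acyclic(dag)
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms (%d obsolete), namespaces: %s\n",
              nrow(x$terms), sum(x$terms$obsolete),
              paste(sort(unique(stats::na.omit(x$terms$namespace))),
                    collapse = ", ")))
  invisible(x)
}

# Kahn topological check: every term must be emitted, else there is a cycle.
validate_acyclic <- function(dag) {
  indeg <- lengths(dag$parents)
  children <- split(
    rep(names(dag$parents), lengths(dag$parents)),
    factor(unlist(dag$parents), levels = dag$terms$term)
  )
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < nrow(dag$terms)) abort("Ontology parent graph contains a cycle.")
  invisible(dag)
}

#' All ancestors of a term
#'
#' Transitive closure over `is_a`/`part_of` parents, excluding the term
#' itself.
#'
#' @param dag An `ontology_dag`.
#' @param term Term identifier.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
term_ancestors <- function(dag, term) {
  if (!term %in% names(dag$parents)) {
    abort(sprintf("Unknown term `%s`.", term))
  }
  out <- character()
  frontier <- dag$parents[[term]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), out)
  }
  sort(out)
}

#' Resolve a term id through the alt_id table
#'
#' @param dag An `ontology_dag`.
#' @param terms Character vector of term ids.
#' @return Character vector with alternate ids replaced by primary ids;
#'   ids unknown to the ontology are returned unchanged.
#' @export
resolve_terms <- function(dag, terms) {
  hit <- terms %in% names(dag$alt_id)
  terms[hit] <- unname(dag$alt_id[terms[hit]])
  terms
}
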