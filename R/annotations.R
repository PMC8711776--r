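#' Parse a GAF 2.x annotation file
#'
#' Reads a Gene Association File (tab-separated, 17 columns, `!` comments)
#' into a protein -> GO term map. Annotations whose qualifier contains `NOT`
#' are dropped (standard GAF semantics), alternate term ids are resolved to
#' primary ids, and annotations to obsolete terms are dropped with a warning.
#'
#' @param path Path to a GAF file.
#' @param ontology An `ontology_dag` from [parse_obo()].
#' @param id_column Column holding the protein identifier (default 2, the DB
#'   object id).
#' @param exclude_evidence Optional character vector of evidence codes to
#'   drop (e.g. `"IEA"`). No evidence filtering by default.
#' @param namespace Optional single namespace (`"biological_process"`,
#'   `"molecular_function"` or `"cellular_component"`) to restrict to; by
#'   default all three are pooled.
#' @return An `annotation_map`: list with `direct` (named list
#'   protein -> character vector of term ids) and `propagated` (`NULL` until
#'   [propagate_annotations()] is called).
#' @export
parse_gaf <- function(path, ontology, id_column = 2L,
                      exclude_evidence = character(),
                      namespace = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) abort(sprintf("No annotation lines in %s", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15)) {
    bad <- idx[which(nf < 15)[1]]
    abort(sprintf("Malformed GAF line %d in %s: expected >= 15 columns, got %d.",
                  bad, path, nf[which(nf < 15)[1]]))
  }
  protein <- vapply(fields, `[[`, character(1), id_column)
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  term <- vapply(fields, `[[`, character(1), 5L)
  evidence <- vapply(fields, `[[`, character(1), 7L)

  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  if (length(exclude_evidence)) keep <- keep & !(evidence %in% exclude_evidence)
  protein <- protein[keep]; term <- term[keep]

  term <- resolve_terms(ontology, term)
  known <- term %in% ontology$terms$term
  if (any(!known)) {
    warn(sprintf("Dropped %d annotation(s) to terms absent from the ontology.",
                 sum(!known)))
    protein <- protein[known]; term <- term[known]
  }
  obs <- ontology$terms$term[ontology$terms$obsolete]
  is_obs <- term %in% obs
  if (any(is_obs)) {
    warn(sprintf("Dropped %d annotation(s) to obsolete terms.", sum(is_obs)))
    protein <- protein[!is_obs]; term <- term[!is_obs]
  }
  if (!is.null(namespace)) {
    ns <- setNames(ontology$terms$namespace, ontology$terms$term)
    in_ns <- ns[term] == namespace
    protein <- protein[in_ns]; term <- term[in_ns]
  }
  direct <- lapply(split(term, protein), function(x) sort(unique(x)))
  annotation_map(direct)
}

#' Construct an annotation map
#'
#' @param direct Named list: protein -> character vector of term ids.
#' @param propagated Optional named list of ancestor-closed term sets.
#' @return An `annotation_map` object.
#' @export
annotation_map <- function(direct, propagated = NULL) {
  stopifnot(is.list(direct))
  structure(list(direct = direct, propagated = propagated),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d proteins, %d direct annotations%s\n",
              length(x$direct), sum(lengths(x$direct)),
              if (is.null(x$propagated)) "" else
                sprintf(", %d after propagation", sum(lengths(x$propagated)))))
  invisible(x)
}

#' Propagate annotations up the ontology
#'
#' Fills the `propagated` slot with the ancestor closure of every protein's
#' direct term set (transitive `is_a`/`part_of`). Information-content based
#' similarity measures of the GIC family are defined on these closed sets.
#'
#' @param annotations An `annotation_map`.
#' @param ontology An `ontology_dag`.
#' @return The `annotation_map` with `propagated` filled.
#' @export
propagate_annotations <- function(annotations, ontology) {
  stopifnot(inherits(annotations, "annotation_map"))
  anc_cache <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (is.null(anc_cache[[t]])) anc_cache[[t]] <- term_ancestors(ontology, t)
    anc_cache[[t]]
  }
  annotations$propagated <- lapply(annotations$direct, function(terms) {
    sort(unique(c(terms, unlist(lapply(terms, anc), use.names = FALSE))))
  })
  annotations
}

annotation_sets <- function(annotations, use_propagated = TRUE) {
  if (use_propagated && !is.null(annotations$propagated)) {
    annotations$propagated
  } else {
    annotations$direct
  }
}

#' Term frequencies and information content
#'
#' Counts how often every term occurs across the annotation corpus (one
#' occurrence per protein-term pair) and converts frequencies to information
#' content: `p(T) = count(T) / N` with `N` the total number of annotation
#' occurrences, and `ic(T) = -log p(T)`. A term annotating every occurrence
#' slot is maximally general and carries zero information.
#'
#' @param annotations An `annotation_map`.
#' @param use_propagated Count over the ancestor-closed sets (default) or the
#'   direct sets.
#' @return An `ic_table`: list with a `table` tibble (`term`, `count`, `p`,
#'   `ic`) and the scalar `total`.
#' @export
term_frequencies <- function(annotations, use_propagated = TRUE) {
  sets <- annotation_sets(annotations, use_propagated)
  occ <- unlist(sets, use.names = FALSE)
  if (length(occ) == 0) abort("Annotation corpus is empty.")
  counts <- table(occ)
  total <- sum(counts)
  tab <- tibble(
    term = names(counts),
    count = as.integer(counts),
    p = as.integer(counts) / total,
    ic = -log(as.integer(counts) / total)
  )
  structure(list(table = tab, total = total,
                 ic = setNames(tab$ic, tab$term)),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("<ic_table> %d terms over %d annotation occurrences\n",
              nrow(x$table), x$total))
  invisible(x)
}

#' @rdname term_frequencies
#' @param x An `ic_table`.
#' @param ... Unused.
#' @export
tidy.ic_table <- function(x, ...) x$table

#' Write an information-content table as TSV
#'
#' @param x An `ic_table`.
#' @param path Output path; columns `term`, `count`, `ic`.
#' @return `path`, invisibly.
#' @export
write_ic_table <- function(x, path) {
  stopifnot(inherits(x, "ic_table"))
  writeLines(c("term\tcount\tic",
               sprintf("%s\t%d\t%.6f", x$table$term, x$table$count,
                       x$table$ic)), path)
  invisible(path)
}

#' Summed information content of a term set
#'
#' The information content of a set of terms is the sum of the member ICs:
#' a large, specific annotation profile carries more information than a
#' small or generic one.
#'
#' @param terms Character vector of term ids.
#' @param table An `ic_table`.
#' @return Non-negative scalar.
#' @export
set_ic <- function(terms, table) {
  stopifnot(inherits(table, "ic_table"))
  if (length(terms) == 0) return(0)
  unknown <- setdiff(terms, names(table$ic))
  if (length(unknown)) {
    abort(sprintf("Term(s) not in the information-content table: %s",
                  paste(unknown, collapse = ", ")))
  }
  sum(table$ic[terms])
}

# set_ic variant used inside similarity: terms never seen in the corpus have
# no defined IC and contribute zero (a -log 0 would otherwise dominate).
set_ic_lenient <- function(terms, ic) {
  if (length(terms) == 0) return(0)
  sum(ic[intersect(terms, names(ic))])
}

#' GO semantic similarity between two proteins
#'
#' Information-content overlap of the two proteins' (by default ancestor
#' propagated) annotation profiles:
#' `se(u, v) = sum(ic over A intersect B) / max(set_ic(A), set_ic(B))`.
#' The score is 1 for identical informative profiles, 0 for disjoint ones,
#' and 0 by convention when either protein is unannotated or both profiles
#' carry zero information.
#'
#' @param u,v Protein identifiers.
#' @param annotations An `annotation_map`.
#' @param table An `ic_table` (typically [term_frequencies()] on the same
#'   corpus).
#' @param use_propagated Use the ancestor-closed term sets (default).
#' @return A similarity in \[0, 1\]; symmetric in `u` and `v`.
#' @export
semantic_similarity <- function(u, v, annotations, table,
                                use_propagated = TRUE) {
  stopifnot(inherits(annotations, "annotation_map"),
            inherits(table, "ic_table"))
  sets <- annotation_sets(annotations, use_propagated)
  A <- sets[[u]]; B <- sets[[v]]
  if (is.null(A) || is.null(B)) return(0)
  ic <- table$ic
  denom <- max(set_ic_lenient(A, ic), set_ic_lenient(B, ic))
  if (denom <= 0) return(0)
  min(1, max(0, set_ic_lenient(intersect(A, B), ic) / denom))
}
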