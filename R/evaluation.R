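#' Match predicted complexes against a reference catalogue
#'
#' A predicted complex counts as matched when its best overlap ratio
#' ([complex_overlap()]) against any reference complex reaches
#' `ol_threshold`, and symmetrically for reference complexes; the two counts
#' differ in general and no one-to-one assignment is enforced. A perfect
#' match is an exactly identical member set (overlap ratio 1).
#'
#' @param predicted,reference `complex_set` objects; `reference` must be
#'   non-empty.
#' @param ol_threshold Overlap-ratio threshold in (0, 1\]. Default 0.2, the
#'   conventional operating point for complex matching.
#' @return Named list: `n_matched_predicted`, `n_matched_reference`,
#'   `perfect_matches` (predicted complexes identical to some reference
#'   complex).
#' @export
match_sets <- function(predicted, reference, ol_threshold = 0.2) {
  stopifnot(inherits(predicted, "complex_set"),
            inherits(reference, "complex_set"))
  if (length(reference) == 0) abort("Reference complex set is empty.")
  if (!is.numeric(ol_threshold) || ol_threshold <= 0 || ol_threshold > 1) {
    abort("`ol_threshold` must lie in (0, 1].")
  }
  if (length(predicted) == 0) {
    return(list(n_matched_predicted = 0L, n_matched_reference = 0L,
                perfect_matches = 0L))
  }
  ol <- matrix(0, nrow = length(predicted), ncol = length(reference))
  for (i in seq_along(predicted$complexes)) {
    for (j in seq_along(reference$complexes)) {
      ol[i, j] <- complex_overlap(predicted$complexes[[i]],
                                  reference$complexes[[j]])
    }
  }
  list(
    n_matched_predicted = sum(apply(ol, 1, max) >= ol_threshold),
    n_matched_reference = sum(apply(ol, 2, max) >= ol_threshold),
    perfect_matches = sum(apply(ol, 1, max) == 1)
  )
}

#' Recall, precision and F1 from matching counts
#'
#' Recall is the fraction of reference complexes recovered; precision is the
#' fraction of predictions that hit a reference complex; F1 is their
#' harmonic mean (0 when both are 0).
#'
#' @param n_matched_reference,n_reference Reference-side matched count and
#'   catalogue size.
#' @param n_matched_predicted,n_predicted Prediction-side matched count and
#'   catalogue size.
#' @return A one-row tibble with `recall`, `precision`, `f1`.
#' @export
recall_precision_f1 <- function(n_matched_reference, n_reference,
                                n_matched_predicted, n_predicted) {
  if (n_reference <= 0 || n_predicted <= 0) {
    abort("Reference and prediction counts must be positive.")
  }
  r <- n_matched_reference / n_reference
  p <- n_matched_predicted / n_predicted
  tibble(recall = r, precision = p, f1 = f1_score(r, p))
}

#' Harmonic mean of recall and precision
#'
#' `F1 = 2 * R * P / (R + P)`, and 0 when `R + P = 0`.
#'
#' @param recall,precision Values in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(recall, precision) {
  ifelse(recall + precision > 0,
         2 * recall * precision / (recall + precision), 0)
}

#' Catalogue size statistics
#'
#' @param predicted A `complex_set`.
#' @return A one-row tibble: `n_complexes`, `average_size` (0 for an empty
#'   catalogue), `coverage` (distinct proteins across all complexes).
#' @export
size_and_coverage <- function(predicted) {
  stopifnot(inherits(predicted, "complex_set"))
  n <- length(predicted)
  tibble(
    n_complexes = n,
    average_size = if (n == 0) 0 else mean(lengths(predicted$complexes)),
    coverage = length(unique(unlist(predicted$complexes)))
  )
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail over-representation probability: drawing a complex of size
#' `C_size` from a universe of `V_size` proteins of which `F_size` carry the
#' property of interest, the p-value is `P(X >= m)` for the hypergeometric
#' count `X` of property carriers in the draw — equivalently one minus the
#' cumulative sum up to `m - 1`. Computed through [stats::phyper()] (log-space
#' stable).
#'
#' @param m Observed number of carriers in the complex.
#' @param F_size Carriers in the universe.
#' @param V_size Universe size.
#' @param C_size Complex size.
#' @return A p-value in \[0, 1\] (1 when `m = 0`).
#' @export
hypergeometric_pvalue <- function(m, F_size, V_size, C_size) {
  if (m < 0 || F_size < 0 || C_size < 0 || V_size <= 0 ||
      F_size > V_size || C_size > V_size || m > min(F_size, C_size)) {
    abort("Invalid hypergeometric parameters: need 0 <= m <= min(F, C) and F, C <= V.")
  }
  if (m == 0) return(1)
  phyper(m - 1, F_size, V_size - F_size, C_size, lower.tail = FALSE)
}

#' Per-complex functional enrichment
#'
#' For every predicted complex and every term annotating at least one
#' member, tests over-representation of the term among the members with the
#' hypergeometric upper tail ([hypergeometric_pvalue()]); reports each
#' complex's best (minimum p-value) term. A complex with no annotated
#' member yields no test.
#'
#' @param predicted A `complex_set`.
#' @param annotations An `annotation_map` (propagated sets are used when
#'   available).
#' @param universe Optional character vector of protein identifiers (for
#'   example the nodes of the analysed network); annotations outside it are
#'   ignored and carrier counts are taken within it.
#' @param universe_size Number of proteins in the universe; defaults to
#'   `length(universe)` when a universe is given, otherwise to the number of
#'   annotated proteins. Must be at least the number of annotated proteins
#'   considered (raised with a warning if not).
#' @param alpha Significance cutoff on the raw p-value. Default 0.01.
#' @param adjust Apply Benjamini-Hochberg correction across all tested
#'   (complex, term) pairs before flagging? Off by default: the conventional
#'   benchmark protocol thresholds raw p-values.
#' @param use_propagated Use ancestor-closed annotation sets when available.
#' @return A tibble, one row per complex with at least one annotated member:
#'   `complex_id`, `term`, `m`, `n_term` (carriers in the universe), `size`,
#'   `p_value`, `significant`.
#' @export
enrich_complexes <- function(predicted, annotations, universe = NULL,
                             universe_size = NULL, alpha = 0.01,
                             adjust = FALSE, use_propagated = TRUE) {
  stopifnot(inherits(predicted, "complex_set"),
            inherits(annotations, "annotation_map"))
  sets <- annotation_sets(annotations, use_propagated)
  if (!is.null(universe)) {
    sets <- sets[intersect(names(sets), universe)]
    universe_size <- universe_size %||% length(unique(universe))
  }
  universe_size <- universe_size %||% length(sets)
  if (universe_size < length(sets)) {
    warn("`universe_size` smaller than the annotated corpus; raising it.")
    universe_size <- length(sets)
  }
  term_carriers <- table(unlist(lapply(sets, unique), use.names = FALSE))
  rows <- list()
  for (i in seq_along(predicted$complexes)) {
    members <- predicted$complexes[[i]]
    msets <- sets[intersect(members, names(sets))]
    if (length(msets) == 0) next
    terms <- sort(unique(unlist(msets, use.names = FALSE)))
    m <- vapply(terms, function(t) {
      sum(vapply(msets, function(s) t %in% s, logical(1)))
    }, integer(1))
    f <- as.integer(term_carriers[terms])
    p <- unname(mapply(hypergeometric_pvalue, m, f,
                       MoreArgs = list(V_size = universe_size,
                                       C_size = length(members))))
    rows[[length(rows) + 1L]] <- tibble(
      complex_id = predicted$meta$complex_id[i],
      term = terms, m = unname(m), n_term = f, size = length(members),
      p_value = p
    )
  }
  if (length(rows) == 0) {
    return(tibble(complex_id = character(), term = character(),
                  m = integer(), n_term = integer(), size = integer(),
                  p_value = double(), significant = logical()))
  }
  all_tests <- dplyr::bind_rows(rows)
  if (adjust) {
    all_tests$p_value <- stats::p.adjust(all_tests$p_value, method = "BH")
  }
  all_tests |>
    dplyr::arrange(.data$complex_id, .data$p_value, .data$term) |>
    dplyr::distinct(.data$complex_id, .keep_all = TRUE) |>
    dplyr::mutate(significant = .data$p_value < alpha)
}

#' Evaluate a predicted catalogue against a reference
#'
#' Bundles overlap matching, recall/precision/F1 and catalogue statistics
#' into a single report.
#'
#' @inheritParams match_sets
#' @return An `evaluation_report` (see [glance.evaluation_report()]).
#' @export
evaluate_complexes <- function(predicted, reference, ol_threshold = 0.2) {
  counts <- match_sets(predicted, reference, ol_threshold)
  n_pred <- length(predicted)
  n_ref <- length(reference)
  rpf <- if (n_pred > 0) {
    recall_precision_f1(counts$n_matched_reference, n_ref,
                        counts$n_matched_predicted, n_pred)
  } else {
    tibble(recall = 0, precision = 0, f1 = 0)
  }
  sc <- size_and_coverage(predicted)
  structure(
    list(
      n_predicted = n_pred,
      n_reference = n_ref,
      n_matched_predicted = counts$n_matched_predicted,
      n_matched_reference = counts$n_matched_reference,
      perfect_matches = counts$perfect_matches,
      recall = rpf$recall, precision = rpf$precision, f1 = rpf$f1,
      average_size = sc$average_size, coverage = sc$coverage,
      ol_threshold = ol_threshold
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<evaluation_report> (OL >= %.2f)\n",
           "  predicted: %d (matched %d)   reference: %d (matched %d)\n",
           "  recall %.4f   precision %.4f   F1 %.4f\n",
           "  perfect matches %d   average size %.2f   coverage %d\n"),
    x$ol_threshold, x$n_predicted, x$n_matched_predicted,
    x$n_reference, x$n_matched_reference,
    x$recall, x$precision, x$f1,
    x$perfect_matches, x$average_size, x$coverage))
  invisible(x)
}

#' One-row summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A one-row tibble of all report fields.
#' @export
glance.evaluation_report <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname glance.evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble(metric = names(unclass(x)),
         value = as.numeric(unlist(unclass(x))))
}

#' Write an evaluation report as a flat TSV
#'
#' Two columns, `metric<TAB>value`, full double precision (round-trips
#' through [read.delim()] exactly).
#'
#' @param x An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "evaluation_report"))
  d <- tidy.evaluation_report(x)
  writeLines(c("metric\tvalue",
               sprintf("%s\t%.17g", d$metric, d$value)), path)
  invisible(path)
}

#' Recall/precision bar chart of an evaluation report
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  d <- tibble(metric = factor(c("recall", "precision", "F1"),
                              levels = c("recall", "precision", "F1")),
              value = c(object$recall, object$precision, object$f1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = NULL, x = NULL, title = "Catalogue agreement") +
    ggplot2::theme_minimal()
}
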