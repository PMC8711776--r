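#' Create a complex set
#'
#' A `complex_set` holds a catalogue of protein complexes: a list of member
#' vectors plus per-complex metadata (seed node and tightness where known).
#'
#' @param complexes List of character vectors of protein identifiers.
#' @param source_label Free-text provenance label.
#' @param seed Optional character vector of seed nodes (one per complex).
#' @param tightness Optional numeric vector of tightness scores (WDt).
#' @return A `complex_set` object.
#' @export
complex_set <- function(complexes, source_label = "unknown",
                        seed = NULL, tightness = NULL) {
  complexes <- unname(lapply(complexes,
                             function(m) sort(unique(as.character(m)))))
  n <- length(complexes)
  if (any(vapply(complexes, function(m) any(!nzchar(m)), logical(1)))) {
    abort("Complex members must be non-empty strings.")
  }
  meta <- tibble(
    complex_id = if (n) sprintf("C%03d", seq_len(n)) else character(),
    size = lengths(complexes),
    seed = seed %||% rep(NA_character_, n),
    tightness = tightness %||% rep(NA_real_, n)
  )
  structure(list(complexes = complexes, meta = meta,
                 source_label = source_label),
            class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  cat(sprintf("<complex_set> %d complexes from %s\n",
              length(x$complexes), x$source_label))
  if (length(x$complexes)) {
    cat(sprintf("  sizes: min %d, mean %.2f, max %d\n",
                min(x$meta$size), mean(x$meta$size), max(x$meta$size)))
  }
  invisible(x)
}

#' @export
length.complex_set <- function(x) length(x$complexes)

#' Long membership table of a complex set
#'
#' @param x A `complex_set`.
#' @param ... Unused.
#' @return A tibble with one row per (complex, member), carrying the
#'   per-complex size, seed and tightness.
#' @export
tidy.complex_set <- function(x, ...) {
  if (!length(x$complexes)) {
    return(tibble(complex_id = character(), member = character(),
                  size = integer(), seed = character(),
                  tightness = double()))
  }
  tibble(
    complex_id = rep(x$meta$complex_id, x$meta$size),
    member = unlist(x$complexes, use.names = FALSE)
  ) |>
    dplyr::left_join(x$meta, by = "complex_id")
}

#' One-row-per-complex summary
#'
#' @param x A `complex_set`.
#' @param ... Unused.
#' @return The metadata tibble (complex_id, size, seed, tightness).
#' @export
glance.complex_set <- function(x, ...) x$meta

#' Size distribution of a complex catalogue
#'
#' @param object A `complex_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.complex_set <- function(object, ...) {
  ggplot2::ggplot(object$meta, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar(fill = "darkorange") +
    ggplot2::labs(x = "complex size (proteins)", y = "complexes",
                  title = sprintf("Size distribution (%s)",
                                  object$source_label)) +
    ggplot2::theme_minimal()
}
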