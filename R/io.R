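#' Read a protein interaction pair list
#'
#' Reads a whitespace/tab separated pair list (DIP-style exports reduced to
#' pairs): one interaction per line, first two fields are the protein
#' identifiers. Lines starting with `#` are comments. A numeric third field
#' is taken as an edge weight; any other extra columns are ignored.
#'
#' @param path Path to the file.
#' @return A tibble with columns `protein_a`, `protein_b` and, when a numeric
#'   third column is present on every line, `weight`. Input order preserved;
#'   no cleaning is applied (see [build_network()] for that).
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    warn(sprintf("No interactions found in %s", path))
    return(tibble(protein_a = character(), protein_b = character()))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    bad <- idx[which(nf < 2)[1]]
    abort(sprintf("Malformed interaction line %d in %s: fewer than 2 fields.",
                  bad, path))
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  out <- tibble(protein_a = a, protein_b = b)
  if (all(nf >= 3)) {
    w <- suppressWarnings(as.double(vapply(fields, `[[`, character(1), 3L)))
    if (!anyNA(w)) out$weight <- w
  }
  out
}

#' Write a weighted edge list
#'
#' Writes a three-column TSV `a<TAB>b<TAB>weight` with weights printed to six
#' decimal places. Endpoints within a line are sorted lexicographically and
#' lines are sorted, so output is canonical and round-trips through
#' [read_interactions()] + [build_network()] up to weight precision.
#'
#' @param network A weighted `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weighted_edges <- function(network, path) {
  check_network(network)
  if (nrow(network$edges) > 0 && !network$weighted) {
    abort("Network has no weights; run `weight_network()` first.")
  }
  e <- dplyr::arrange(network$edges, .data$protein_a, .data$protein_b)
  lines <- sprintf("%s\t%s\t%.6f", e$protein_a, e$protein_b, e$weight)
  writeLines(lines, path)
  invisible(path)
}

#' Write an unweighted pair list
#'
#' @param network A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(network, path) {
  check_network(network)
  e <- dplyr::arrange(network$edges, .data$protein_a, .data$protein_b)
  writeLines(sprintf("%s\t%s", e$protein_a, e$protein_b), path)
  invisible(path)
}

#' Read a complex catalogue
#'
#' Reads a CYC2008/MIPS-style catalogue: one complex per line, members
#' whitespace-separated. Duplicate members within a line are collapsed;
#' complexes with fewer than two distinct members are dropped with a warning.
#'
#' @param path Path to the file.
#' @param source_label Label recorded on the returned set (defaults to the
#'   file name).
#' @return A `complex_set`.
#' @export
read_complexes <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  members <- lapply(strsplit(trimws(lines), "\\s+"),
                    function(x) sort(unique(x)))
  small <- lengths(members) < 2
  if (any(small)) {
    warn(sprintf("Dropped %d complex(es) with fewer than 2 members.",
                 sum(small)))
  }
  complex_set(members[!small], source_label = source_label)
}

#' Write a complex catalogue
#'
#' One complex per line, members sorted and tab-separated. When per-complex
#' tightness/seed metadata are present a JSON sidecar `<path>.json` can be
#' written alongside.
#'
#' @param x A `complex_set`.
#' @param path Output path.
#' @param sidecar Write the JSON metadata sidecar? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(x, path, sidecar = FALSE) {
  stopifnot(inherits(x, "complex_set"))
  writeLines(vapply(x$complexes, function(m) paste(sort(m), collapse = "\t"),
                    character(1)), path)
  if (sidecar) {
    jsonlite::write_json(
      list(complexes = x$meta),
      paste0(path, ".json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
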