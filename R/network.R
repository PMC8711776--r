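#' Build a clean PPI network from an interaction table
#'
#' Turns a raw interaction table into a simple undirected graph: self-loops
#' are removed, duplicate pairs (in either orientation) are collapsed, and
#' the node set is the union of the endpoints of the surviving edges.
#' Isolated proteins that only ever appeared in self-loops are therefore
#' dropped; clustering operates on the connected structure.
#'
#' @param interactions A data frame with character columns `protein_a` and
#'   `protein_b` (as returned by [read_interactions()]) and an optional
#'   numeric `weight` column in \[0, 1\]. When duplicates carry different
#'   weights the first occurrence wins.
#' @return A `ppi_network` object.
#' @examples
#' net <- build_network(tibble::tibble(
#'   protein_a = c("P1", "P2", "P3", "P1"),
#'   protein_b = c("P2", "P1", "P3", "P2")
#' ))
#' net
#' @export
build_network <- function(interactions) {
  stopifnot(is.data.frame(interactions))
  if (nrow(interactions) == 0) {
    edges <- tibble(protein_a = character(), protein_b = character(),
                    weight = double())
    return(new_ppi_network(edges, weighted = FALSE))
  }
  if (!all(c("protein_a", "protein_b") %in% names(interactions))) {
    abort("`interactions` must have columns `protein_a` and `protein_b`.")
  }
  a <- as.character(interactions$protein_a)
  b <- as.character(interactions$protein_b)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    abort("Protein identifiers must be non-empty strings.")
  }
  w <- if ("weight" %in% names(interactions)) {
    as.double(interactions$weight)
  } else {
    rep(NA_real_, length(a))
  }
  keep <- a != b
  edges <- tibble(
    protein_a = pmin(a[keep], b[keep]),
    protein_b = pmax(a[keep], b[keep]),
    weight = w[keep]
  )
  edges <- dplyr::distinct(edges, .data$protein_a, .data$protein_b,
                           .keep_all = TRUE)
  edges <- dplyr::arrange(edges, .data$protein_a, .data$protein_b)
  weighted <- nrow(edges) > 0 && !anyNA(edges$weight)
  if (weighted && (any(edges$weight < 0) || any(edges$weight > 1))) {
    abort("Edge weights must lie in [0, 1].")
  }
  new_ppi_network(edges, weighted = weighted)
}

new_ppi_network <- function(edges, weighted, nodes = NULL) {
  nodes <- sort(unique(c(nodes, edges$protein_a, edges$protein_b)))
  if (nrow(edges) > 0) {
    both_from <- c(edges$protein_a, edges$protein_b)
    both_to <- c(edges$protein_b, edges$protein_a)
    both_w <- rep(edges$weight, 2L)
    f <- factor(both_from, levels = nodes)
    adjacency <- split(both_to, f)
    weight_adj <- split(setNames(both_w, both_to), f)
  } else {
    adjacency <- setNames(list(), character())
    weight_adj <- setNames(list(), character())
  }
  structure(
    list(edges = edges, nodes = nodes, weighted = weighted,
         adjacency = adjacency, weight_adj = weight_adj),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              if (x$weighted) "weighted" else "unweighted"))
  if (x$weighted && nrow(x$edges) > 0) {
    cat(sprintf("  weight range: [%.4f, %.4f]\n",
                min(x$edges$weight), max(x$edges$weight)))
  }
  invisible(x)
}

#' @export
as_tibble.ppi_network <- function(x, ...) {
  if (x$weighted) x$edges else x$edges[c("protein_a", "protein_b")]
}

#' @rdname build_network
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @export
tidy.ppi_network <- function(x, ...) as_tibble.ppi_network(x)

#' Is an object a weighted PPI network?
#' @param x Object to test.
#' @return Logical scalar.
#' @export
is_weighted <- function(x) {
  inherits(x, "ppi_network") && isTRUE(x$weighted)
}

#' Nodes of a PPI network
#' @param network A `ppi_network`.
#' @return Character vector of protein identifiers, sorted.
#' @export
network_nodes <- function(network) {
  check_network(network)
  network$nodes
}

#' Neighbourhood of a node
#'
#' The open neighbourhood N(v): all proteins sharing an edge with `v`
#' (excluding `v` itself; the graph is simple).
#'
#' @param network A `ppi_network`.
#' @param v Protein identifier.
#' @return Character vector of neighbours (possibly empty).
#' @export
network_neighbors <- function(network, v) {
  check_node(network, v)
  as.character(network$adjacency[[v]])
}

check_network <- function(network, weighted = FALSE) {
  if (!inherits(network, "ppi_network")) {
    abort("Expected a `ppi_network` object (see `build_network()`).")
  }
  if (weighted && !network$weighted) {
    abort(paste0("This operation needs a weighted network; ",
                 "run `weight_network()` first."))
  }
  invisible(network)
}

check_node <- function(network, v) {
  check_network(network)
  if (length(v) != 1 || !v %in% network$nodes) {
    abort(sprintf("Protein `%s` is not a node of the network.",
                  paste(v, collapse = ",")))
  }
  invisible(v)
}

# Incident edge weights of v as a numeric vector named by neighbour.
incident_weights <- function(network, v) {
  w <- network$weight_adj[[v]]
  if (is.null(w)) setNames(numeric(), character()) else w
}

#' Induced subgraph
#'
#' @param network A `ppi_network`.
#' @param members Character vector of node identifiers (unknown ids ignored).
#' @return A `ppi_network` on `members` (members without internal edges are
#'   kept as isolated nodes) with the original edges and weights.
#' @export
induced_subgraph <- function(network, members) {
  check_network(network)
  members <- intersect(network$nodes, members)
  edges <- dplyr::filter(network$edges,
                         .data$protein_a %in% members,
                         .data$protein_b %in% members)
  new_ppi_network(edges, weighted = network$weighted, nodes = members)
}

#' Distribution of edge weights
#'
#' Histogram of the edge-weight distribution of a weighted network; useful
#' for eyeballing the separation between reliable and noisy interactions
#' before choosing a noise threshold.
#'
#' @param object A weighted `ppi_network`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_network <- function(object, bins = 30, ...) {
  check_network(object, weighted = TRUE)
  ggplot2::ggplot(object$edges, ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "edge weight", y = "edges",
                  title = "Edge-weight distribution") +
    ggplot2::theme_minimal()
}
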