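# Builders shared across test files. Everything is generated in code; no
# stored fixtures.

edge_tbl <- function(a, b, w = NULL) {
  out <- tibble::tibble(protein_a = a, protein_b = b)
  if (!is.null(w)) out$weight <- w
  out
}

unit_clique_network <- function(k, prefix = "c") {
  nodes <- sprintf("%s%02d", prefix, seq_len(k))
  p <- t(utils::combn(nodes, 2))
  build_network(edge_tbl(p[, 1], p[, 2], 1))
}

unit_path_network <- function(nodes = c("a", "b", "c", "d")) {
  n <- length(nodes)
  build_network(edge_tbl(nodes[-n], nodes[-1], 1))
}

# Erdos-Renyi style weighted graph, deterministic given seed.
random_weighted_network <- function(n, p = 0.35, seed = 1, weights = TRUE) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p
    w <- if (weights) round(stats::runif(sum(keep)), 3) else NULL
    build_network(edge_tbl(pairs[keep, 1], pairs[keep, 2], w))
  })
}

# A small annotation corpus with a known information-content structure.
toy_corpus <- function() {
  direct <- list(
    P1 = c("t1", "t2"),
    P2 = c("t2", "t3"),
    P3 = c("t1", "t3"),
    P4 = c("t2")
  )
  annotation_map(direct)
}

# ic_table with hand-chosen ic values, for closed-form similarity checks.
manual_ic_table <- function(ic) {
  structure(
    list(
      table = tibble::tibble(term = names(ic), count = NA_integer_,
                             p = exp(-ic), ic = unname(ic)),
      total = NA_integer_,
      ic = ic
    ),
    class = "ic_table"
  )
}

# Default planted fixture with annotations, propagated and weighted.
planted_pipeline_inputs <- function(seed) {
  spec <- fixture_spec(rng_seed = seed)
  net <- generate_network(spec)
  go <- generate_ontology_and_annotations(spec, net$truth, net$membership)
  ann <- propagate_annotations(go$annotations, go$ontology)
  list(spec = spec, network = net$network, truth = net$truth,
       membership = net$membership, ontology = go$ontology,
       annotations = ann)
}
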