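#' Specification of a planted-complex benchmark instance
#'
#' Describes a synthetic stand-in for the real inputs (interaction list,
#' ontology, annotations, reference catalogue): disjoint protein groups are
#' planted as ground-truth complexes, wired densely inside and sparsely
#' between, and annotated with group-specific signature GO terms plus random
#' background terms.
#'
#' @param n_complexes Number of planted complexes. Default 15.
#' @param size_range Integer pair, inclusive complex size bounds. Default
#'   c(3, 8), the small-complex regime typical of curated yeast catalogues.
#' @param p_within Edge probability inside a planted complex (must exceed
#'   `p_between`). Default 0.95.
#' @param p_between Edge probability across groups and to/among noise nodes.
#'   Default 0.02.
#' @param n_noise_nodes Unassigned background proteins. Default 10.
#' @param annotation_coherence Probability that a member carries its
#'   complex's signature term. Default 0.9.
#' @param n_background_terms Pool of unspecific terms sprinkled over all
#'   proteins. Default 8.
#' @param rng_seed Integer seed; identical specs generate byte-identical
#'   fixtures.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_complexes = 15, size_range = c(3, 8),
                         p_within = 0.95, p_between = 0.02,
                         n_noise_nodes = 10, annotation_coherence = 0.9,
                         n_background_terms = 8, rng_seed = 1) {
  if (length(size_range) != 2 || size_range[1] < 2 ||
      size_range[2] < size_range[1]) {
    abort("`size_range` must be an increasing pair with minimum >= 2.")
  }
  if (!(p_within > 0 && p_within <= 1) || !(p_between >= 0 && p_between < 1)) {
    abort("Need 0 < p_within <= 1 and 0 <= p_between < 1.")
  }
  if (p_within <= p_between) abort("`p_within` must exceed `p_between`.")
  if (annotation_coherence < 0 || annotation_coherence > 1) {
    abort("`annotation_coherence` must lie in [0, 1].")
  }
  if (n_complexes < 1) abort("Need at least one planted complex.")
  structure(list(
    n_complexes = as.integer(n_complexes),
    size_range = as.integer(size_range),
    p_within = p_within, p_between = p_between,
    n_noise_nodes = as.integer(n_noise_nodes),
    annotation_coherence = annotation_coherence,
    n_background_terms = as.integer(n_background_terms),
    rng_seed = as.integer(rng_seed)
  ), class = "fixture_spec")
}

#' Generate a planted-complex network
#'
#' Plants `n_complexes` disjoint groups of proteins, samples internal edges
#' at `p_within` and all other pairs (between groups, to noise nodes, among
#' noise nodes) at `p_between`. Deterministic given the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return List with `network` (a `ppi_network`) and `truth` (a
#'   `complex_set` of the planted groups).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$rng_seed, {
    sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                    spec$n_complexes, replace = TRUE)
    n_nodes <- sum(sizes) + spec$n_noise_nodes
    nodes <- sprintf("P%04d", seq_len(n_nodes))
    group <- rep(c(seq_along(sizes), rep(0L, spec$n_noise_nodes)),
                 times = c(sizes, rep(1L, spec$n_noise_nodes)))
    pairs <- utils::combn(n_nodes, 2)
    same <- group[pairs[1, ]] == group[pairs[2, ]] & group[pairs[1, ]] != 0L
    prob <- ifelse(same, spec$p_within, spec$p_between)
    keep <- stats::runif(ncol(pairs)) < prob
    interactions <- tibble(
      protein_a = nodes[pairs[1, keep]],
      protein_b = nodes[pairs[2, keep]]
    )
    truth <- complex_set(split(nodes[group != 0L], group[group != 0L]),
                         source_label = "planted_truth")
    list(network = build_network(interactions), truth = truth,
         membership = setNames(group, nodes))
  })
}

#' Generate a toy ontology and coherent annotations
#'
#' Builds a small two-namespace DAG: a biological-process branch holding one
#' signature leaf term per planted complex, and a molecular-function branch
#' holding unspecific background terms. Every member of complex *i* receives
#' signature term *i* with probability `annotation_coherence`; every protein
#' (members and noise alike) additionally receives one or two random
#' background terms. Deterministic given the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param truth The planted `complex_set` from [generate_network()].
#' @param membership Optional named group vector from [generate_network()];
#'   when supplied, noise nodes are annotated too.
#' @return List with `ontology` (an `ontology_dag`) and `annotations` (an
#'   `annotation_map`, direct only).
#' @export
generate_ontology_and_annotations <- function(spec, truth,
                                              membership = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(truth, "complex_set"))
  if (length(truth) == 0) abort("`truth` must contain at least one complex.")
  n_sig <- length(truth)
  bp_root <- "GO:0000001"; bp_mid <- "GO:0000002"
  mf_root <- "GO:0000003"
  sig <- sprintf("GO:1%06d", seq_len(n_sig))
  bg <- sprintf("GO:2%06d", seq_len(spec$n_background_terms))
  terms <- tibble(
    term = c(bp_root, bp_mid, mf_root, sig, bg),
    name = c("process root", "complex activity", "function root",
             sprintf("signature process %d", seq_len(n_sig)),
             sprintf("background function %d",
                     seq_len(spec$n_background_terms))),
    namespace = c("biological_process", "biological_process",
                  "molecular_function",
                  rep("biological_process", n_sig),
                  rep("molecular_function", length(bg))),
    obsolete = FALSE
  )
  parents <- c(
    setNames(list(character(), bp_root, character()),
             c(bp_root, bp_mid, mf_root)),
    setNames(rep(list(bp_mid), n_sig), sig),
    setNames(rep(list(mf_root), length(bg)), bg)
  )
  ontology <- structure(
    list(terms = terms, parents = parents,
         alt_id = setNames(character(), character())),
    class = "ontology_dag"
  )
  proteins <- if (!is.null(membership)) {
    names(membership)
  } else {
    unique(unlist(truth$complexes))
  }
  withr::with_seed(spec$rng_seed + 1L, {
    direct <- setNames(vector("list", length(proteins)), proteins)
    for (p in proteins) {
      ts <- sample(bg, sample(1:2, 1))
      grp <- if (!is.null(membership)) {
        membership[[p]]
      } else {
        which(vapply(truth$complexes, function(m) p %in% m, logical(1)))[1]
      }
      if (length(grp) == 1 && !is.na(grp) && grp > 0 &&
          stats::runif(1) < spec$annotation_coherence) {
        ts <- c(ts, sig[grp])
      }
      direct[[p]] <- sort(unique(ts))
    }
    list(ontology = ontology, annotations = annotation_map(direct))
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the four file formats the real pipeline reads: `pairs.tsv`
#' (interaction list), `ontology.obo`, `annotations.gaf` and
#' `reference_complexes.txt` (the planted truth). The files are synthetic
#' stand-ins for DIP/GO/CYC2008-style inputs.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return Named list of the four file paths plus the in-memory objects,
#'   invisibly.
#' @export
generate_fixture <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- generate_network(spec)
  onto <- generate_ontology_and_annotations(spec, net$truth, net$membership)
  paths <- list(
    pairs = file.path(dir, "pairs.tsv"),
    obo = file.path(dir, "ontology.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    reference = file.path(dir, "reference_complexes.txt")
  )
  write_pairs(net$network, paths$pairs)
  write_obo(onto$ontology, paths$obo)
  write_gaf(onto$annotations, paths$gaf)
  write_complexes(net$truth, paths$reference)
  invisible(c(paths, list(network = net$network, truth = net$truth,
                          ontology = onto$ontology,
                          annotations = onto$annotations)))
}

#' Write an ontology as OBO 1.2
#'
#' @param ontology An `ontology_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "ontology_dag"))
  header <- c("format-version: 1.2", "ontology: synthetic")
  stanzas <- lapply(seq_len(nrow(ontology$terms)), function(i) {
    t <- ontology$terms[i, ]
    parents <- ontology$parents[[t$term]]
    c("", "[Term]",
      paste0("id: ", t$term),
      paste0("name: ", t$name),
      paste0("namespace: ", t$namespace),
      if (t$obsolete) "is_obsolete: true",
      if (length(parents)) paste0("is_a: ", parents))
  })
  writeLines(c(header, unlist(stanzas)), path)
  invisible(path)
}

#' Write an annotation map as GAF 2.2
#'
#' @param annotations An `annotation_map` (direct sets are written).
#' @param path Output path.
#' @param aspect_of Optional function mapping a term id to a GAF aspect
#'   letter; defaults to `"P"` for every term.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path, aspect_of = NULL) {
  stopifnot(inherits(annotations, "annotation_map"))
  header <- "!gaf-version: 2.2"
  lines <- unlist(lapply(names(annotations$direct), function(p) {
    vapply(annotations$direct[[p]], function(t) {
      aspect <- if (is.null(aspect_of)) "P" else aspect_of(t)
      paste(c("SYN", p, p, "involved_in", t, "SYN_REF:0000001", "IDA", "",
              aspect, "", "", "protein", "taxon:0000", "20260101", "SYN",
              "", ""), collapse = "\t")
    }, character(1))
  }), use.names = FALSE)
  writeLines(c(header, lines), path)
  invisible(path)
}
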