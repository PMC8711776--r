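#' Stage 1: weight an interaction list
#'
#' Reads a pair list, cleans it into a simple network, optionally loads GO
#' inputs for the semantic component, computes the combined edge weights and
#' writes the weighted edge list plus a JSON run manifest
#' (`<out>.manifest.json`: input checksums, parameters, node/edge counts,
#' package version).
#'
#' @param network Path to a pair-list TSV.
#' @param out Output path for the weighted edge TSV.
#' @param obo,gaf Optional paths to an OBO ontology and GAF annotation file;
#'   both or neither must be given.
#' @param config A [similarity_config()].
#' @param use_propagated Use ancestor-closed annotation sets.
#' @return Invisibly, a list with the weighted `ppi_network` and the
#'   manifest.
#' @export
run_weight <- function(network, out, obo = NULL, gaf = NULL,
                       config = similarity_config(), use_propagated = TRUE) {
  if (is.null(obo) != is.null(gaf)) {
    abort("Semantic weighting needs both `obo` and `gaf` (or neither).")
  }
  net <- build_network(read_interactions(network))
  annotations <- NULL; ontology <- NULL
  if (!is.null(obo)) {
    ontology <- parse_obo(obo)
    annotations <- parse_gaf(gaf, ontology)
  }
  weighted <- weight_network(net, annotations = annotations,
                             config = config, ontology = ontology,
                             use_propagated = use_propagated)
  write_weighted_edges(weighted, out)
  manifest <- write_manifest(
    out,
    inputs = c(network = network, obo = obo, gaf = gaf),
    parameters = unclass(config),
    counts = list(input_nodes = length(net$nodes),
                  input_edges = nrow(net$edges),
                  output_nodes = length(weighted$nodes),
                  output_edges = nrow(weighted$edges))
  )
  invisible(list(network = weighted, manifest = manifest))
}

#' Stage 2: detect complexes on a weighted edge list
#'
#' Reads a three-column weighted edge TSV (as written by [run_weight()]),
#' runs the seed-and-extend detector and writes the complex catalogue (one
#' complex per line) plus a JSON sidecar with per-complex seed and
#' tightness, and a run manifest.
#'
#' @param weighted Path to a weighted edge TSV.
#' @param out Output path for the complex catalogue.
#' @param config An [nnp_config()].
#' @return Invisibly, a list with the detected `complex_set` and the
#'   manifest.
#' @export
run_detect <- function(weighted, out, config = nnp_config()) {
  interactions <- read_interactions(weighted)
  if (nrow(interactions) > 0 && !"weight" %in% names(interactions)) {
    abort("Input has no weight column; run `run_weight()` first.")
  }
  net <- build_network(interactions)
  if (nrow(net$edges) == 0) {
    warn("Empty weighted network; writing an empty catalogue.")
    net <- new_ppi_network(net$edges, weighted = TRUE)
  }
  found <- detect_complexes(net, config)
  write_complexes(found, out, sidecar = TRUE)
  manifest <- write_manifest(
    out,
    inputs = c(weighted = weighted),
    parameters = unclass(config),
    counts = list(n_complexes = length(found),
                  coverage = length(unique(unlist(found$complexes))))
  )
  invisible(list(complexes = found, manifest = manifest))
}

#' Stage 3: evaluate a predicted catalogue
#'
#' Scores predictions against a reference catalogue (overlap matching,
#' recall/precision/F1, size statistics) and writes the report as a
#' `metric<TAB>value` TSV. When GO inputs are supplied, per-complex
#' enrichment is written alongside as `<out>.enrichment.tsv`.
#'
#' @param pred Path to the predicted catalogue.
#' @param ref Path to the reference catalogue.
#' @param out Output path for the report TSV.
#' @param ol_threshold Overlap-ratio matching threshold. Default 0.2.
#' @param obo,gaf Optional GO inputs for enrichment.
#' @param universe_size Universe size for enrichment; defaults to the number
#'   of annotated proteins.
#' @param alpha Enrichment significance cutoff. Default 0.01.
#' @return Invisibly, a list with the `evaluation_report` (and enrichment
#'   tibble when computed) and the manifest.
#' @export
run_evaluate <- function(pred, ref, out, ol_threshold = 0.2,
                         obo = NULL, gaf = NULL, universe_size = NULL,
                         alpha = 0.01) {
  if (is.null(obo) != is.null(gaf)) {
    abort("Enrichment needs both `obo` and `gaf` (or neither).")
  }
  predicted <- suppressWarnings(read_complexes(pred))
  reference <- read_complexes(ref)
  report <- evaluate_complexes(predicted, reference, ol_threshold)
  write_report(report, out)
  enrichment <- NULL
  if (!is.null(obo)) {
    ontology <- parse_obo(obo)
    annotations <- propagate_annotations(parse_gaf(gaf, ontology), ontology)
    enrichment <- enrich_complexes(predicted, annotations,
                                   universe_size = universe_size,
                                   alpha = alpha)
    enr_path <- paste0(out, ".enrichment.tsv")
    writeLines(c(
      "complex_id\tterm\tm\tn_term\tsize\tp_value\tsignificant",
      sprintf("%s\t%s\t%d\t%d\t%d\t%.6e\t%s",
              enrichment$complex_id, enrichment$term, enrichment$m,
              enrichment$n_term, enrichment$size, enrichment$p_value,
              enrichment$significant)
    ), enr_path)
  }
  manifest <- write_manifest(
    out,
    inputs = c(pred = pred, ref = ref, obo = obo, gaf = gaf),
    parameters = list(ol_threshold = ol_threshold, alpha = alpha),
    counts = list(n_predicted = report$n_predicted,
                  n_reference = report$n_reference)
  )
  invisible(list(report = report, enrichment = enrichment,
                 manifest = manifest))
}

#' Generate fixture files from the command line workflow
#'
#' Thin wrapper over [generate_fixture()] keyed by an explicit seed.
#'
#' @param out_dir Output directory.
#' @param rng_seed Integer seed.
#' @param ... Passed to [fixture_spec()].
#' @return Invisibly, the fixture path list.
#' @export
run_simulate <- function(out_dir, rng_seed = 1, ...) {
  generate_fixture(fixture_spec(rng_seed = rng_seed, ...), out_dir)
}

#' Read a YAML run configuration
#'
#' Reads a YAML file mirroring the pipeline flags; recognised top-level keys
#' are `network`, `obo`, `gaf`, `reference`, `out_dir`, plus nested
#' `similarity` (fields of [similarity_config()]) and `nnp` (fields of
#' [nnp_config()]) blocks and `ol_threshold`/`alpha`.
#'
#' @param path Path to a YAML file.
#' @return A list with `similarity` and `nnp` realised as config objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg$similarity <- do.call(similarity_config, cfg$similarity %||% list())
  cfg$nnp <- do.call(nnp_config, cfg$nnp %||% list())
  cfg
}

write_manifest <- function(out, inputs, parameters, counts) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    package = "nnpclust",
    version = as.character(utils::packageVersion("nnpclust")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(as.list(inputs), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    parameters = parameters,
    counts = counts,
    output = out
  )
  jsonlite::write_json(manifest, paste0(out, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}
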