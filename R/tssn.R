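#' Edge-weighting configuration
#'
#' Tunables for [weight_network()].
#'
#' @param noise_threshold In `threshold_mode = "fixed"`, edges with combined
#'   similarity strictly below this value are removed. Default 0 (filter
#'   off). Values above 1 are capped at 1.
#' @param threshold_mode How the noise cutoff is obtained: `"fixed"` uses
#'   `noise_threshold` as given; `"percentile"` drops the lowest
#'   `noise_threshold` fraction of edge weights; `"mixture"` derives a
#'   data-driven (conditional) cutoff by fitting a two-component Gaussian
#'   mixture to the weight distribution and cutting at the class boundary —
#'   when the two components are not clearly separated (mean difference
#'   below the sum of the component standard deviations) no edge is removed,
#'   so clean networks pass through untouched.
#' @param combine_normalization `"pair_mean"` (default) averages the per
#'   neighbour-pair scores, guaranteeing weights in \[0, 1\];
#'   `"half_sum"` keeps the raw half-sum over neighbour pairs, which can
#'   exceed 1 and is provided for fidelity experiments only.
#' @param alpha Mixing weight between the topological and the semantic
#'   component of each neighbour-pair score: `alpha * J + (1 - alpha) * se`.
#'   Default 0.5 (plain average).
#' @return A `similarity_config` list.
#' @export
similarity_config <- function(noise_threshold = 0,
                              threshold_mode = c("fixed", "percentile", "mixture"),
                              combine_normalization = c("pair_mean",
                                                        "half_sum"),
                              alpha = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  combine_normalization <- match.arg(combine_normalization)
  if (!is.numeric(noise_threshold) || noise_threshold < 0) {
    abort("`noise_threshold` must be a non-negative number.")
  }
  noise_threshold <- min(noise_threshold, 1)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].")
  }
  structure(list(noise_threshold = noise_threshold,
                 threshold_mode = threshold_mode,
                 combine_normalization = combine_normalization,
                 alpha = alpha),
            class = "similarity_config")
}

#' Jaccard similarity of two nodes' neighbourhoods
#'
#' `J(u, v) = |N(u) intersect N(v)| / |N(u) union N(v)|` with N the open
#' neighbourhood (the node itself is excluded; the graph is simple). Two
#' nodes in the same dense module share most neighbours and score near 1.
#'
#' @param network A `ppi_network`.
#' @param u,v Node identifiers.
#' @return A similarity in \[0, 1\]; 0 when both neighbourhoods are empty.
#' @export
jaccard <- function(network, u, v) {
  check_node(network, u); check_node(network, v)
  nu <- network$adjacency[[u]]; nv <- network$adjacency[[v]]
  uni <- length(union(nu, nv))
  if (uni == 0) return(0)
  length(intersect(nu, nv)) / uni
}

#' Combined topological + semantic similarity of an adjacent pair
#'
#' The weight attached to an interaction (u, v) is obtained from the
#' neighbour pairs of its endpoints: for every `u1` in N(u) and `v1` in
#' N(v), the per-pair score `alpha * J(u1, v1) + (1 - alpha) * se(u1, v1)`
#' is computed, and the scores are averaged
#' (`combine_normalization = "pair_mean"`, guaranteed in \[0, 1\]) or
#' half-summed (`"half_sum"`). The score is 0 when either neighbourhood
#' is empty.
#'
#' @param network A `ppi_network`.
#' @param u,v Adjacent node identifiers (weights are computed for edges, but
#'   any node pair is accepted).
#' @param sem Semantic similarity: a function of two protein ids returning a
#'   value in \[0, 1\], or `NULL` to use topology alone (the semantic
#'   component is then dropped from the per-pair score rather than scored 0,
#'   so a purely topological run still spans \[0, 1\]).
#' @param config A [similarity_config()].
#' @return A non-negative score; in \[0, 1\] under `"pair_mean"`.
#' @export
pair_similarity <- function(network, u, v, sem = NULL,
                            config = similarity_config()) {
  check_node(network, u); check_node(network, v)
  nu <- network$adjacency[[u]]; nv <- network$adjacency[[v]]
  if (length(nu) == 0 || length(nv) == 0) return(0)
  alpha <- if (is.null(sem)) 1 else config$alpha
  total <- 0
  for (u1 in nu) {
    for (v1 in nv) {
      s <- alpha * jaccard(network, u1, v1)
      if (!is.null(sem)) s <- s + (1 - config$alpha) * sem(u1, v1)
      total <- total + s
    }
  }
  if (config$combine_normalization == "pair_mean") {
    total / (length(nu) * length(nv))
  } else {
    total / 2
  }
}

#' Build the similarity-weighted network
#'
#' Re-weights every edge of a cleaned PPI network by the combined
#' topological/semantic similarity of its endpoints ([pair_similarity()]),
#' then removes edges falling below the noise cutoff and drops nodes left
#' isolated. No edges are ever added: the procedure denoises, it does not
#' densify.
#'
#' @param network A `ppi_network` (cleaned, see [build_network()]).
#' @param annotations Optional `annotation_map`; when supplied the semantic
#'   component is used (the map is ancestor-propagated on the fly if needed,
#'   which requires `ontology`).
#' @param table Optional `ic_table`; computed from `annotations` via
#'   [term_frequencies()] when missing.
#' @param config A [similarity_config()].
#' @param ontology Optional `ontology_dag`, only needed to propagate a
#'   not-yet-propagated annotation map.
#' @param use_propagated Use ancestor-closed annotation sets (default).
#' @return A weighted `ppi_network`.
#' @export
weight_network <- function(network, annotations = NULL, table = NULL,
                           config = similarity_config(), ontology = NULL,
                           use_propagated = TRUE) {
  check_network(network)
  stopifnot(inherits(config, "similarity_config"))
  if (nrow(network$edges) == 0) {
    return(new_ppi_network(network$edges, weighted = TRUE))
  }
  sem <- NULL
  if (!is.null(annotations)) {
    if (use_propagated && is.null(annotations$propagated)) {
      if (is.null(annotations$propagated) && is.null(ontology)) {
        abort("Supply `ontology` (or a pre-propagated map) to use propagated annotation sets.")
      }
      annotations <- propagate_annotations(annotations, ontology)
    }
    if (is.null(table)) {
      table <- term_frequencies(annotations, use_propagated = use_propagated)
    }
    sets <- annotation_sets(annotations, use_propagated)
    ic <- table$ic
    profile_ic <- vapply(sets, set_ic_lenient, numeric(1), ic = ic)
    sem_cache <- new.env(parent = emptyenv())
    sem <- function(p, q) {
      key <- if (p < q) paste0(p, "\r", q) else paste0(q, "\r", p)
      hit <- sem_cache[[key]]
      if (!is.null(hit)) return(hit)
      A <- sets[[p]]; B <- sets[[q]]
      val <- if (is.null(A) || is.null(B)) {
        0
      } else {
        denom <- max(profile_ic[[p]], profile_ic[[q]])
        if (denom <= 0) 0 else
          min(1, set_ic_lenient(intersect(A, B), ic) / denom)
      }
      sem_cache[[key]] <- val
      val
    }
  }

  jac_cache <- new.env(parent = emptyenv())
  jac <- function(p, q) {
    key <- if (p < q) paste0(p, "\r", q) else paste0(q, "\r", p)
    hit <- jac_cache[[key]]
    if (!is.null(hit)) return(hit)
    np <- network$adjacency[[p]]; nq <- network$adjacency[[q]]
    uni <- length(union(np, nq))
    val <- if (uni == 0) 0 else length(intersect(np, nq)) / uni
    jac_cache[[key]] <- val
    val
  }

  alpha <- if (is.null(sem)) 1 else config$alpha
  score_edge <- function(u, v) {
    nu <- network$adjacency[[u]]; nv <- network$adjacency[[v]]
    if (length(nu) == 0 || length(nv) == 0) return(0)
    total <- 0
    for (u1 in nu) {
      for (v1 in nv) {
        s <- alpha * jac(u1, v1)
        if (!is.null(sem)) s <- s + (1 - config$alpha) * sem(u1, v1)
        total <- total + s
      }
    }
    if (config$combine_normalization == "pair_mean") {
      total / (length(nu) * length(nv))
    } else {
      total / 2
    }
  }

  e <- network$edges
  w <- mapply(score_edge, e$protein_a, e$protein_b, USE.NAMES = FALSE)
  cutoff <- switch(config$threshold_mode,
    fixed = config$noise_threshold,
    percentile = as.numeric(quantile(w, probs = config$noise_threshold,
                                     type = 1)),
    mixture = mixture_threshold(w)
  )
  keep <- w >= cutoff
  new_ppi_network(
    tibble(protein_a = e$protein_a[keep], protein_b = e$protein_b[keep],
           weight = w[keep]),
    weighted = TRUE
  )
}

# Conditional noise cutoff: two-component Gaussian mixture on the weights,
# cut midway between the top of the noise class and the bottom of the signal
# class. Degenerate or unimodal distributions yield 0 (nothing removed).
mixture_threshold <- function(w) {
  if (length(unique(w)) < 5) return(0)
  fit <- tryCatch(
    Mclust(w, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) {
      warn(sprintf("Mixture threshold fit failed (%s); no edges removed.",
                   conditionMessage(e)))
      NULL
    }
  )
  if (is.null(fit)) return(0)
  mu <- fit$parameters$mean
  sd <- sqrt(fit$parameters$variance$sigmasq)
  lo <- which.min(mu); hi <- which.max(mu)
  if (mu[hi] - mu[lo] < sd[lo] + sd[hi]) return(0)
  up <- fit$classification == hi
  (max(w[!up]) + min(w[up])) / 2
}
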