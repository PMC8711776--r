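#' Clustering configuration
#'
#' Tunables of the seed-and-extend complex detector ([detect_complexes()]).
#'
#' @param wnt Weighted-neighbour-ratio admission threshold in \[0, 1\].
#'   Default 0.22, the value at which the method's precision peaks on the
#'   yeast DIP benchmark.
#' @param ol_merge Overlap-ratio threshold for post-filtering: of any two
#'   complexes with overlap at or above it, only the tighter survives.
#'   Default 0.2.
#' @param min_size Minimum complex size. Default 2 (curated catalogues such
#'   as CYC2008 contain heterodimers).
#' @param max_iterations Cap on candidate evaluations per seed; `NULL` means
#'   the node count of the network.
#' @return An `nnp_config` list.
#' @export
nnp_config <- function(wnt = 0.22, ol_merge = 0.2, min_size = 2,
                       max_iterations = NULL) {
  if (!is.numeric(wnt) || wnt < 0 || wnt > 1) abort("`wnt` must be in [0, 1].")
  if (!is.numeric(ol_merge) || ol_merge < 0 || ol_merge > 1) {
    abort("`ol_merge` must be in [0, 1].")
  }
  if (!is.numeric(min_size) || min_size < 2) abort("`min_size` must be >= 2.")
  structure(list(wnt = wnt, ol_merge = ol_merge,
                 min_size = as.integer(min_size),
                 max_iterations = max_iterations),
            class = "nnp_config")
}

#' Weighted degree of a node
#'
#' Sum of the weights of the node's incident edges, optionally restricted to
#' edges whose other endpoint lies in `within`.
#'
#' @param network A weighted `ppi_network`.
#' @param v Node identifier.
#' @param within Optional character vector restricting the counted
#'   neighbours.
#' @return Non-negative scalar (0 for an isolated node).
#' @export
weighted_degree <- function(network, v, within = NULL) {
  check_node(network, v)
  check_network(network, weighted = TRUE)
  w <- incident_weights(network, v)
  if (!is.null(within)) w <- w[names(w) %in% within]
  if (length(w) == 0) 0 else sum(w)
}

#' Average weighted degree
#'
#' The weighted degree divided by the total node count of the network. The
#' denominator is a network-wide constant, so ranking nodes by average
#' weighted degree and by weighted degree is identical; the averaged form is
#' what the seed ordering is defined on.
#'
#' @inheritParams weighted_degree
#' @return Non-negative scalar.
#' @export
average_weighted_degree <- function(network, v) {
  check_network(network, weighted = TRUE)
  if (length(network$nodes) == 0) abort("Network is empty.")
  weighted_degree(network, v) / length(network$nodes)
}

# Nodes at shortest-path distance exactly 2 from v.
second_order_nodes <- function(network, v) {
  nv <- network$adjacency[[v]]
  if (length(nv) == 0) return(character())
  setdiff(unique(unlist(network$adjacency[nv], use.names = FALSE)),
          c(v, nv))
}

#' Second-order neighbour subgraph
#'
#' The subgraph induced by the nodes at shortest-path distance exactly 2
#' from `v` (the node itself and its direct neighbours are excluded),
#' carrying the original edge weights.
#'
#' @param network A `ppi_network`.
#' @param v Node identifier.
#' @return A `ppi_network` (possibly empty).
#' @export
second_order_subgraph <- function(network, v) {
  check_node(network, v)
  induced_subgraph(network, second_order_nodes(network, v))
}

#' Weighted neighbour ratio
#'
#' Measures how self-contained a node's neighbourhood is. With `WD(v)` the
#' node's weighted degree and `cut2(v)` the total weight of the edges
#' linking its direct neighbours N(v) to its second-order shell (nodes at
#' distance exactly 2),
#' `WN(v) = WD(v) / (WD(v) + cut2(v))`.
#' A node inside a tight module has no second-order shell (or only weakly
#' connected one) and scores near 1; a peripheral node hanging off a dense
#' region scores near 0. Returns 0 when both terms are 0 (isolated node).
#'
#' @param network A weighted `ppi_network`.
#' @param v Node identifier.
#' @return A ratio in \[0, 1\].
#' @export
weighted_neighbor_ratio <- function(network, v) {
  check_node(network, v)
  check_network(network, weighted = TRUE)
  wd1 <- weighted_degree(network, v)
  shell <- second_order_nodes(network, v)
  cut2 <- 0
  if (length(shell)) {
    for (y in network$adjacency[[v]]) {
      wy <- incident_weights(network, y)
      cut2 <- cut2 + sum(wy[names(wy) %in% shell])
    }
  }
  if (wd1 + cut2 <= 0) return(0)
  wd1 / (wd1 + cut2)
}

#' Tightness (weighted density) of a complex
#'
#' `WDt = 2 * sum(internal edge weights) / (k * (k - 1))` for a complex of
#' `k` members: the total internal weight relative to the weight of a
#' unit-weight clique of the same size. A unit-weight clique scores exactly 1.
#'
#' @param network A weighted `ppi_network`.
#' @param members Character vector of at least two node identifiers.
#' @return Non-negative scalar.
#' @export
complex_tightness <- function(network, members) {
  check_network(network, weighted = TRUE)
  members <- unique(members)
  if (length(members) < 2) abort("A complex needs at least 2 members.")
  e <- network$edges
  internal <- e$protein_a %in% members & e$protein_b %in% members
  k <- length(members)
  2 * sum(e$weight[internal]) / (k * (k - 1))
}

#' Overlap ratio between two complexes
#'
#' The neighbourhood-affinity overlap
#' `OL(C1, C2) = |C1 intersect C2|^2 / (|C1| * |C2|)`:
#' 1 for identical member sets, 0 for disjoint ones.
#'
#' @param c1,c2 Character vectors of members (non-empty).
#' @return A ratio in \[0, 1\]; symmetric.
#' @export
complex_overlap <- function(c1, c2) {
  c1 <- unique(c1); c2 <- unique(c2)
  if (length(c1) == 0 || length(c2) == 0) {
    abort("Overlap is undefined for empty complexes.")
  }
  length(intersect(c1, c2))^2 / (length(c1) * length(c2))
}

#' Seed ordering
#'
#' All nodes sorted by average weighted degree, descending; ties are broken
#' by lexicographic node id so the ordering (and everything downstream) is
#' deterministic.
#'
#' @param network A weighted `ppi_network`.
#' @return Character vector of node ids.
#' @export
build_seed_list <- function(network, ...) {
  check_network(network, weighted = TRUE)
  nodes <- network$nodes
  if (length(nodes) == 0) return(character())
  awd <- vapply(nodes, function(v) weighted_degree(network, v), numeric(1)) /
    length(nodes)
  nodes[order(-awd, nodes)]
}

# Per-node weighted neighbour ratio for all nodes, as a named vector.
all_weighted_neighbor_ratios <- function(network) {
  vapply(network$nodes, function(v) weighted_neighbor_ratio(network, v),
         numeric(1))
}

#' Grow a complex from a seed
#'
#' Deterministic seed expansion: starting from `C = {seed}`, the neighbours
#' of the current complex form the candidate pool; candidates are examined
#' in order of (descending total edge weight into the complex, ascending
#' id). A candidate `x` is admitted when its weighted neighbour ratio
#' reaches `config$wnt` **both** on the full network (is `x` interior to
#' some tight region at all?) and on the subgraph induced by `C` and `x`
#' (is `x` coherent with *this* complex? — a candidate reached over a weak
#' bridge edge sees the rest of the complex as a heavily connected
#' second-order shell and is rejected). Admission adds the candidate's own
#' neighbours to the pool; the loop stops when the pool is exhausted (a
#' rejected node is never reconsidered) or `max_iterations` candidates have
#' been examined.
#'
#' @param network A weighted `ppi_network`.
#' @param seed Seed node identifier.
#' @param config An [nnp_config()].
#' @param wn Optional pre-computed named vector of per-node weighted
#'   neighbour ratios (an internal optimisation for [detect_complexes()]).
#' @return Named list with `members`, `seed` and `tightness` (`NA` for a
#'   singleton).
#' @export
grow_complex <- function(network, seed, config = nnp_config(), wn = NULL) {
  check_node(network, seed)
  check_network(network, weighted = TRUE)
  stopifnot(inherits(config, "nnp_config"))
  max_iter <- config$max_iterations %||% length(network$nodes)

  wn_of <- function(v) {
    if (!is.null(wn)) return(wn[[v]])
    weighted_neighbor_ratio(network, v)
  }

  members <- seed
  processed <- seed
  # candidate -> total edge weight into the complex
  cand <- incident_weights(network, seed)
  cand <- cand[!names(cand) %in% processed]
  iter <- 0L
  while (length(cand) > 0 && iter < max_iter) {
    iter <- iter + 1L
    ord <- order(-cand, names(cand))
    x <- names(cand)[ord[1]]
    cand <- cand[names(cand) != x]
    processed <- c(processed, x)
    admit <- wn_of(x) >= config$wnt &&
      weighted_neighbor_ratio(induced_subgraph(network, c(members, x)),
                              x) >= config$wnt
    if (admit) {
      members <- c(members, x)
      wx <- incident_weights(network, x)
      wx <- wx[!names(wx) %in% processed]
      for (nb in names(wx)) {
        cand[nb] <- (if (nb %in% names(cand)) cand[[nb]] else 0) + wx[[nb]]
      }
    }
  }
  members <- sort(members)
  list(
    members = members,
    seed = seed,
    tightness = if (length(members) >= 2) {
      complex_tightness(network, members)
    } else {
      NA_real_
    }
  )
}

#' Post-filter candidate complexes
#'
#' Applies the retention rules: complexes below `min_size` are dropped,
#' exact duplicates are collapsed, and of every pair with overlap ratio at
#' least `ol_merge` only one survives — the tighter (higher WDt) complex,
#' with ties broken towards the larger complex and then the
#' lexicographically first seed. Output is sorted by descending tightness,
#' then ascending seed.
#'
#' @param candidates List of grown complexes (as returned by
#'   [grow_complex()]).
#' @param config An [nnp_config()].
#' @return A `complex_set`.
#' @export
filter_complexes <- function(candidates, config = nnp_config()) {
  stopifnot(inherits(config, "nnp_config"))
  candidates <- candidates[
    vapply(candidates, function(c) length(c$members) >= config$min_size,
           logical(1))
  ]
  if (length(candidates) == 0) {
    return(complex_set(list(), source_label = "nnp"))
  }
  key <- vapply(candidates, function(c) paste(c$members, collapse = "\r"),
                character(1))
  wdt <- vapply(candidates, `[[`, numeric(1), "tightness")
  size <- vapply(candidates, function(c) length(c$members), integer(1))
  seed <- vapply(candidates, `[[`, character(1), "seed")
  # order by the retention priority, then deduplicate and greedily keep
  # anything not over-overlapping an already kept (i.e. stronger) complex
  ord <- order(-wdt, -size, seed)
  candidates <- candidates[ord]
  key <- key[ord]
  candidates <- candidates[!duplicated(key)]
  kept <- list()
  for (c in candidates) {
    clash <- any(vapply(kept, function(k) {
      complex_overlap(k$members, c$members) >= config$ol_merge
    }, logical(1)))
    if (!clash) kept <- c(kept, list(c))
  }
  complex_set(
    lapply(kept, `[[`, "members"),
    source_label = "nnp",
    seed = vapply(kept, `[[`, character(1), "seed"),
    tightness = vapply(kept, `[[`, numeric(1), "tightness")
  )
}

#' Detect protein complexes in a weighted network
#'
#' The full seed-and-extend pipeline on a similarity-weighted network:
#' nodes are ordered by average weighted degree ([build_seed_list()]); each
#' seed not yet covered by an emitted complex is grown ([grow_complex()]),
#' and the retention rule of [filter_complexes()] is applied as each
#' candidate is obtained — a grown complex is emitted only if it is at least
#' `min_size` and beats (by tightness, then size, then seed id) every
#' already-emitted complex it overlaps at `ol_merge` or more, in which case
#' it replaces them. A complex discarded on arrival never blocks later
#' seeds, so a sprawling low-tightness cluster grown from a weakly attached
#' seed cannot shadow the tight complexes inside it. Nodes may belong to
#' several complexes (only seeding is exclusive), and the whole procedure is
#' deterministic for a fixed network and configuration.
#'
#' @param network A weighted `ppi_network` (see [weight_network()]).
#' @param config An [nnp_config()].
#' @return A `complex_set` with per-complex seed and tightness.
#' @examples
#' edges <- tibble::tibble(
#'   protein_a = c("A", "A", "B", "X", "X", "Y"),
#'   protein_b = c("B", "C", "C", "Y", "Z", "Z"),
#'   weight = 1
#' )
#' detect_complexes(build_network(edges))
#' @export
detect_complexes <- function(network, config = nnp_config()) {
  check_network(network, weighted = TRUE)
  stopifnot(inherits(config, "nnp_config"))
  if (length(network$nodes) == 0) {
    return(complex_set(list(), source_label = "nnp"))
  }
  wn <- all_weighted_neighbor_ratios(network)
  seeds <- build_seed_list(network)
  kept <- list()
  covered <- character()
  for (s in seeds) {
    if (s %in% covered) next
    g <- grow_complex(network, s, config, wn = wn)
    if (length(g$members) < config$min_size) next
    clash <- if (length(kept)) {
      which(vapply(kept, function(k) {
        complex_overlap(k$members, g$members) >= config$ol_merge
      }, logical(1)))
    } else {
      integer()
    }
    beats <- function(k) {
      g$tightness > k$tightness ||
        (g$tightness == k$tightness &&
           (length(g$members) > length(k$members) ||
              (length(g$members) == length(k$members) && g$seed < k$seed)))
    }
    if (length(clash) == 0 || all(vapply(kept[clash], beats, logical(1)))) {
      kept <- kept[setdiff(seq_along(kept), clash)]
      kept <- c(kept, list(g))
    }
    covered <- unique(unlist(lapply(kept, `[[`, "members")))
  }
  filter_complexes(kept, config)
}
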