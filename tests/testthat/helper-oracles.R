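# Independent brute-force oracles. These re-derive each quantity from first
# principles (set arithmetic, exhaustive enumeration, log-space summation)
# and never call the implementation under test.

oracle_neighbors <- function(network, v) {
  e <- network$edges
  sort(c(e$protein_b[e$protein_a == v], e$protein_a[e$protein_b == v]))
}

oracle_jaccard <- function(network, u, v) {
  nu <- oracle_neighbors(network, u)
  nv <- oracle_neighbors(network, v)
  uni <- union(nu, nv)
  if (length(uni) == 0) return(0)
  length(intersect(nu, nv)) / length(uni)
}

oracle_pair_similarity <- function(network, u, v, sem = NULL, alpha = 0.5,
                                   normalize = TRUE) {
  nu <- oracle_neighbors(network, u)
  nv <- oracle_neighbors(network, v)
  if (length(nu) == 0 || length(nv) == 0) return(0)
  if (is.null(sem)) {
    sem <- function(p, q) 0
    alpha <- 1
  }
  total <- 0
  for (u1 in nu) for (v1 in nv) {
    total <- total + alpha * oracle_jaccard(network, u1, v1) +
      (1 - alpha) * sem(u1, v1)
  }
  if (normalize) total / (length(nu) * length(nv)) else total / 2
}

oracle_weighted_degree <- function(network, v, within = NULL) {
  e <- network$edges
  inc <- e[e$protein_a == v | e$protein_b == v, ]
  if (!is.null(within)) {
    other <- ifelse(inc$protein_a == v, inc$protein_b, inc$protein_a)
    inc <- inc[other %in% within, ]
  }
  sum(inc$weight)
}

# distance-exactly-2 node set by explicit BFS layers
oracle_second_order <- function(network, v) {
  l1 <- oracle_neighbors(network, v)
  l2 <- unique(unlist(lapply(l1, oracle_neighbors, network = network)))
  sort(setdiff(l2, c(v, l1)))
}

oracle_wn <- function(network, v) {
  wd1 <- oracle_weighted_degree(network, v)
  shell <- oracle_second_order(network, v)
  e <- network$edges
  n1 <- oracle_neighbors(network, v)
  cross <- (e$protein_a %in% n1 & e$protein_b %in% shell) |
    (e$protein_b %in% n1 & e$protein_a %in% shell)
  cut2 <- sum(e$weight[cross])
  if (wd1 + cut2 <= 0) 0 else wd1 / (wd1 + cut2)
}

oracle_overlap <- function(c1, c2) {
  length(intersect(c1, c2))^2 / (length(c1) * length(c2))
}

# hypergeometric upper tail by direct log-space summation over the support
oracle_hyper <- function(m, F_size, V_size, C_size) {
  if (m == 0) return(1)
  i <- m:min(F_size, C_size)
  terms <- lchoose(F_size, i) + lchoose(V_size - F_size, C_size - i) -
    lchoose(V_size, C_size)
  sum(exp(terms))
}

# independent re-implementation of the growth admission rule
oracle_grow <- function(network, seed, wnt) {
  members <- seed
  processed <- seed
  repeat {
    nb <- unique(unlist(lapply(members, oracle_neighbors,
                               network = network)))
    cand <- setdiff(nb, c(processed, members))
    if (length(cand) == 0) break
    into <- vapply(cand, oracle_weighted_degree, numeric(1),
                   network = network, within = members)
    x <- cand[order(-into, cand)][1]
    processed <- c(processed, x)
    sub <- induced_subgraph(network, c(members, x))
    ok <- oracle_wn(network, x) >= wnt &&
      (!x %in% sub$nodes || oracle_wn(sub, x) >= wnt)
    if (ok) members <- c(members, x)
  }
  sort(members)
}
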