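test_that("configuration defaults and validation", {
  cfg <- nnp_config()
  expect_equal(cfg$wnt, 0.22)
  expect_equal(cfg$ol_merge, 0.2)
  expect_equal(cfg$min_size, 2L)
  expect_error(nnp_config(wnt = 1.2), "wnt")
  expect_error(nnp_config(min_size = 1), "min_size")
})

test_that("weighted degree sums incident weights", {
  net <- build_network(edge_tbl(c("v", "v"), c("a", "b"), c(0.3, 0.7)))
  expect_equal(weighted_degree(net, "v"), 1)
  expect_equal(weighted_degree(net, "v", within = "a"), 0.3)
  expect_error(weighted_degree(net, "zz"), "not a node")

  net2 <- random_weighted_network(15, p = 0.3, seed = 7)
  for (v in network_nodes(net2)) {
    expect_equal(weighted_degree(net2, v), oracle_weighted_degree(net2, v))
  }
})

test_that("average weighted degree rescales without reordering", {
  net <- build_network(edge_tbl("a", "b", 0.8))
  expect_equal(average_weighted_degree(net, "a"), 0.4)

  net2 <- random_weighted_network(20, p = 0.25, seed = 2)
  nodes <- network_nodes(net2)
  wd <- vapply(nodes, weighted_degree, numeric(1), network = net2)
  awd <- vapply(nodes, average_weighted_degree, numeric(1), network = net2)
  expect_equal(order(-wd, nodes), order(-awd, nodes))
  expect_equal(awd, wd / length(nodes))
})

test_that("second-order subgraphs contain exactly the distance-2 shell", {
  path <- unit_path_network(c("a", "b", "c"))
  expect_equal(network_nodes(second_order_subgraph(path, "a")), "c")
  expect_equal(nrow(second_order_subgraph(path, "a")$edges), 0)

  star <- build_network(edge_tbl(rep("h", 4), paste0("s", 1:4), 1))
  expect_equal(length(network_nodes(second_order_subgraph(star, "h"))), 0)

  skip_if_not_installed("igraph")
  for (seed in 1:3) {
    net <- random_weighted_network(20, p = 0.15, seed = seed)
    g <- igraph::graph_from_data_frame(
      net$edges[, c("protein_a", "protein_b")], directed = FALSE)
    dmat <- igraph::distances(g)
    for (v in network_nodes(net)) {
      shell <- sort(colnames(dmat)[dmat[v, ] == 2])
      expect_equal(network_nodes(second_order_subgraph(net, v)),
                   shell)
      expect_equal(network_nodes(second_order_subgraph(net, v)),
                   oracle_second_order(net, v))
    }
  }
})

test_that("weighted neighbour ratio measures neighbourhood closure", {
  # no second-order shell: fully interior node
  tri <- unit_clique_network(3)
  for (v in network_nodes(tri)) {
    expect_equal(weighted_neighbor_ratio(tri, v), 1)
  }
  # a-b-c-d: b's neighbourhood leaks to d through c
  path <- unit_path_network()
  expect_equal(weighted_neighbor_ratio(path, "b"), 2 / 3)
  expect_equal(weighted_neighbor_ratio(path, "a"), 1 / 2)
  # a node attached only by a zero-weight edge has no weighted support
  loner <- build_network(edge_tbl(c("a", "b"), c("b", "c"), c(0, 0)))
  expect_equal(weighted_neighbor_ratio(loner, "a"), 0)

  for (seed in 1:4) {
    net <- random_weighted_network(14, p = 0.3, seed = seed)
    for (v in network_nodes(net)) {
      wn <- weighted_neighbor_ratio(net, v)
      expect_equal(wn, oracle_wn(net, v))
      expect_gte(wn, 0); expect_lte(wn, 1)
    }
  }
})

test_that("tightness is the weighted density of the induced subgraph", {
  pair <- build_network(edge_tbl("a", "b", 0.37))
  expect_equal(complex_tightness(pair, c("a", "b")), 0.37)
  # three members, no internal edges
  net <- build_network(edge_tbl(c("a", "b", "c"), c("x", "x", "x"), 1))
  expect_equal(complex_tightness(net, c("a", "b", "c")), 0)
  for (k in 3:5) {
    cl <- unit_clique_network(k)
    expect_equal(complex_tightness(cl, network_nodes(cl)), 1)
  }
  expect_error(complex_tightness(pair, "a"), "at least 2")
})

test_that("overlap ratio is the squared-intersection affinity", {
  expect_equal(complex_overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(complex_overlap(c("a", "b"), c("x", "y")), 0)
  expect_equal(complex_overlap(c("a", "b", "c"), c("b", "c", "d", "e")),
               1 / 3)
  expect_error(complex_overlap(character(), "a"), "empty")
  for (seed in 1:5) {
    sets <- withr::with_seed(seed, {
      list(sample(letters, 6), sample(letters, 9))
    })
    expect_equal(complex_overlap(sets[[1]], sets[[2]]),
                 oracle_overlap(sets[[1]], sets[[2]]))
    expect_equal(complex_overlap(sets[[1]], sets[[2]]),
                 complex_overlap(sets[[2]], sets[[1]]))
  }
})

test_that("seed list orders by average weighted degree with id tie-break", {
  two <- build_network(edge_tbl("b", "a", 0.5))
  expect_equal(build_seed_list(two), c("a", "b"))

  tri <- build_network(edge_tbl(c("a", "a", "c"), c("b", "c", "b"),
                                c(0.7, 0.5, 0.2)))
  # summed degrees: a 1.2, b 0.9, c 0.7
  expect_equal(build_seed_list(tri), c("a", "b", "c"))

  net <- random_weighted_network(50, p = 0.1, seed = 12)
  nodes <- network_nodes(net)
  awd <- vapply(nodes, average_weighted_degree, numeric(1), network = net)
  expect_equal(build_seed_list(net), nodes[order(-awd, nodes)])
})

test_that("growth recovers cliques and rejects weak attachments", {
  tri <- unit_clique_network(3)
  for (s in network_nodes(tri)) {
    expect_equal(grow_complex(tri, s)$members, network_nodes(tri))
  }

  # maximal threshold admits nothing on a path: every node leaks weight
  path <- unit_path_network()
  g <- grow_complex(path, "b", nnp_config(wnt = 1))
  expect_equal(g$members, "b")
  expect_equal(length(detect_complexes(path, nnp_config(wnt = 1))), 0)

  # planted 6-clique with a weakly attached pendant node
  cl <- t(utils::combn(sprintf("c%d", 1:6), 2))
  net <- build_network(edge_tbl(c(cl[, 1], "c1"), c(cl[, 2], "p"),
                                c(rep(1, 15), 0.05)))
  g2 <- grow_complex(net, "c2")
  expect_equal(g2$members, sprintf("c%d", 1:6))
  expect_equal(g2$tightness, complex_tightness(net, g2$members))
})

test_that("growth matches an exhaustive re-implementation of admission", {
  for (seed in 1:6) {
    net <- random_weighted_network(8, p = 0.45, seed = seed)
    for (s in network_nodes(net)) {
      for (wnt in c(0.1, 0.22, 0.5)) {
        expect_equal(
          grow_complex(net, s, nnp_config(wnt = wnt))$members,
          oracle_grow(net, s, wnt)
        )
      }
    }
  }
})

test_that("growth shrinks toward the threshold extremes", {
  # wnt = 0 admits every reachable node: the connected component
  skip_if_not_installed("igraph")
  for (seed in 1:3) {
    net <- random_weighted_network(12, p = 0.25, seed = seed)
    g <- igraph::graph_from_data_frame(
      net$edges[, c("protein_a", "protein_b")], directed = FALSE)
    comp <- igraph::components(g)
    for (s in network_nodes(net)[1:4]) {
      full <- grow_complex(net, s, nnp_config(wnt = 0))$members
      expect_equal(full,
                   sort(names(comp$membership[
                     comp$membership == comp$membership[s]])))
      # any stricter threshold grows inside the component
      for (wnt in c(0.3, 0.7, 1)) {
        expect_true(all(
          grow_complex(net, s, nnp_config(wnt = wnt))$members %in% full))
      }
    }
  }
})

test_that("filtering drops duplicates, undersized and dominated complexes", {
  net <- unit_clique_network(5)
  nodes <- network_nodes(net)
  mk <- function(members, seed) {
    list(members = sort(members), seed = seed,
         tightness = complex_tightness(net, members))
  }
  # identical complexes collapse
  out <- filter_complexes(list(mk(nodes[1:3], nodes[1]),
                               mk(nodes[1:3], nodes[2])))
  expect_equal(length(out), 1)

  # disjoint complexes both survive
  net2 <- build_network(edge_tbl(c("a", "x"), c("b", "y"), 1))
  out2 <- filter_complexes(list(
    list(members = c("a", "b"), seed = "a",
         tightness = complex_tightness(net2, c("a", "b"))),
    list(members = c("x", "y"), seed = "x",
         tightness = complex_tightness(net2, c("x", "y")))
  ))
  expect_equal(length(out2), 2)

  # nested pair with high overlap: the tighter (smaller) one wins
  net3 <- build_network(edge_tbl(
    c(t(utils::combn(c("a", "b", "c"), 2))[, 1], "c"),
    c(t(utils::combn(c("a", "b", "c"), 2))[, 2], "d"),
    c(1, 1, 1, 0.1)))
  inner <- list(members = c("a", "b", "c"), seed = "a",
                tightness = complex_tightness(net3, c("a", "b", "c")))
  outer <- list(members = c("a", "b", "c", "d"), seed = "a",
                tightness = complex_tightness(net3, c("a", "b", "c", "d")))
  expect_gt(inner$tightness, outer$tightness)
  expect_gte(complex_overlap(inner$members, outer$members), 0.2)
  kept <- filter_complexes(list(outer, inner))
  expect_equal(length(kept), 1)
  expect_equal(kept$complexes[[1]], c("a", "b", "c"))

  # undersized complexes are dropped
  out3 <- filter_complexes(list(list(members = "a", seed = "a",
                                     tightness = NA_real_)),
                           nnp_config(min_size = 2))
  expect_equal(length(out3), 0)
})

test_that("detection finds disjoint cliques exactly", {
  empty <- build_network(edge_tbl(character(), character()))
  expect_error(detect_complexes(empty), "weight")

  c1 <- t(utils::combn(paste0("a", 1:4), 2))
  c2 <- t(utils::combn(paste0("b", 1:4), 2))
  net <- build_network(edge_tbl(c(c1[, 1], c2[, 1]), c(c1[, 2], c2[, 2]), 1))
  found <- detect_complexes(net)
  expect_equal(length(found), 2)
  expect_equal(found$complexes[[1]], paste0("a", 1:4))
  expect_equal(found$complexes[[2]], paste0("b", 1:4))
  expect_equal(found$meta$tightness, c(1, 1))
})

test_that("detected catalogues satisfy the output contracts", {
  for (seed in c(1, 4)) {
    inp <- planted_pipeline_inputs(seed)
    w <- weight_network(inp$network, inp$annotations,
                        config = similarity_config(
                          threshold_mode = "mixture"))
    found <- detect_complexes(w)
    cfg <- nnp_config()
    expect_true(all(lengths(found$complexes) >= cfg$min_size))
    expect_true(all(found$meta$tightness > 0))
    if (length(found) > 1) {
      for (i in seq_len(length(found) - 1)) {
        for (j in (i + 1):length(found)) {
          expect_lt(complex_overlap(found$complexes[[i]],
                                    found$complexes[[j]]),
                    cfg$ol_merge)
        }
      }
    }
  }
})

test_that("detection is invariant to input edge order", {
  inp <- planted_pipeline_inputs(2)
  w <- weight_network(inp$network, inp$annotations,
                      config = similarity_config(threshold_mode = "mixture"))
  found1 <- detect_complexes(w)
  shuffled <- withr::with_seed(77, w$edges[sample(nrow(w$edges)), ])
  found2 <- detect_complexes(build_network(shuffled))
  expect_identical(found1$complexes, found2$complexes)
  expect_identical(found1$meta, found2$meta)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_complexes(found1, f1); write_complexes(found2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
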