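obo_lines <- function(...) c("format-version: 1.2", ...)

write_obo_text <- function(lines) {
  withr::local_tempfile(lines = lines, .local_envir = parent.frame())
}

test_that("parse_obo records chains, obsolescence and alt_ids", {
  f <- write_obo_text(obo_lines(
    "", "[Term]", "id: t1", "name: root", "namespace: biological_process",
    "", "[Term]", "id: t2", "name: mid", "namespace: biological_process",
    "is_a: t1 ! root",
    "", "[Term]", "id: t3", "name: leaf", "namespace: biological_process",
    "is_a: t2", "alt_id: t3alt",
    "", "[Term]", "id: t4", "name: gone", "namespace: biological_process",
    "is_obsolete: true"
  ))
  dag <- parse_obo(f)
  expect_equal(dag$parents$t3, "t2")
  expect_equal(dag$parents$t2, "t1")
  expect_equal(dag$parents$t1, character())
  expect_true(dag$terms$obsolete[dag$terms$term == "t4"])
  expect_equal(length(dag$parents$t4), 0)
  expect_equal(resolve_terms(dag, c("t3alt", "t1")), c("t3", "t1"))
  expect_equal(term_ancestors(dag, "t3"), c("t1", "t2"))
})

test_that("parse_obo validates the parent graph", {
  cyc <- write_obo_text(obo_lines(
    "", "[Term]", "id: a", "name: a", "is_a: b",
    "", "[Term]", "id: b", "name: b", "is_a: a"
  ))
  expect_error(parse_obo(cyc), "cycle")

  dangling <- write_obo_text(obo_lines(
    "", "[Term]", "id: a", "name: a", "is_a: ghost"
  ))
  expect_error(parse_obo(dangling), "ghost")
})

test_that("generated fixture ontology partitions namespaces as constructed", {
  spec <- fixture_spec(n_complexes = 4, n_background_terms = 3, rng_seed = 1)
  net <- generate_network(spec)
  go <- generate_ontology_and_annotations(spec, net$truth, net$membership)
  ns <- table(go$ontology$terms$namespace)
  # 2 BP structural + 4 signature vs 1 MF root + 3 background
  expect_equal(unname(ns[["biological_process"]]), 6)
  expect_equal(unname(ns[["molecular_function"]]), 4)

  f <- withr::local_tempfile()
  write_obo(go$ontology, f)
  reparsed <- parse_obo(f)
  expect_equal(sort(reparsed$terms$term), sort(go$ontology$terms$term))
  expect_equal(reparsed$parents[order(names(reparsed$parents))],
               go$ontology$parents[order(names(go$ontology$parents))])
})

gaf_line <- function(protein, term, qualifier = "involved_in",
                     evidence = "IDA") {
  paste(c("SYN", protein, protein, qualifier, term, "REF:1", evidence, "",
          "P", "", "", "protein", "taxon:0", "20260101", "SYN", "", ""),
        collapse = "\t")
}

test_that("parse_gaf applies NOT, obsolete and evidence filters", {
  obo <- write_obo_text(obo_lines(
    "", "[Term]", "id: t1", "name: a", "namespace: biological_process",
    "", "[Term]", "id: t2", "name: b", "namespace: biological_process",
    "is_a: t1",
    "", "[Term]", "id: t9", "name: dead", "namespace: biological_process",
    "is_obsolete: true"
  ))
  dag <- parse_obo(obo)
  f <- withr::local_tempfile(lines = c(
    "!gaf-version: 2.2",
    gaf_line("P1", "t1"),
    gaf_line("P1", "t2"),
    gaf_line("P2", "t1", qualifier = "NOT|involved_in"),
    gaf_line("P2", "t2", evidence = "IEA"),
    gaf_line("P3", "t9")
  ))
  expect_warning(ann <- parse_gaf(f, dag), "obsolete")
  expect_equal(ann$direct$P1, c("t1", "t2"))
  expect_equal(ann$direct$P2, "t2")
  expect_false("P3" %in% names(ann$direct))

  suppressWarnings({
    strict <- parse_gaf(f, dag, exclude_evidence = "IEA")
  })
  expect_false("P2" %in% names(strict$direct))

  bad <- withr::local_tempfile(lines = c("!h", "SYN\tP1\tonly three\tcols"))
  expect_error(parse_gaf(bad, dag), "line 2")
})

test_that("propagation equals a brute-force ancestor BFS", {
  # hand chain
  obo <- write_obo_text(obo_lines(
    "", "[Term]", "id: t1", "name: r", "", "[Term]", "id: t2", "name: m",
    "is_a: t1", "", "[Term]", "id: t3", "name: l", "is_a: t2"
  ))
  dag <- parse_obo(obo)
  ann <- propagate_annotations(annotation_map(list(P = "t3", Q = "t1")), dag)
  expect_equal(ann$propagated$P, c("t1", "t2", "t3"))
  expect_equal(ann$propagated$Q, "t1")

  # random DAGs: parents only among earlier terms, so acyclic by construction
  for (seed in 1:4) {
    dag2 <- withr::with_seed(seed, {
      terms <- sprintf("g%02d", 1:20)
      parents <- setNames(lapply(seq_along(terms), function(i) {
        if (i == 1) return(character())
        sample(terms[seq_len(i - 1)], sample(0:min(2, i - 1), 1))
      }), terms)
      structure(list(
        terms = tibble::tibble(term = terms, name = terms,
                               namespace = "biological_process",
                               obsolete = FALSE),
        parents = parents,
        alt_id = setNames(character(), character())
      ), class = "ontology_dag")
    })
    bfs_up <- function(t) {
      seen <- character(); frontier <- t
      while (length(frontier)) {
        ps <- unique(unlist(dag2$parents[frontier]))
        frontier <- setdiff(ps, seen)
        seen <- union(seen, frontier)
      }
      sort(seen)
    }
    direct <- withr::with_seed(seed + 100, {
      list(A = sample(dag2$terms$term, 3), B = sample(dag2$terms$term, 2))
    })
    got <- propagate_annotations(annotation_map(direct), dag2)$propagated
    for (p in names(direct)) {
      expected <- sort(unique(c(direct[[p]],
                                unlist(lapply(direct[[p]], bfs_up)))))
      expect_equal(got[[p]], expected)
    }
  }
})

test_that("term frequencies convert occurrence counts to information", {
  ubiq <- term_frequencies(annotation_map(list(P1 = "t1", P2 = "t1")),
                           use_propagated = FALSE)
  expect_equal(ubiq$table$p, 1)
  expect_equal(ubiq$table$ic, 0)

  half <- term_frequencies(annotation_map(list(P1 = "t1", P2 = "t2")),
                           use_propagated = FALSE)
  expect_equal(half$ic[["t1"]], log(2))
  expect_equal(half$ic[["t1"]], half$ic[["t2"]])

  # independent counting pass on a random corpus
  corpus <- withr::with_seed(11, {
    setNames(lapply(1:10, function(i) {
      sample(sprintf("t%d", 1:6), sample(1:4, 1))
    }), sprintf("P%02d", 1:10))
  })
  tab <- term_frequencies(annotation_map(corpus), use_propagated = FALSE)
  occ <- unlist(corpus, use.names = FALSE)
  for (t in unique(occ)) {
    expect_equal(tab$ic[[t]], -log(sum(occ == t) / length(occ)))
  }

  expect_error(term_frequencies(annotation_map(list())), "empty")
})

test_that("adding an occurrence of a term never increases its information", {
  base <- list(P1 = c("t1", "t2"), P2 = "t2", P3 = c("t3"))
  ic0 <- term_frequencies(annotation_map(base), use_propagated = FALSE)
  grown <- c(base, list(P4 = "t2"))
  ic1 <- term_frequencies(annotation_map(grown), use_propagated = FALSE)
  expect_lte(ic1$ic[["t2"]], ic0$ic[["t2"]])
})

test_that("set information content sums member terms", {
  tab <- manual_ic_table(c(t1 = 0.7, t2 = 2, t3 = 3))
  expect_equal(set_ic(character(), tab), 0)
  expect_equal(set_ic("t1", tab), 0.7)
  some <- c("t1", "t3")
  expect_equal(set_ic(some, tab), 0.7 + 3)
  expect_error(set_ic("nope", tab), "nope")
})

test_that("semantic similarity follows the shared-information ratio", {
  tab <- manual_ic_table(c(t1 = 1, t2 = 2, t3 = 3))
  ann <- annotation_map(list(u = c("t1", "t2"), v = c("t2", "t3"),
                             w = c("t1", "t2"), x = "t9"))
  # shared t2 (ic 2) over max(1+2, 2+3)
  expect_equal(semantic_similarity("u", "v", ann, tab), 0.4)
  expect_equal(semantic_similarity("u", "w", ann, tab), 1)
  expect_equal(semantic_similarity("u", "u", ann, tab), 1)
  # disjoint and unannotated cases collapse to zero
  ann2 <- annotation_map(list(a = "t1", b = "t3"))
  expect_equal(semantic_similarity("a", "b", ann2, tab), 0)
  expect_equal(semantic_similarity("a", "missing", ann2, tab), 0)
  # profile of never-observed terms carries no information
  expect_equal(semantic_similarity("x", "x", ann, tab), 0)
})

test_that("semantic similarity is symmetric and bounded on real corpora", {
  inp <- planted_pipeline_inputs(3)
  tab <- term_frequencies(inp$annotations)
  prots <- withr::with_seed(5, sample(names(inp$annotations$direct), 12))
  for (i in seq_along(prots)) {
    for (j in seq_len(i)) {
      s_ij <- semantic_similarity(prots[i], prots[j], inp$annotations, tab)
      s_ji <- semantic_similarity(prots[j], prots[i], inp$annotations, tab)
      expect_identical(s_ij, s_ji)
      expect_gte(s_ij, 0)
      expect_lte(s_ij, 1)
      if (i == j) expect_equal(s_ij, 1)
    }
  }
})
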