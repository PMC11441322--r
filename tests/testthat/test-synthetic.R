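test_that("graph generation is byte-identical for a fixed seed", {
  spec <- graph_spec(seed = 77)
  g1 <- simulate_graph(spec)
  g2 <- simulate_graph(spec)
  dir <- withr::local_tempdir()
  write_graph(g1, file.path(dir, "n1.tsv"), file.path(dir, "e1.tsv"))
  write_graph(g2, file.path(dir, "n2.tsv"), file.path(dir, "e2.tsv"))
  expect_identical(readLines(file.path(dir, "n1.tsv")),
    readLines(file.path(dir, "n2.tsv")))
  expect_identical(readLines(file.path(dir, "e1.tsv")),
    readLines(file.path(dir, "e2.tsv")))
  # different seeds give different graphs
  g3 <- simulate_graph(graph_spec(seed = 78))
  expect_false(identical(g1$edges$subject_id, g3$edges$subject_id) &&
    identical(g1$edges$object_id, g3$edges$object_id))
})

test_that("generated counts follow the spec and declared fractions", {
  spec <- graph_spec(n_diseases = 25, n_genes = 100, assoc_per_disease = 8,
    fraction_textmining = 0.5, seed = 79)
  g <- simulate_graph(spec)
  expect_equal(sum(g$nodes$node_type == "Disease"), 25)
  expect_equal(sum(g$nodes$node_type == "Gene"), 100)
  dg <- g$edges[g$edges$predicate == "ASSOCIATES_DaG", ]
  expect_equal(nrow(dg), 200)
  n_tm <- sum(dg$source_type == "textmining")
  expect_lt(abs(n_tm - 100), 3 * sqrt(200 * 0.25) + 1)

  # exact-fraction mode pins the count
  ge <- simulate_graph(graph_spec(n_diseases = 25, n_genes = 100,
    assoc_per_disease = 8, fraction_textmining = 0.5,
    exact_fractions = TRUE, seed = 80))
  dge <- ge$edges[ge$edges$predicate == "ASSOCIATES_DaG", ]
  expect_equal(sum(dge$source_type == "textmining"), 100)

  # evidence distributions: p-values in (0, 0.05], z-scores finite
  ps <- vapply(dg$evidence, function(e) e$p_value, numeric(1))
  expect_true(all(ps > 0 & ps <= 0.05))
})

test_that("a diseaseless spec yields a graph without disease-incident edges", {
  g <- simulate_graph(graph_spec(n_diseases = 0, seed = 81))
  expect_equal(sum(g$nodes$node_type == "Disease"), 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("infeasible densities are rejected", {
  expect_error(simulate_graph(graph_spec(n_genes = 5, assoc_per_disease = 10)),
    "Infeasible")
  expect_error(simulate_questions(simulate_graph(graph_spec(
    n_diseases = 2, assoc_per_disease = 2, seed = 82)), "mcq", 500),
    class = "kgrag_generate_error")
})

test_that("True/False sets are balanced and label-consistent with the graph", {
  g <- simulate_graph(graph_spec(seed = 83))
  qs <- simulate_questions(g, "tf", 50, seed = 84)
  expect_equal(sum(qs$correct == "True"), 25)
  expect_equal(sum(qs$correct == "False"), 25)

  # every True assertion is a surviving filtered edge; every False one is not
  pool <- association_pool(g, context_filter())
  stmts <- stringr::str_match(qs$text, "^True or False: (.*)\\.$")[, 2]
  is_real <- stmts %in% pool$sentence
  expect_identical(is_real, qs$correct == "True")
})

test_that("MCQ distractors are unlinked and never equal the answer", {
  g <- simulate_graph(graph_spec(seed = 85))
  qs <- simulate_questions(g, "mcq", 30, seed = 86)
  pool <- association_pool(g, context_filter())
  linked <- split(pool$gene_name, pool$disease_name)
  for (i in seq_len(nrow(qs))) {
    d <- stringr::str_match(qs$text[i], "Disease (.*)\\? Given")[, 2]
    opts <- qs$options[[i]]
    expect_length(opts, 5)
    expect_true(qs$correct[i] %in% opts)
    distractors <- setdiff(opts, qs$correct[i])
    expect_length(distractors, 4)
    expect_false(any(distractors %in% linked[[d]]))
    expect_true(qs$correct[i] %in% linked[[d]])
  }
})

test_that("retrieval truth sets match the filtered neighborhood exactly", {
  g <- simulate_graph(graph_spec(seed = 87))
  qs <- simulate_questions(g, "retrieval", 15, seed = 88)
  for (i in seq_len(nrow(qs))) {
    ents <- extract_disease_entities(qs$text[i],
      dictionary_extractor(g$nodes$name[g$nodes$node_type == "Disease"]))
    node <- find_nodes_by_name(g, "Disease", ents$diseases[1])
    tr <- neighborhood(g, node$node_id)
    genes <- tr$neighbor_name[tr$neighbor_type == "Gene"]
    expect_setequal(qs$truth_set[[i]], genes)
  }
})

test_that("question generation is reproducible under a fixed seed", {
  g <- simulate_graph(graph_spec(seed = 89))
  a <- simulate_questions(g, "mcq", 10, seed = 90)
  b <- simulate_questions(g, "mcq", 10, seed = 90)
  expect_identical(a, b)
})
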