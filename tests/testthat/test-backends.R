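test_that("the echo backend returns exactly the context block", {
  g <- simulate_graph(graph_spec(seed = 18))
  emb <- reference_embedder()
  idx <- disease_name_index(g, emb)
  be <- mock_backend("echo")
  ans <- answer_question(
    "Which Genes show an association with the Disease Hypertension?",
    g, be, embedder = emb, disease_index = idx, pruning = NULL,
    include_provenance = TRUE)
  expect_equal(ans$status, "ok")
  for (s in ans$prompt$contexts$text) {
    expect_true(grepl(s, ans$text, fixed = TRUE))
  }
})

test_that("cited provenance is always drawn from the supplied context", {
  g <- simulate_graph(graph_spec(seed = 18))
  emb <- reference_embedder()
  idx <- disease_name_index(g, emb)
  be <- mock_backend("echo")
  qs <- simulate_questions(g, "retrieval", 12, seed = 19)
  for (q in qs$text) {
    ans <- answer_question(q, g, be, embedder = emb, disease_index = idx,
      pruning = NULL, include_provenance = TRUE)
    pool <- unique(unlist(ans$prompt$contexts$provenance))
    expect_true(all(ans$cited_provenance %in% pool))
    expect_gt(length(ans$cited_provenance), 0)  # echo repeats the clauses
  }
})

test_that("the TF-lookup mock answers True exactly when the assertion is in context", {
  g <- simulate_graph(graph_spec(seed = 18))
  emb <- reference_embedder()
  idx <- disease_name_index(g, emb)
  tpl <- prompt_template("json_tf")
  be <- mock_backend("tf-lookup", tpl)
  qs <- simulate_questions(g, "tf", 20, seed = 23)
  ev <- evaluate_questions(qs, function(t) {
    answer_question(t, g, be, embedder = emb, disease_index = idx,
      template = tpl, pruning = NULL)
  })
  expect_true(all(ev$correct))
  expect_equal(attr(ev, "n_unparseable"), 0L)
})

test_that("the MCQ-lookup mock finds the one option present in context", {
  g <- simulate_graph(graph_spec(seed = 18))
  emb <- reference_embedder()
  idx <- disease_name_index(g, emb)
  tpl <- prompt_template("json_mcq")
  be <- mock_backend("mcq-lookup", tpl)
  qs <- simulate_questions(g, "mcq", 15, seed = 24)
  ev <- evaluate_questions(qs, function(t) {
    answer_question(t, g, be, embedder = emb, disease_index = idx,
      template = tpl, pruning = NULL)
  })
  expect_true(all(ev$correct))
})

test_that("an empty graph yields an explicit no-context answer", {
  g <- kg_graph(
    tibble::tibble(node_id = character(), node_type = character(),
      name = character()),
    tibble::tibble(subject_id = character(), predicate = character(),
      object_id = character()))
  ans <- answer_question("Anything?", g, mock_backend("echo"))
  expect_s3_class(ans, "kg_answer")
  expect_equal(ans$status, "no_context")
  expect_equal(ans$token_usage, 0L)

  # strict mode: linked node but nothing survives pruning
  g2 <- golden_graph()
  ans2 <- answer_question("completely unrelated words qqq", g2,
    mock_backend("echo"),
    pruning = pruning_config(min_similarity = 0.99), strict = TRUE)
  expect_equal(ans2$status, "no_context")
})

test_that("end-to-end answers are identical across repeated runs", {
  g <- simulate_graph(graph_spec(seed = 18))
  emb <- reference_embedder()
  idx <- disease_name_index(g, emb)
  tpl <- prompt_template("json_mcq")
  be <- mock_backend("mcq-lookup", tpl)
  q <- simulate_questions(g, "mcq", 1, seed = 25)$text[1]
  run <- function() {
    answer_question(q, g, be, embedder = emb, disease_index = idx,
      template = tpl, pruning = pruning_config(min_similarity = 0))
  }
  a <- run(); b <- run()
  expect_identical(a$text, b$text)
  expect_identical(a$prompt$rendered_text, b$prompt$rendered_text)
  expect_identical(a$token_usage, b$token_usage)
})

test_that("structured answers parse letters, text and malformed output sensibly", {
  expect_equal(parse_structured_answer('{"answer": "True"}', "json_tf"), TRUE)
  expect_equal(parse_structured_answer('{"answer": "false"}', "json_tf"), FALSE)
  expect_null(parse_structured_answer('{"answer": "maybe"}', "json_tf"))
  expect_null(parse_structured_answer("no json here", "json_tf"))
  expect_equal(
    parse_structured_answer('The answer is {"answer": "VHL"} indeed.', "json_mcq"),
    "VHL")
})
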