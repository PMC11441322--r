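test_that("retrieve_context unions verbalized neighborhoods per matched node", {
  g <- filter_fixture_graph()
  matches <- tibble::tibble(node_id = "d1")
  ctx <- retrieve_context(g, matches)
  expect_equal(nrow(ctx), 3)
  expect_true(all(ctx$entity_node_id == "d1"))
  expect_true(all(nzchar(ctx$sentence)))

  # a matched node with an empty filtered neighborhood contributes nothing
  ctx2 <- retrieve_context(g, tibble::tibble(node_id = c("d1", "i1")))
  expect_equal(nrow(ctx2), 3)
  # two matched nodes concatenate their contributions
  ctx3 <- retrieve_context(g, tibble::tibble(node_id = c("d1", "g2")))
  expect_equal(nrow(ctx3), 4)
  expect_equal(unique(ctx3$entity_node_id), c("d1", "g2"))

  expect_error(retrieve_context(g, tibble::tibble(node_id = character())),
    class = "kgrag_link_error")
  expect_error(retrieve_context(g, tibble::tibble(node_id = "zz")),
    class = "kgrag_lookup_error")
})

test_that("pruning matches the independent brute-force oracle on 500 random instances", {
  emb <- reference_embedder()
  cfg <- pruning_config()
  withr::with_seed(73, {
    for (trial in seq_len(500)) {
      n <- sample(1:20, 1)
      ctx <- random_contexts(n, n_groups = sample(1:3, 1))
      prompt <- random_prompt()
      got <- prune_context(prompt, ctx, emb, cfg)
      want <- oracle_prune(prompt, ctx, emb, 75, 0.5, 150)
      expect_identical(got$sentence, want$sentence)
      expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
    }
  })
})

test_that("the floor dominates: nothing below 0.5 survives any percentile", {
  emb <- reference_embedder()
  # sentences sharing no trigram with the prompt have similarity ~ 0
  ctx <- tibble::tibble(
    sentence = c("zzz qqq vvv", "www uuu kkk", "jjj fff bbb"),
    entity_node_id = "d1")
  out <- prune_context("hypertension gene", ctx, emb,
    pruning_config(percentile = 0, min_similarity = 0.5))
  expect_equal(nrow(out), 0)
  # and the empty input stays empty
  expect_equal(nrow(prune_context("x", ctx[0, ], emb)), 0)
})

test_that("pruning respects the cap and both monotonicities", {
  emb <- reference_embedder()
  withr::with_seed(74, {
    ctx <- random_contexts(18, n_groups = 2)
    prompt <- random_prompt()
    loose <- pruning_config(percentile = 25, min_similarity = -1,
      context_volume = 5)
    out <- prune_context(prompt, ctx, emb, loose)
    expect_lte(nrow(out), 5)

    # raising the floor or the percentile never adds a sentence
    for (trial in 1:20) {
      ctx <- random_contexts(sample(4:16, 1))
      prompt <- random_prompt()
      base <- prune_context(prompt, ctx, emb,
        pruning_config(percentile = 50, min_similarity = 0.2))
      higher_floor <- prune_context(prompt, ctx, emb,
        pruning_config(percentile = 50, min_similarity = 0.4))
      higher_pct <- prune_context(prompt, ctx, emb,
        pruning_config(percentile = 80, min_similarity = 0.2))
      expect_true(all(higher_floor$sentence %in% base$sentence))
      expect_true(all(higher_pct$sentence %in% base$sentence))
      # raising the volume never removes one
      small <- prune_context(prompt, ctx, emb,
        pruning_config(percentile = 50, min_similarity = 0.2,
          context_volume = 3))
      expect_true(all(small$sentence %in% base$sentence))
      expect_lte(nrow(small), 3)
    }
  })
})

test_that("with one entity the strict-greater rule keeps at most the top quarter plus ties", {
  emb <- reference_embedder()
  withr::with_seed(75, {
    for (trial in 1:25) {
      n <- sample(4:20, 1)
      ctx <- random_contexts(n, n_groups = 1)
      out <- prune_context(random_prompt(), ctx, emb,
        pruning_config(min_similarity = -1))
      expect_lte(nrow(out), ceiling(0.25 * n) + 1)
    }
  })
})

test_that("pruned output is invariant under lower-casing the prompt", {
  emb <- reference_embedder()
  g <- simulate_graph(graph_spec(seed = 8))
  ctx <- retrieve_context(g, tibble::tibble(node_id = "d0001"))
  prompt <- "Which Genes show an association with the Disease Hypertension?"
  a <- prune_context(prompt, ctx, emb, pruning_config(min_similarity = 0.1))
  b <- prune_context(tolower(prompt), ctx, emb,
    pruning_config(min_similarity = 0.1))
  expect_identical(a$sentence, b$sentence)
})

test_that("the context-volume sweep is monotone and plateaus", {
  g <- simulate_graph(graph_spec(seed = 14))
  qs <- simulate_questions(g, "retrieval", 20, seed = 15)
  sweep <- sweep_context_volume(qs, g, volumes = c(0, 1, 2, 5, 10, 50, 100))
  expect_s3_class(sweep, "kg_sweep")
  # volume 0 retrieves nothing, and every truth set is non-empty
  expect_equal(sweep$mean_jaccard[sweep$context_volume == 0], 0)
  # non-decreasing in volume
  expect_true(all(diff(sweep$mean_jaccard) >= -1e-12))
  # once the volume exceeds all surviving context the curve is flat
  expect_equal(sweep$mean_jaccard[sweep$context_volume == 50],
    sweep$mean_jaccard[sweep$context_volume == 100])
  expect_error(sweep_context_volume(qs[0, ], g, volumes = 10),
    class = "kgrag_benchmark_error")
  expect_s3_class(autoplot(sweep), "ggplot")
})
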