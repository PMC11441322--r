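test_that("question sets round-trip through JSON and are validated on load", {
  g <- simulate_graph(graph_spec(seed = 33))
  dir <- withr::local_tempdir()

  empty_path <- file.path(dir, "empty.json")
  writeLines("[]", empty_path)
  expect_equal(nrow(read_questions(empty_path)), 0)

  qs <- simulate_questions(g, "mcq", 20, seed = 34)
  path <- file.path(dir, "mcq.json")
  write_questions(qs, path)
  back <- read_questions(path, kind = "mcq")
  expect_equal(nrow(back), 20)
  expect_equal(back$question_id, qs$question_id)
  expect_equal(back$options, qs$options)
  expect_equal(back$correct, qs$correct)

  # an MCQ record without exactly 5 options is rejected
  bad <- qs
  bad$options[[3]] <- bad$options[[3]][1:4]
  bad_path <- file.path(dir, "bad.json")
  write_questions(bad, bad_path)
  expect_error(read_questions(bad_path), "5", class = "kgrag_load_error")

  # retrieval records must carry ground truth
  r <- simulate_questions(g, "retrieval", 5, seed = 35)
  r$truth_set[[2]] <- character()
  rp <- file.path(dir, "ret.json")
  write_questions(r, rp)
  expect_error(read_questions(rp), class = "kgrag_load_error")
})

test_that("evaluation scores option letters, option text and garbage correctly", {
  qs <- tibble::tibble(
    question_id = c("q1", "q2", "q3", "q4"),
    kind = "mcq",
    text = c("t1", "t2", "t3", "t4"),
    options = list(c("A1", "B1", "C1", "D1", "E1"))[rep(1, 4)],
    correct = "C1",
    truth_set = list(character())[rep(1, 4)]
  )
  answers <- c("c1", "C", "E1", "not an option")
  i <- 0
  ev <- suppressMessages(evaluate_questions(qs, function(t) {
    i <<- i + 1
    answers[i]
  }))
  expect_equal(ev$correct, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(ev, "n_unparseable"), 1L)
  expect_equal(nrow(suppressMessages(evaluate_questions(qs[0, ], identity))), 0)
})

test_that("a fixed-position answerer scores at chance on shuffled MCQs", {
  g <- simulate_graph(graph_spec(n_diseases = 60, n_genes = 300,
    assoc_per_disease = 12, fraction_textmining = 0.2,
    exact_fractions = TRUE, seed = 36))
  qs <- simulate_questions(g, "mcq", 500, seed = 37)
  ev <- evaluate_questions(qs, function(t) {
    # always pick the first listed option
    stringr::str_split(stringr::str_match(t, "Given list is: (.*)\\.$")[, 2],
      ", ")[[1]][1]
  })
  acc <- mean(ev$correct)
  expect_lt(abs(acc - 0.2), 3 * sqrt(0.2 * 0.8 / 500))
})

test_that("bootstrap accuracy reproduces and concentrates where it should", {
  all_right <- rep(TRUE, 40)
  bs <- bootstrap_accuracy(all_right, sample_size = 150, iterations = 200,
    seed = 7)
  expect_true(all(bs$accuracies == 1))
  expect_equal(bs$std, 0)

  # fixed seed, bit-identical distribution
  v <- withr::with_seed(38, sample(c(TRUE, FALSE), 500, replace = TRUE,
    prob = c(0.6, 0.4)))
  b1 <- bootstrap_accuracy(v, seed = 99)
  b2 <- bootstrap_accuracy(v, seed = 99)
  expect_identical(b1$accuracies, b2$accuracies)
  expect_false(identical(b1$accuracies,
    bootstrap_accuracy(v, seed = 100)$accuracies))

  # the bootstrap mean tracks the point accuracy
  expect_lt(abs(b1$mean - mean(v)), 3 * sqrt(0.6 * 0.4 / 150))
  expect_error(bootstrap_accuracy(logical()), class = "kgrag_benchmark_error")

  expect_equal(nrow(tidy(b1)), 1000)
  expect_equal(glance(b1)$iterations, 1000)
  expect_s3_class(autoplot(b1), "ggplot")
})

test_that("jaccard handles the boundary cases and random set pairs", {
  expect_equal(jaccard(c("x", "y"), c("y", "z")), 1 / 3)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(), character()), 1)
  expect_equal(jaccard(character(), "a"), 0)
  withr::with_seed(39, {
    for (i in 1:50) {
      a <- sample(letters, sample(0:10, 1))
      b <- sample(letters, sample(0:10, 1))
      expect_equal(jaccard(a, b), jaccard(b, a))
      expect_gte(jaccard(a, b), 0)
      expect_lte(jaccard(a, b), 1)
    }
  })
})

test_that("lowercase perturbation is idempotent and count-preserving", {
  g <- simulate_graph(graph_spec(seed = 40))
  qs <- simulate_questions(g, "retrieval", 10, seed = 41)
  p1 <- perturb_lowercase(qs)
  expect_equal(nrow(p1), nrow(qs))
  expect_equal(p1$question_id, qs$question_id)
  expect_identical(perturb_lowercase(p1)$text, p1$text)
  expect_identical(p1$text, tolower(qs$text))

  # entity-substring mode touches only the named entities
  q <- tibble::tibble(question_id = "a", kind = "retrieval",
    text = "Does VHL associate with Hypertension?",
    options = list(character()), correct = NA_character_,
    truth_set = list("VHL"))
  out <- perturb_lowercase(q, entities = "Hypertension")
  expect_equal(out$text, "Does VHL associate with hypertension?")
})

test_that("token usage reports mean and SEM per system", {
  qs <- tibble::tibble(question_id = c("a", "b", "c"), kind = "retrieval",
    text = c("q1", "q2", "q3"), options = list(character())[rep(1, 3)],
    correct = NA_character_, truth_set = list("x")[rep(1, 3)])
  counts <- c(10, 20, 30)
  i <- 0
  rep <- token_usage_report(qs, list(fixed = function(q) {
    i <<- i + 1
    counts[i]
  }))
  expect_equal(rep$summary$mean_tokens, 20)
  expect_equal(rep$summary$sem, sd(counts) / sqrt(3), tolerance = 1e-9)
  expect_equal(rep$summary$sem, 5.7735, tolerance = 1e-3)
  expect_error(token_usage_report(qs[0, ], list(s = identity)),
    class = "kgrag_benchmark_error")
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("semantic retrieval is case-invariant while exact matching collapses", {
  g <- simulate_graph(graph_spec(seed = 42))
  qs <- simulate_questions(g, "retrieval", 30, seed = 43)

  sem <- retrieval_accuracy(qs, semantic_retriever(g), system_name = "semantic")
  expect_equal(sem$accuracy_original, sem$accuracy_perturbed)
  expect_equal(sem$accuracy_original, 1)

  exact <- retrieval_accuracy(qs, exact_match_retriever(g),
    system_name = "exact")
  expect_equal(exact$accuracy_original, 1)
  # no generated graph name is all-lower-case, so lower-casing kills it
  expect_equal(exact$accuracy_perturbed, 0)

  expect_equal(nrow(tidy(sem)), 30)
  expect_s3_class(autoplot(exact), "ggplot")

  # overlap mode is at least as permissive as subset mode
  sem_overlap <- retrieval_accuracy(qs, semantic_retriever(g), mode = "overlap")
  expect_gte(sem_overlap$accuracy_original, sem$accuracy_original)
})
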