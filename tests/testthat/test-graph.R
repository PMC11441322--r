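test_that("an empty graph loads and queries cleanly", {
  g <- kg_graph(
    tibble::tibble(node_id = character(), node_type = character(),
      name = character()),
    tibble::tibble(subject_id = character(), predicate = character(),
      object_id = character())
  )
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$edges), 0)
  expect_equal(nrow(find_nodes_by_name(g, "Disease", "anything")), 0)
})

test_that("construction enforces the record invariants", {
  nodes <- tibble::tibble(
    node_id = c("a", "a"), node_type = c("Disease", "Disease"),
    name = c("X", "Y"))
  expect_error(kg_graph(nodes, tibble::tibble(subject_id = character(),
    predicate = character(), object_id = character())),
    '"a"', class = "kgrag_load_error")

  nodes <- tibble::tibble(node_id = "d1", node_type = "Disease", name = "X")
  edges <- tibble::tibble(subject_id = "d1", predicate = "ASSOCIATES_DaG",
    object_id = "X99")
  expect_error(kg_graph(nodes, edges), "X99", class = "kgrag_load_error")

  nodes <- tibble::tibble(node_id = c("d1", "g1"),
    node_type = c("Disease", "Gene"), name = c("X", "Y"))
  expect_error(
    kg_graph(nodes, tibble::tibble(subject_id = "d1",
      predicate = "associates_dag", object_id = "g1")),
    class = "kgrag_schema_error")
  # predicate type initials must agree with the endpoint node types
  expect_error(
    kg_graph(nodes, tibble::tibble(subject_id = "g1",
      predicate = "ASSOCIATES_DaG", object_id = "d1")),
    class = "kgrag_load_error")
})

test_that("name lookup is case-insensitive, typed and deterministic", {
  g <- filter_fixture_graph()
  hit <- find_nodes_by_name(g, "Disease", "hypertension")
  expect_equal(hit$node_id, "d1")
  expect_equal(find_nodes_by_name(g, "Disease", "HYPERTENSION")$node_id, "d1")
  expect_equal(nrow(find_nodes_by_name(g, "Gene", "Hypertension")), 0)
  expect_equal(nrow(find_nodes_by_name(g, "NoSuchType", "x")), 0)
  expect_equal(nrow(find_nodes_by_name(g, "Disease", "absent")), 0)
})

test_that("neighborhood applies the default quality filters to hand-counts", {
  g <- filter_fixture_graph()
  tr <- neighborhood(g, "d1")
  # phase-3 treatment + curated protein + curated disease-gene edge
  expect_equal(nrow(tr), 3)
  expect_setequal(tr$neighbor_name, c("DrugB", "ProtCur", "GeneCur"))
  # stored orientation is preserved: the treatment edge keeps Compound as subject
  treat <- tr[tr$predicate == "TREATS_CtD", ]
  expect_equal(treat$subject_name, "DrugB")
  expect_equal(treat$object_name, "Hypertension")
  # deterministic ordering by predicate then neighbor id
  expect_equal(tr$predicate, sort(tr$predicate))

  expect_error(neighborhood(g, "nope"), "nope", class = "kgrag_lookup_error")
})

test_that("each filter dial controls exactly its edge class", {
  g <- filter_fixture_graph()
  expect_equal(nrow(neighborhood(g, "d1", permissive_filter())), 6)
  expect_setequal(
    neighborhood(g, "d1", context_filter(min_clinical_phase = 0))$neighbor_name,
    c("DrugA", "DrugB", "ProtCur", "GeneCur"))
  expect_setequal(
    neighborhood(g, "d1",
      context_filter(require_curated_protein = FALSE))$neighbor_name,
    c("DrugB", "ProtCur", "ProtRaw", "GeneCur"))
  expect_setequal(
    neighborhood(g, "d1",
      context_filter(exclude_textmining_disease_gene = FALSE))$neighbor_name,
    c("DrugB", "ProtCur", "GeneTM", "GeneCur"))
  # an isolated node has an empty neighborhood
  expect_equal(nrow(neighborhood(g, "i1", permissive_filter())), 0)
})

test_that("relaxing any single filter never reduces the triple count", {
  g <- simulate_graph(graph_spec(seed = 11))
  diseases <- g$nodes$node_id[g$nodes$node_type == "Disease"]
  base <- context_filter()
  for (id in diseases[1:8]) {
    n0 <- nrow(neighborhood(g, id, base))
    expect_gte(nrow(neighborhood(g, id, context_filter(min_clinical_phase = 0))), n0)
    expect_gte(nrow(neighborhood(g, id,
      context_filter(require_curated_protein = FALSE))), n0)
    expect_gte(nrow(neighborhood(g, id,
      context_filter(exclude_textmining_disease_gene = FALSE))), n0)
  }
})

test_that("a permissive neighborhood equals the brute-force incident scan", {
  withr::with_seed(7, {
    for (trial in 1:4) {
      g <- simulate_graph(graph_spec(
        n_diseases = 6, n_genes = 25, n_compounds = 10, n_proteins = 10,
        assoc_per_disease = 4, treats_per_disease = 2, protein_per_disease = 2,
        seed = 100 + trial))
      ids <- sample(g$nodes$node_id, 50, replace = TRUE)
      for (id in ids) {
        got <- neighborhood(g, id, permissive_filter())
        want <- g$edges[g$edges$subject_id == id | g$edges$object_id == id, ]
        expect_equal(nrow(got), nrow(want))
        expect_setequal(
          paste(got$subject_id, got$predicate, got$object_id),
          paste(want$subject_id, want$predicate, want$object_id))
      }
    }
  })
})

test_that("write then read round-trips node and edge multisets (TSV and JSONL)", {
  g <- simulate_graph(graph_spec(n_diseases = 5, n_genes = 15, n_compounds = 6,
    n_proteins = 6, assoc_per_disease = 3, treats_per_disease = 2,
    protein_per_disease = 1, seed = 5))
  for (fmt in c("tsv", "jsonl")) {
    ext <- if (fmt == "tsv") "tsv" else "jsonl"
    np <- withr::local_tempfile(fileext = paste0(".", ext))
    ep <- withr::local_tempfile(fileext = paste0(".", ext))
    write_graph(g, np, ep, format = fmt)
    g2 <- read_graph(np, ep)
    expect_equal(nrow(g2$nodes), nrow(g$nodes))
    expect_equal(nrow(g2$edges), nrow(g$edges))
    expect_setequal(g2$nodes$node_id, g$nodes$node_id)
    expect_setequal(
      paste(g2$edges$subject_id, g2$edges$predicate, g2$edges$object_id),
      paste(g$edges$subject_id, g$edges$predicate, g$edges$object_id))
    # attributes and evidence survive
    o <- order(g$edges$subject_id, g$edges$predicate, g$edges$object_id)
    o2 <- order(g2$edges$subject_id, g2$edges$predicate, g2$edges$object_id)
    ev <- g$edges$evidence[o]
    ev2 <- g2$edges$evidence[o2]
    has <- which(!vapply(ev, is.null, logical(1)))
    expect_equal(
      vapply(ev[has], function(e) e$p_value, numeric(1)),
      vapply(ev2[has], function(e) as.numeric(e$p_value), numeric(1)),
      tolerance = 1e-9)
    pr <- find_nodes_by_name(g2, "Protein", g$nodes$name[g$nodes$node_type == "Protein"][1])
    expect_type(pr$attributes[[1]]$curated, "logical")
  }
})
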