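# Fixture graphs and independent oracles used across the suite.

# The worked verbalization fixture: node types stored with the exact casing
# the golden sentence uses ("disease" lower-case, "Gene" capitalized).
golden_graph <- function() {
  kg_graph(
    nodes = tibble::tibble(
      node_id = c("d1", "g1"),
      node_type = c("disease", "Gene"),
      name = c("hypertension", "VHL")
    ),
    edges = tibble::tibble(
      subject_id = "d1", predicate = "ASSOCIATES_DaG", object_id = "g1",
      provenance = list("GWAS Catalog"),
      evidence = list(list(p_value = 0.001, z_score = 4.2))
    )
  )
}

# Hand-countable filter fixture centred on one disease:
#   - TREATS_CtD at clinical phase 2 (dropped by default filter)
#   - TREATS_CtD at clinical phase 3 (kept)
#   - ASSOCIATES_DaP to a curated protein (kept)
#   - ASSOCIATES_DaP to an uncurated protein (dropped)
#   - ASSOCIATES_DaG with source_type "textmining" (dropped)
#   - ASSOCIATES_DaG with source_type "curated" (kept)
# Default-filter survivor count: 3.
filter_fixture_graph <- function() {
  nodes <- tibble::tibble(
    node_id = c("d1", "c1", "c2", "p1", "p2", "g1", "g2", "i1"),
    node_type = c("Disease", "Compound", "Compound", "Protein", "Protein",
      "Gene", "Gene", "Symptom"),
    name = c("Hypertension", "DrugA", "DrugB", "ProtCur", "ProtRaw",
      "GeneTM", "GeneCur", "Isolated"),
    attributes = list(list(), list(), list(), list(curated = TRUE),
      list(curated = FALSE), list(), list(), list())
  )
  edges <- tibble::tibble(
    subject_id = c("c1", "c2", "d1", "d1", "d1", "d1"),
    predicate = c("TREATS_CtD", "TREATS_CtD", "ASSOCIATES_DaP",
      "ASSOCIATES_DaP", "ASSOCIATES_DaG", "ASSOCIATES_DaG"),
    object_id = c("d1", "d1", "p1", "p2", "g1", "g2"),
    provenance = list("ChEMBL", "ChEMBL", "UniProt", "UniProt",
      "SemMedDB", "GWAS Catalog"),
    evidence = list(NULL, NULL, NULL, NULL, NULL,
      list(p_value = 0.01, z_score = 3.5)),
    clinical_phase = c(2L, 3L, NA, NA, NA, NA),
    source_type = c(NA, NA, NA, NA, "textmining", "curated")
  )
  kg_graph(nodes, edges)
}

# Independent brute-force cosine similarity: embeds with the package embedder
# but ranks with its own arithmetic (full scan, explicit dot products).
oracle_scan <- function(index, text, k, emb) {
  qv <- embed_texts(emb, text)[1, ]
  sims <- vapply(seq_len(nrow(index$entries)), function(i) {
    sum(index$vectors[i, ] * qv)
  }, numeric(1))
  ord <- order(-sims, index$entries$id)
  ord[seq_len(min(k, length(ord)))]
}

# Independent pruning oracle: sorts similarities, computes the
# linear-interpolation percentile by hand, applies strict-greater + floor per
# entity group, pools, sorts, caps.
oracle_prune <- function(prompt, contexts, emb, percentile = 75,
                         min_sim = 0.5, volume = 150) {
  if (nrow(contexts) == 0) return(contexts[0, ])
  pv <- embed_texts(emb, prompt)[1, ]
  sims <- as.numeric(embed_texts(emb, contexts$sentence) %*% pv)
  contexts$similarity <- sims
  kept <- lapply(split(seq_len(nrow(contexts)), contexts$entity_node_id),
    function(rows) {
      s <- sort(sims[rows])
      n <- length(s)
      h <- (n - 1) * percentile / 100
      lo <- floor(h)
      thr <- if (lo + 1 >= n) s[n] else s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
      rows[sims[rows] > thr & sims[rows] >= min_sim]
    })
  kept <- unlist(kept, use.names = FALSE)
  out <- contexts[kept, ]
  out <- out[order(-out$similarity, out$sentence), ]
  utils::head(out, volume)
}

# Random context-sentence sets for oracle trials: words drawn from a small
# vocabulary so prompt-sentence similarities spread over a wide range.
random_contexts <- function(n_sentences, n_groups = 1) {
  vocab <- c("disease", "gene", "protein", "compound", "associates", "treats",
    "hypertension", "asthma", "migraine", "psoriasis", "kinase", "receptor",
    "pathway", "mutation", "variant", "expression", "binds", "inhibits")
  sentences <- vapply(seq_len(n_sentences), function(i) {
    paste(sample(vocab, sample(3:8, 1), replace = TRUE), collapse = " ")
  }, character(1))
  tibble::tibble(
    sentence = sentences,
    entity_node_id = sample(paste0("d", seq_len(n_groups)), n_sentences,
      replace = TRUE)
  )
}

random_prompt <- function() {
  vocab <- c("which", "genes", "are", "associated", "with", "the", "disease",
    "hypertension", "asthma", "migraine", "treats", "compound", "protein")
  paste(sample(vocab, sample(4:9, 1), replace = TRUE), collapse = " ")
}

# Uniform-random schema-valid predicate specs for round-trip checks.
random_predicate_spec <- function() {
  word <- function() {
    paste(sample(LETTERS, sample(3:10, 1), replace = TRUE), collapse = "")
  }
  name <- paste(vapply(seq_len(sample(1:3, 1)), function(i) word(),
    character(1)), collapse = "_")
  types <- c("Disease", "Gene", "Protein", "Compound", "Symptom", "Anatomy",
    "Food", "Variant")
  list(name = name, subject_type = sample(types, 1), object_type = sample(types, 1))
}
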