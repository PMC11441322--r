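#' Specification for a synthetic SPOKE-like graph
#'
#' Describes the shape of a generated property graph: node counts per type,
#' how many associations of each kind every disease carries, the fraction of
#' Disease-Gene edges derived from text mining, the fraction of curated
#' proteins, the clinical-phase distribution of treatment edges, and the
#' evidence distribution (p-values uniform on (0, 0.05]; z-scores normal).
#'
#' The first few nodes of each type take names from small built-in pools of
#' real disease/gene/compound names (including `"Hypertension"` and
#' `"VHL"`), the rest are numbered (`"Disease_0013"`). All generated names
#' are mixed-case, which is what gives the lower-casing robustness probe its
#' bite against exact-string matching.
#'
#' @param n_diseases,n_genes,n_compounds,n_proteins Node counts.
#' @param assoc_per_disease Disease-Gene association edges per disease.
#' @param treats_per_disease Compound-treats-Disease edges per disease.
#' @param protein_per_disease Disease-Protein association edges per disease.
#' @param fraction_textmining Fraction of Disease-Gene edges with
#'   `source_type = "textmining"`.
#' @param fraction_curated_proteins Fraction of Protein nodes flagged
#'   curated.
#' @param clinical_phase_probs Probability weights over phases 0-4 for
#'   treatment edges.
#' @param z_mean,z_sd Normal parameters for edge z-scores.
#' @param exact_fractions Draw textmining/curated flags as exact rounded
#'   counts instead of independent Bernoulli draws.
#' @param disease_names,gene_names,compound_names Name pools used before
#'   numbered names kick in.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `kg_graph_spec`.
#' @export
graph_spec <- function(n_diseases = 20L, n_genes = 120L, n_compounds = 40L,
                       n_proteins = 40L,
                       assoc_per_disease = 8L, treats_per_disease = 3L,
                       protein_per_disease = 2L,
                       fraction_textmining = 0.2,
                       fraction_curated_proteins = 0.7,
                       clinical_phase_probs = c(0.1, 0.1, 0.2, 0.3, 0.3),
                       z_mean = 4, z_sd = 2,
                       exact_fractions = FALSE,
                       disease_names = default_disease_names(),
                       gene_names = default_gene_names(),
                       compound_names = default_compound_names(),
                       seed = 42L) {
  stopifnot(
    n_diseases >= 0, n_genes >= 0, n_compounds >= 0, n_proteins >= 0,
    assoc_per_disease >= 0, treats_per_disease >= 0, protein_per_disease >= 0,
    fraction_textmining >= 0, fraction_textmining <= 1,
    fraction_curated_proteins >= 0, fraction_curated_proteins <= 1,
    length(clinical_phase_probs) == 5, all(clinical_phase_probs >= 0),
    sum(clinical_phase_probs) > 0
  )
  structure(
    list(
      n_diseases = as.integer(n_diseases), n_genes = as.integer(n_genes),
      n_compounds = as.integer(n_compounds), n_proteins = as.integer(n_proteins),
      assoc_per_disease = as.integer(assoc_per_disease),
      treats_per_disease = as.integer(treats_per_disease),
      protein_per_disease = as.integer(protein_per_disease),
      fraction_textmining = fraction_textmining,
      fraction_curated_proteins = fraction_curated_proteins,
      clinical_phase_probs = clinical_phase_probs / sum(clinical_phase_probs),
      z_mean = z_mean, z_sd = z_sd,
      exact_fractions = isTRUE(exact_fractions),
      disease_names = as.character(disease_names),
      gene_names = as.character(gene_names),
      compound_names = as.character(compound_names),
      seed = as.integer(seed)
    ),
    class = "kg_graph_spec"
  )
}

default_disease_names <- function() {
  c("Hypertension", "Asthma", "Bardet-Biedl syndrome", "Parkinson disease",
    "Rheumatoid arthritis", "Multiple sclerosis", "Sickle cell anemia",
    "Cystic fibrosis", "Liver benign neoplasm", "Migraine", "Psoriasis",
    "Type 2 diabetes mellitus")
}

default_gene_names <- function() {
  c("VHL", "TP53", "BRCA1", "CFTR", "HBB", "PNPLA3", "HLA-B", "APOE",
    "EGFR", "LRRK2", "IL6", "TNF")
}

default_compound_names <- function() {
  c("Metformin", "Lisinopril", "Albuterol", "Setmelanotide", "Ibuprofen",
    "Hydroxyurea", "Levodopa", "Methotrexate")
}

make_names <- function(pool, prefix, n) {
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, sprintf("%s_%04d", prefix, seq.int(length(pool) + 1L, n)))
}

pick_flags <- function(n, fraction, exact) {
  if (n == 0) return(logical())
  if (exact) {
    k <- round(fraction * n)
    flags <- rep(FALSE, n)
    flags[sample.int(n, k)] <- TRUE
    flags
  } else {
    stats::runif(n) < fraction
  }
}

#' Generate a synthetic SPOKE-like property graph
#'
#' Builds a schema-compliant graph from a [graph_spec()]: Disease, Gene,
#' Compound and Protein nodes; `ASSOCIATES_DaG` edges with provenance,
#' p-value/z-score evidence and a text-mining fraction; `TREATS_CtD` edges
#' with clinical phases; `ASSOCIATES_DaP` edges to (partly curated)
#' proteins. Generation is deterministic for a fixed spec seed.
#'
#' @param spec A [graph_spec()].
#' @return A validated [kg_graph()].
#' @export
simulate_graph <- function(spec = graph_spec()) {
  stopifnot(inherits(spec, "kg_graph_spec"))
  if (spec$assoc_per_disease > spec$n_genes) {
    abort(sprintf("Infeasible spec: %d Disease-Gene edges per disease but only %d genes.",
      spec$assoc_per_disease, spec$n_genes))
  }
  if (spec$treats_per_disease > spec$n_compounds) {
    abort(sprintf("Infeasible spec: %d treatment edges per disease but only %d compounds.",
      spec$treats_per_disease, spec$n_compounds))
  }
  if (spec$protein_per_disease > spec$n_proteins) {
    abort(sprintf("Infeasible spec: %d protein edges per disease but only %d proteins.",
      spec$protein_per_disease, spec$n_proteins))
  }
  withr::with_seed(spec$seed, simulate_graph_impl(spec))
}

simulate_graph_impl <- function(spec) {
  mk_nodes <- function(n, type, pool, id_prefix) {
    if (n == 0) {
      return(tibble(node_id = character(), node_type = character(),
        name = character(), identifier = character(), attributes = list()))
    }
    tibble(
      node_id = sprintf("%s%04d", id_prefix, seq_len(n)),
      node_type = type,
      name = make_names(pool, type, n),
      identifier = sprintf("%s:%04d", toupper(id_prefix), seq_len(n)),
      attributes = rep(list(list()), n)
    )
  }
  diseases <- mk_nodes(spec$n_diseases, "Disease", spec$disease_names, "d")
  genes <- mk_nodes(spec$n_genes, "Gene", spec$gene_names, "g")
  compounds <- mk_nodes(spec$n_compounds, "Compound", spec$compound_names, "c")
  proteins <- mk_nodes(spec$n_proteins, "Protein", character(), "p")
  curated <- pick_flags(spec$n_proteins, spec$fraction_curated_proteins,
    spec$exact_fractions)
  proteins$attributes <- map(seq_len(nrow(proteins)), function(i) {
    list(curated = curated[i])
  })
  nodes <- bind_rows(diseases, genes, compounds, proteins)

  dg_prov_pool <- c("GWAS Catalog", "DisGeNET", "ClinVar", "OMIM")
  td_prov_pool <- c("ChEMBL", "DrugCentral")
  dp_prov_pool <- c("UniProt", "STRING")

  dg <- make_edges(diseases, genes, spec$assoc_per_disease, "ASSOCIATES_DaG")
  if (nrow(dg) > 0) {
    tm <- pick_flags(nrow(dg), spec$fraction_textmining, spec$exact_fractions)
    dg$source_type <- ifelse(tm, "textmining", "curated")
    dg$provenance <- map(ifelse(tm, "SemMedDB", NA), function(x) {
      if (!is.na(x)) x else sample(dg_prov_pool, sample.int(2L, 1L))
    })
    dg$evidence <- map(seq_len(nrow(dg)), function(i) {
      list(p_value = stats::runif(1, 0, 0.05),
        z_score = stats::rnorm(1, spec$z_mean, spec$z_sd))
    })
  }

  td <- make_edges(compounds, diseases, spec$treats_per_disease, "TREATS_CtD",
    per = "object")
  if (nrow(td) > 0) {
    td$clinical_phase <- sample(0:4, nrow(td), replace = TRUE,
      prob = spec$clinical_phase_probs)
    td$provenance <- map(seq_len(nrow(td)), function(i) {
      sample(td_prov_pool, 1L)
    })
  }

  dp <- make_edges(diseases, proteins, spec$protein_per_disease, "ASSOCIATES_DaP")
  if (nrow(dp) > 0) {
    dp$provenance <- map(seq_len(nrow(dp)), function(i) sample(dp_prov_pool, 1L))
  }

  edges <- bind_rows(dg, td, dp)
  kg_graph(nodes, edges)
}

# Draw `k` partners per center node. `per = "subject"` centers on the subject
# side (disease -> partner); `per = "object"` centers on the object side
# (partner -> disease), which keeps TREATS edges stored Compound -> Disease.
make_edges <- function(subjects, objects, k, predicate, per = "subject") {
  centers <- if (per == "subject") subjects else objects
  partners <- if (per == "subject") objects else subjects
  if (nrow(centers) == 0 || nrow(partners) == 0 || k == 0) {
    return(tibble(subject_id = character(), predicate = character(),
      object_id = character()))
  }
  rows <- map(seq_len(nrow(centers)), function(i) {
    pick <- partners$node_id[sample.int(nrow(partners), k)]
    if (per == "subject") {
      tibble(subject_id = centers$node_id[i], predicate = predicate,
        object_id = pick)
    } else {
      tibble(subject_id = pick, predicate = predicate,
        object_id = centers$node_id[i])
    }
  })
  list_rbind(rows)
}

#' Generate benchmark questions matched to a synthetic graph
#'
#' Builds question sets whose ground truth is consistent with the graph's
#' *filtered* Disease-Gene associations (default [context_filter()]), so the
#' questions exercise exactly the context the retrieval pipeline can see:
#'
#' * `"tf"` — half the questions assert an existing association (labelled
#'   True), half assert a rewired one whose gene is not linked to the
#'   disease (labelled False). Statements are the verbalized triples, asked
#'   as `"True or False: <statement>."`.
#' * `"mcq"` — `"Out of the given list, which Gene is associated with the
#'   Disease <name>? Given list is: ..."` with the linked gene and four
#'   same-type distractors not linked to that disease, in shuffled order.
#' * `"retrieval"` — phrasings from a small template bank naming the disease
#'   verbatim; `truth_set` is the disease's full set of filtered associated
#'   gene names.
#'
#' @param graph A [kg_graph()].
#' @param kind `"tf"`, `"mcq"` or `"retrieval"`.
#' @param n_questions Number of questions.
#' @param seed Integer seed.
#' @param filter The [context_filter()] defining which associations count as
#'   ground truth.
#' @return A validated question tibble (see [read_questions()]).
#' @export
simulate_questions <- function(graph, kind = c("tf", "mcq", "retrieval"),
                               n_questions, seed = 1L,
                               filter = context_filter()) {
  kind <- match.arg(kind)
  stopifnot(inherits(graph, "kg_graph"), n_questions >= 1)
  pool <- association_pool(graph, filter)
  withr::with_seed(as.integer(seed), {
    switch(kind,
      tf = simulate_tf(graph, pool, n_questions),
      mcq = simulate_mcq(graph, pool, n_questions),
      retrieval = simulate_retrieval(pool, n_questions)
    )
  })
}

# All filtered Disease-Gene associations, one row per (disease, gene), with
# the verbalized assertion sentence.
association_pool <- function(graph, filter) {
  diseases <- graph$nodes[graph$nodes$node_type == "Disease", ]
  rows <- map(diseases$node_id, function(id) {
    tr <- neighborhood(graph, id, filter = filter)
    tr <- tr[tr$neighbor_type == "Gene", ]
    if (nrow(tr) == 0) return(NULL)
    tr <- verbalize_triples(tr, abbreviations = graph$abbreviations)
    tibble(
      disease_id = id,
      disease_name = diseases$name[diseases$node_id == id],
      gene_id = tr$neighbor_id, gene_name = tr$neighbor_name,
      sentence = tr$sentence,
      subject_type = tr$subject_type, object_type = tr$object_type,
      predicate = tr$predicate
    )
  })
  list_rbind(keep(rows, function(x) !is.null(x)))
}

require_pool <- function(pool, needed, what) {
  if (nrow(pool) < needed) {
    abort(sprintf(
      "Insufficient associations to generate %s: %d needed but only %d filtered Disease-Gene association(s) exist.",
      what, needed, nrow(pool)), class = "kgrag_generate_error")
  }
}

simulate_tf <- function(graph, pool, n) {
  n_true <- ceiling(n / 2)
  n_false <- n - n_true
  require_pool(pool, n_true + n_false, sprintf("%d True/False questions", n))
  rows <- pool[sample.int(nrow(pool), n_true + n_false), ]
  genes <- graph$nodes[graph$nodes$node_type == "Gene", ]
  linked <- split(pool$gene_id, pool$disease_id)

  stmts <- character(nrow(rows))
  labels <- c(rep("True", n_true), rep("False", n_false))
  for (i in seq_len(nrow(rows))) {
    if (labels[i] == "True") {
      stmts[i] <- rows$sentence[i]
    } else {
      unlinked <- setdiff(genes$node_id, linked[[rows$disease_id[i]]])
      if (length(unlinked) == 0) {
        abort("Cannot rewire a False statement: every gene is linked to this disease.",
          class = "kgrag_generate_error")
      }
      g <- genes[genes$node_id == sample(unlinked, 1L), ]
      fake <- rows[i, ]
      stmts[i] <- paste(fake$subject_type, fake$disease_name,
        tolower(stringr::str_replace_all(
          parse_predicate(fake$predicate)$predicate_name, "_", " ")),
        g$node_type, g$name)
    }
  }
  ord <- sample.int(nrow(rows))
  tibble(
    question_id = sprintf("tf_%04d", seq_len(nrow(rows))),
    kind = "tf",
    text = sprintf("True or False: %s.", stmts[ord]),
    options = rep(list(character()), nrow(rows)),
    correct = labels[ord],
    truth_set = rep(list(character()), nrow(rows))
  )
}

simulate_mcq <- function(graph, pool, n) {
  require_pool(pool, n, sprintf("%d MCQ questions", n))
  rows <- pool[sample.int(nrow(pool), n), ]
  genes <- graph$nodes[graph$nodes$node_type == "Gene", ]
  linked <- split(pool$gene_name, pool$disease_id)
  recs <- map(seq_len(n), function(i) {
    not_linked <- setdiff(genes$name, linked[[rows$disease_id[i]]])
    if (length(not_linked) < 4) {
      abort(sprintf(
        "Insufficient unlinked genes for MCQ distractors: 4 needed, %d available.",
        length(not_linked)), class = "kgrag_generate_error")
    }
    distractors <- sample(not_linked, 4L)
    options <- sample(c(rows$gene_name[i], distractors))
    tibble(
      question_id = sprintf("mcq_%04d", i),
      kind = "mcq",
      text = sprintf(
        "Out of the given list, which Gene is associated with the Disease %s? Given list is: %s.",
        rows$disease_name[i], paste(options, collapse = ", ")),
      options = list(options),
      correct = rows$gene_name[i],
      truth_set = list(character())
    )
  })
  list_rbind(recs)
}

retrieval_templates <- function() {
  c("What are the Genes associated with the Disease %s?",
    "List the Genes that associate with the Disease %s.",
    "Which Genes show an association with the Disease %s?",
    "The Disease %s is associated with which Genes?",
    "Name the Genes linked to the Disease %s.",
    "Give the Gene associations of the Disease %s.")
}

simulate_retrieval <- function(pool, n) {
  per_disease <- pool |>
    group_by(.data$disease_id, .data$disease_name) |>
    summarise(truth = list(unique(.data$gene_name)), .groups = "drop")
  templates <- retrieval_templates()
  combos <- tidyr::expand_grid(d = seq_len(nrow(per_disease)),
    t = seq_along(templates))
  if (n > nrow(combos)) {
    abort(sprintf(
      "Insufficient material for %d retrieval questions: %d diseases x %d templates = %d available.",
      n, nrow(per_disease), length(templates), nrow(combos)),
      class = "kgrag_generate_error")
  }
  pick <- combos[sample.int(nrow(combos), n), ]
  tibble(
    question_id = sprintf("ret_%04d", seq_len(n)),
    kind = "retrieval",
    text = sprintf(templates[pick$t], per_disease$disease_name[pick$d]),
    options = rep(list(character()), n),
    correct = NA_character_,
    truth_set = per_disease$truth[pick$d]
  )
}
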