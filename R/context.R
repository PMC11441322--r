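#' Context pruning configuration
#'
#' Three knobs govern how much graph context flows into the prompt:
#'
#' * `percentile` — per disease node, only sentences whose prompt-context
#'   cosine similarity is *strictly greater* than this percentile of that
#'   node's similarity distribution are kept (default 75). The percentile is
#'   computed by linear interpolation between order statistics.
#' * `min_similarity` — an absolute similarity floor applied alongside the
#'   percentile rule (default 0.5).
#' * `context_volume` — the global cap on how many context sentences may
#'   flow into the prompt, applied after pooling across disease nodes by
#'   similarity rank (default 150; 100 is the conventional choice for
#'   True/False question runs).
#'
#' @param percentile Percentile in `[0, 100]`.
#' @param min_similarity Similarity floor.
#' @param context_volume Non-negative integer cap; 0 lets no context through
#'   at all (the degenerate end of the context-volume dial).
#' @return A `kg_pruning_config`.
#' @export
pruning_config <- function(percentile = 75, min_similarity = 0.5,
                           context_volume = 150L) {
  stopifnot(
    is.numeric(percentile), length(percentile) == 1,
    percentile >= 0, percentile <= 100,
    is.numeric(min_similarity), length(min_similarity) == 1,
    is.numeric(context_volume), length(context_volume) == 1, context_volume >= 0
  )
  structure(
    list(percentile = percentile, min_similarity = min_similarity,
      context_volume = as.integer(context_volume)),
    class = "kg_pruning_config"
  )
}

#' Retrieve verbalized context for linked disease nodes
#'
#' For every matched node, pulls its quality-filtered one-hop
#' [neighborhood()] and verbalizes the surviving triples. Sentences are
#' tagged with the node they came from (`entity_node_id`), which is the
#' grouping the percentile pruning rule operates on. Order is deterministic:
#' matches in rank order, each neighborhood in its own deterministic order.
#'
#' @param graph A [kg_graph()].
#' @param matches A tibble of entity matches from [link_entities()] (needs a
#'   `node_id` column).
#' @param filter A [context_filter()].
#' @return A tibble of context sentences: the verbalized triple columns (see
#'   [verbalize_triples()]) plus `entity_node_id`.
#' @export
retrieve_context <- function(graph, matches, filter = context_filter()) {
  stopifnot(inherits(graph, "kg_graph"))
  matches <- as_tibble(matches)
  if (nrow(matches) == 0) {
    abort("`matches` is empty: no linked disease nodes to retrieve context for.",
      class = "kgrag_link_error")
  }
  out <- map(unique(matches$node_id), function(id) {
    tr <- neighborhood(graph, id, filter = filter)
    tr <- verbalize_triples(tr, abbreviations = graph$abbreviations)
    tr$entity_node_id <- rep(id, nrow(tr))
    tr
  })
  list_rbind(out)
}

#' Prune context sentences to the prompt-aware subset
#'
#' Implements the percentile-plus-floor rule. Per disease node
#' (`entity_node_id` group): the prompt and every bare context sentence are
#' embedded, cosine similarities computed, and a sentence is kept only if
#' its similarity is strictly greater than the group's `percentile`
#' (linear-interpolation definition) *and* at least `min_similarity`.
#' Surviving sentences from all groups are then pooled, sorted by similarity
#' descending (ties by sentence text ascending) and truncated to
#' `context_volume`.
#'
#' Similarity is always computed on the bare sentence, never on provenance
#' or evidence clauses; those are re-attached at prompt-assembly time.
#'
#' @param prompt Question text.
#' @param contexts Context sentences from [retrieve_context()].
#' @param embedder The context [embedder()].
#' @param config A [pruning_config()].
#' @return The kept rows of `contexts` with a `similarity` column, in pooled
#'   pruned order.
#' @export
prune_context <- function(prompt, contexts, embedder,
                          config = pruning_config()) {
  stopifnot(inherits(config, "kg_pruning_config"), inherits(embedder, "kg_embedder"))
  contexts <- as_tibble(contexts)
  if (nrow(contexts) == 0) {
    contexts$similarity <- numeric()
    return(contexts)
  }
  if (!"entity_node_id" %in% names(contexts)) {
    contexts$entity_node_id <- ""
  }
  pv <- embed_texts(embedder, prompt)[1, ]
  sv <- embed_texts(embedder, contexts$sentence)
  contexts$similarity <- cosine_against(sv, pv)

  kept <- contexts |>
    group_by(.data$entity_node_id) |>
    filter(
      .data$similarity > quantile(.data$similarity, config$percentile / 100,
        type = 7, names = FALSE),
      .data$similarity >= config$min_similarity
    ) |>
    ungroup()
  kept <- kept[order(-kept$similarity, kept$sentence), ]
  head(kept, config$context_volume)
}

#' Sweep the context-volume hyperparameter against retrieval ground truth
#'
#' For each candidate context volume, runs the full retrieval pipeline
#' (extract, link, retrieve, prune) on every retrieval-type benchmark
#' question and scores the set of retrieved neighbor names against the
#' question's ground-truth association set with the [jaccard()] similarity.
#' The mean Jaccard per volume traces the context-enhancement vs token-budget
#' trade-off; on synthetic data the curve is non-decreasing and plateaus once
#' the volume exceeds the surviving context of every question.
#'
#' @param questions Retrieval-kind question records (columns `text`,
#'   `truth_set`).
#' @param graph A [kg_graph()].
#' @param volumes Integer vector of context volumes to evaluate.
#' @param embedder The [embedder()] used for linking and pruning.
#' @param extractor A [extractor()]; defaults to a dictionary extractor over
#'   the graph's disease names.
#' @param filter A [context_filter()].
#' @param percentile,min_similarity Pruning settings used at every volume.
#'   `percentile = NULL` (default) disables the percentile rule and
#'   `min_similarity = -1` disables the floor, so the default sweep isolates
#'   the volume effect; pass the standard `75` / `0.5` to sweep the full
#'   pruning rule.
#' @param truth_type Node type(s) the ground-truth sets are made of (default
#'   `"Gene"`, matching retrieval questions built from disease-gene
#'   associations); retrieved neighbors of other types do not enter the
#'   Jaccard comparison.
#' @return A tibble of class `kg_sweep`: `context_volume`, `mean_jaccard`,
#'   `n_questions`.
#' @export
sweep_context_volume <- function(questions, graph, volumes,
                                 embedder = reference_embedder(),
                                 extractor = NULL,
                                 filter = context_filter(),
                                 percentile = NULL, min_similarity = -1,
                                 truth_type = "Gene") {
  questions <- as_tibble(questions)
  if (nrow(questions) == 0) {
    abort("`questions` is empty.", class = "kgrag_benchmark_error")
  }
  stopifnot(is.numeric(volumes), length(volumes) >= 1)
  if (is.null(extractor)) {
    extractor <- dictionary_extractor(
      graph$nodes$name[graph$nodes$node_type == "Disease"])
  }
  index <- disease_name_index(graph, embedder)

  # Retrieval + similarity scoring happen once per question; each volume then
  # just truncates the ranked sentence list differently.
  per_q <- map(seq_len(nrow(questions)), function(i) {
    q <- questions$text[i]
    ents <- extract_disease_entities(q, extractor)
    matches <- link_entities(ents, q, index, embedder)
    ctx <- retrieve_context(graph, matches, filter = filter)
    if (is.null(percentile)) {
      if (nrow(ctx) > 0) {
        pv <- embed_texts(embedder, q)[1, ]
        ctx$similarity <- cosine_against(embed_texts(embedder, ctx$sentence), pv)
        ctx <- ctx[ctx$similarity >= min_similarity, ]
        ctx <- ctx[order(-ctx$similarity, ctx$sentence), ]
      }
    } else {
      ctx <- prune_context(q, ctx, embedder,
        pruning_config(percentile = percentile, min_similarity = min_similarity,
          context_volume = .Machine$integer.max))
    }
    list(neighbors = ctx$neighbor_name, types = ctx$neighbor_type,
      truth = questions$truth_set[[i]])
  })

  res <- map(volumes, function(v) {
    js <- map_dbl(per_q, function(p) {
      got <- head(p$neighbors, v)
      got <- unique(got[head(p$types, v) %in% truth_type])
      jaccard(got, p$truth)
    })
    tibble(context_volume = as.integer(v), mean_jaccard = mean(js),
      n_questions = nrow(questions))
  })
  out <- list_rbind(res)
  class(out) <- c("kg_sweep", class(out))
  out
}

#' @describeIn sweep_context_volume Plot the mean-Jaccard vs context-volume
#'   curve.
#' @param object A `kg_sweep` tibble.
#' @param ... Unused.
#' @export
autoplot.kg_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$context_volume, y = .data$mean_jaccard)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Context volume", y = "Mean Jaccard similarity") +
    ggplot2::theme_minimal()
}
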