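#' Build a semantic (embedding-based) retriever
#'
#' Returns a function mapping a question to the set of neighbor names its
#' retrieved context mentions, via the full pipeline: entity extraction,
#' embedding-based entity linking, filtered neighborhood retrieval and
#' (optionally) pruning. With the case-insensitive [reference_embedder()]
#' and a dictionary extractor this retriever is invariant under
#' lower-casing of the question.
#'
#' @param graph A [kg_graph()].
#' @param embedder An [embedder()].
#' @param extractor A [extractor()]; defaults to a dictionary extractor over
#'   the graph's disease names.
#' @param filter A [context_filter()].
#' @param pruning A [pruning_config()] or `NULL` (default) for no pruning —
#'   retrieval questions ask for complete association sets, so the default
#'   returns the full filtered neighborhood.
#' @return `function(question) -> character vector` of retrieved neighbor
#'   names.
#' @export
semantic_retriever <- function(graph, embedder = reference_embedder(),
                               extractor = NULL,
                               filter = context_filter(),
                               pruning = NULL) {
  stopifnot(inherits(graph, "kg_graph"))
  if (is.null(extractor)) {
    extractor <- dictionary_extractor(
      graph$nodes$name[graph$nodes$node_type == "Disease"])
  }
  index <- disease_name_index(graph, embedder)
  function(question) {
    ents <- extract_disease_entities(question, extractor)
    matches <- link_entities(ents, question, index, embedder)
    ctx <- retrieve_context(graph, matches, filter = filter)
    if (!is.null(pruning)) {
      ctx <- prune_context(question, ctx, embedder, pruning)
    }
    unique(ctx$neighbor_name)
  }
}

#' Build an exact-string-match baseline retriever
#'
#' The lexical comparator for robustness experiments: a disease node is
#' matched only when its name occurs in the question *verbatim*
#' (case-sensitive substring). Matched nodes' filtered neighborhoods are
#' retrieved as with the semantic retriever. Because matching is
#' case-sensitive, lower-casing a question that mentions mixed-case names
#' makes this baseline retrieve nothing.
#'
#' @inheritParams semantic_retriever
#' @return `function(question) -> character vector` of retrieved neighbor
#'   names (empty when no name matches).
#' @export
exact_match_retriever <- function(graph, filter = context_filter()) {
  stopifnot(inherits(graph, "kg_graph"))
  diseases <- graph$nodes[graph$nodes$node_type == "Disease", ]
  function(question) {
    hit <- map_lgl(diseases$name, function(nm) {
      stringr::str_detect(question, stringr::fixed(nm))
    })
    ids <- diseases$node_id[hit]
    if (length(ids) == 0) return(character())
    out <- map(ids, function(id) neighborhood(graph, id, filter = filter)$neighbor_name)
    unique(unlist(out))
  }
}
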