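#' Build a vector index over texts
#'
#' Embeds each item's text with the given embedder and stores the vectors
#' alongside the entries for exact top-k cosine search. The typical use is a
#' disease-name index: one entry per Disease node, with the node id as
#' payload (see [disease_name_index()]).
#'
#' @param items A data frame with columns `id` (unique), `text`, and
#'   optionally `payload` (any column; kept as-is).
#' @param embedder A [embedder()].
#' @return A `kg_index`: entries tibble, vector matrix, and the embedder's
#'   name and dimension stamp.
#' @export
build_index <- function(items, embedder) {
  stopifnot(inherits(embedder, "kg_embedder"))
  items <- as_tibble(items)
  need <- setdiff(c("id", "text"), names(items))
  if (length(need) > 0) {
    abort(sprintf("`items` is missing column(s): %s.", paste(need, collapse = ", ")))
  }
  if (!"payload" %in% names(items)) items$payload <- items$id
  items$id <- as.character(items$id)
  items$text <- as.character(items$text)
  dup <- items$id[duplicated(items$id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate index id(s): %s.",
      paste(encodeString(unique(dup), quote = '"'), collapse = ", ")))
  }
  structure(
    list(
      entries = items[c("id", "text", "payload")],
      vectors = embed_texts(embedder, items$text),
      embedder_name = embedder$name,
      dimension = embedder$dimension
    ),
    class = "kg_index"
  )
}

#' @export
print.kg_index <- function(x, ...) {
  cat(sprintf("<kg_index> %d entries, %d dimensions (embedder %s)\n",
    nrow(x$entries), x$dimension, x$embedder_name))
  invisible(x)
}

#' Query a vector index
#'
#' Exact cosine top-k search: the query text is embedded with the same
#' reference pipeline the index was built with (the caller supplies the
#' embedder), scored against every entry, and the best `k` returned.
#' Similarity ties are broken by entry id ascending, which keeps results
#' fully deterministic.
#'
#' @param index A [build_index()] result.
#' @param text Query text.
#' @param k Number of matches to return (fewer if the index is smaller).
#' @param embedder The [embedder()] used to build the index.
#' @return A tibble with columns `query_text`, `id`, `text`, `payload`,
#'   `similarity`, `rank`, ordered by rank.
#' @export
query_index <- function(index, text, k, embedder) {
  stopifnot(inherits(index, "kg_index"), inherits(embedder, "kg_embedder"))
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be a positive integer.")
  if (embedder$dimension != index$dimension) {
    abort(sprintf("Embedder dimension (%d) does not match the index stamp (%d).",
      embedder$dimension, index$dimension))
  }
  n <- nrow(index$entries)
  if (n == 0) {
    return(tibble(query_text = character(), id = character(), text = character(),
      payload = index$entries$payload[0], similarity = numeric(), rank = integer()))
  }
  v <- embed_texts(embedder, text)[1, ]
  sims <- cosine_against(index$vectors, v)
  ord <- order(-sims, index$entries$id)
  take <- ord[seq_len(min(k, n))]
  tibble(
    query_text = text,
    id = index$entries$id[take],
    text = index$entries$text[take],
    payload = index$entries$payload[take],
    similarity = sims[take],
    rank = seq_along(take)
  )
}

#' Persist a vector index to disk
#'
#' Written as a plain-text pair: `<path>.entries.jsonl` (one entry per line)
#' and `<path>.vectors.tsv` (one row of numbers per entry), plus a
#' `<path>.meta.json` with the embedder stamp. [read_index()] restores an
#' index that answers queries identically.
#'
#' @param index A `kg_index`.
#' @param path Path prefix (no extension).
#' @return Invisibly, `path`.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "kg_index"))
  entries <- index$entries
  lines <- map_chr(seq_len(nrow(entries)), function(i) {
    as.character(jsonlite::toJSON(
      list(id = entries$id[i], text = entries$text[i],
        payload = entries$payload[[i]]),
      auto_unbox = TRUE, digits = NA, null = "null"
    ))
  })
  readr::write_lines(lines, paste0(path, ".entries.jsonl"))
  readr::write_lines(
    apply(index$vectors, 1, function(r) paste(format(r, digits = 17), collapse = "\t")),
    paste0(path, ".vectors.tsv")
  )
  jsonlite::write_json(
    list(embedder_name = index$embedder_name, dimension = index$dimension),
    paste0(path, ".meta.json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Restore a vector index written by [write_index()]
#'
#' @param path Path prefix used at write time.
#' @return A `kg_index`.
#' @export
read_index <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  lines <- readr::read_lines(paste0(path, ".entries.jsonl"))
  lines <- lines[nzchar(lines)]
  rows <- map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  entries <- tibble(
    id = map_chr(rows, "id"),
    text = map_chr(rows, "text"),
    payload = map_chr(rows, function(r) as.character(r$payload))
  )
  vecs <- if (length(lines) == 0) {
    matrix(numeric(), nrow = 0, ncol = meta$dimension)
  } else {
    as.matrix(readr::read_tsv(paste0(path, ".vectors.tsv"),
      col_names = FALSE, show_col_types = FALSE, progress = FALSE))
  }
  dimnames(vecs) <- NULL
  structure(
    list(entries = entries, vectors = vecs,
      embedder_name = meta$embedder_name, dimension = as.integer(meta$dimension)),
    class = "kg_index"
  )
}

#' Build a disease-name index from a graph
#'
#' One entry per node of `node_type` (default `"Disease"`), keyed by node id
#' with the node id as payload. This is the index [link_entities()] expects.
#'
#' @param graph A [kg_graph()].
#' @param embedder A [embedder()].
#' @param node_type Node type to index; configurable so non-disease entity
#'   types can be linked the same way.
#' @return A `kg_index`.
#' @export
disease_name_index <- function(graph, embedder, node_type = "Disease") {
  stopifnot(inherits(graph, "kg_graph"))
  nodes <- graph$nodes[graph$nodes$node_type %in% node_type, ]
  build_index(
    tibble(id = nodes$node_id, text = nodes$name, payload = nodes$node_id),
    embedder
  )
}
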