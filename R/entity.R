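#' Entity extractors
#'
#' An extractor is the pluggable first stage of disease entity recognition:
#' it takes the free-text question and returns a raw response string that is
#' expected to be JSON with a `"Diseases"` array. Two constructors are
#' provided:
#'
#' * [dictionary_extractor()] — a deterministic matcher over a known list of
#'   disease names; it reports every dictionary name occurring
#'   (case-insensitively) in the prompt, in order of first appearance. Used
#'   for tests and offline runs.
#' * [llm_extractor()] — an adapter wrapping a chat-model backend with a
#'   configurable zero-shot system prompt instructing the model to return
#'   disease entities as JSON.
#'
#' @param name Extractor name.
#' @param fn Function mapping a prompt string to the raw response string. A
#'   transport failure should be signalled as an error; malformed output is
#'   handled downstream as a failed extraction, which triggers the
#'   whole-prompt fallback in [link_entities()].
#' @return A `kg_extractor`.
#' @export
extractor <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  structure(list(name = name, fn = fn), class = "kg_extractor")
}

#' @rdname extractor
#' @param disease_names Character vector of known disease names to scan for.
#' @export
dictionary_extractor <- function(disease_names) {
  disease_names <- unique(as.character(disease_names))
  extractor("dictionary", function(prompt) {
    hay <- stringr::str_to_lower(prompt)
    pos <- stringr::str_locate(hay, stringr::fixed(stringr::str_to_lower(disease_names)))[, "start"]
    found <- disease_names[!is.na(pos)]
    found <- found[order(pos[!is.na(pos)])]
    as.character(jsonlite::toJSON(list(Diseases = found)))
  })
}

#' @rdname extractor
#' @param backend A [chat_backend()] used to run the zero-shot extraction.
#' @param system_prompt Zero-shot instruction text; configuration, not a
#'   constant (defaults to a plain instruction to return
#'   `{"Diseases": [...]}`).
#' @export
llm_extractor <- function(backend,
                          system_prompt = paste(
                            "Extract all disease entities mentioned in the text.",
                            'Return JSON of the form {"Diseases": ["..."]} and nothing else.'
                          )) {
  stopifnot(inherits(backend, "kg_backend"))
  extractor(paste0("llm-", backend$name), function(prompt) {
    backend$complete(paste0(system_prompt, "\n\nText: ", prompt), temperature = 0)
  })
}

#' Extract disease entities from a question
#'
#' Runs the pluggable extractor and parses its raw response as JSON with a
#' `"Diseases"` array (a bare JSON array is also accepted). Malformed output
#' yields a failed extraction (`succeeded = FALSE`, no diseases) rather than
#' an error; transport errors raised by the extractor itself propagate, so
#' "the extractor broke" is always distinguishable from "no entities found".
#'
#' @param prompt Question text.
#' @param extractor A [extractor()].
#' @return A `kg_entities` list: `diseases` (character), `raw_response`,
#'   `succeeded`.
#' @export
extract_disease_entities <- function(prompt, extractor) {
  stopifnot(inherits(extractor, "kg_extractor"))
  raw <- extractor$fn(prompt)
  parsed <- tryCatch(jsonlite::fromJSON(raw, simplifyVector = TRUE),
    error = function(e) NULL)
  diseases <- character()
  succeeded <- FALSE
  if (!is.null(parsed)) {
    vals <- if (is.list(parsed) && !is.null(parsed$Diseases)) {
      parsed$Diseases
    } else if (is.character(parsed)) {
      parsed
    } else {
      NULL
    }
    if (!is.null(vals) || (is.list(parsed) && "Diseases" %in% names(parsed))) {
      diseases <- as.character(unlist(vals))
      diseases <- diseases[nzchar(diseases)]
      succeeded <- TRUE
    }
  }
  structure(
    list(diseases = diseases, raw_response = raw, succeeded = succeeded),
    class = "kg_entities"
  )
}

#' @export
print.kg_entities <- function(x, ...) {
  cat(sprintf("<kg_entities> succeeded: %s; diseases: %s\n",
    x$succeeded,
    if (length(x$diseases)) paste(x$diseases, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Link extracted entities to graph nodes
#'
#' Second stage of disease entity recognition: each extracted entity string
#' is matched against the disease-name vector index and its rank-1 node kept
#' (deduplicated by node id when two mentions resolve to the same node).
#' When extraction failed or found nothing, the whole prompt text is matched
#' instead and the top `fallback_k` disease concepts are returned.
#'
#' @param entities A `kg_entities` from [extract_disease_entities()].
#' @param prompt The original question text (used for the fallback).
#' @param disease_index A [disease_name_index()] (payload = node id).
#' @param embedder The [embedder()] the index was built with.
#' @param fallback_k How many whole-prompt matches to return on extraction
#'   failure (default 5).
#' @return A tibble of matches: `query_text`, `node_id`, `name`,
#'   `similarity`, `rank`.
#' @export
link_entities <- function(entities, prompt, disease_index, embedder,
                          fallback_k = 5L) {
  stopifnot(inherits(entities, "kg_entities"), inherits(disease_index, "kg_index"))
  if (nrow(disease_index$entries) == 0) {
    abort("The disease index is empty; cannot link entities.",
      class = "kgrag_link_error")
  }
  as_match <- function(res) {
    tibble(
      query_text = res$query_text, node_id = as.character(res$payload),
      name = res$text, similarity = res$similarity, rank = res$rank
    )
  }
  if (entities$succeeded && length(entities$diseases) > 0) {
    hits <- map(entities$diseases, function(d) {
      as_match(query_index(disease_index, d, k = 1L, embedder = embedder))
    })
    out <- list_rbind(hits)
    out <- out[!duplicated(out$node_id), ]
    out$rank <- seq_len(nrow(out))
    out
  } else {
    as_match(query_index(disease_index, prompt, k = fallback_k, embedder = embedder))
  }
}
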