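#' Chat-model backends
#'
#' A backend maps a rendered prompt and a temperature to a completion
#' string. Real chat models (an OpenAI-style HTTP API, a local Llama server)
#' are adapters built with [chat_backend()]; they are configuration-only and
#' never required — the bundled [mock_backend()]s are deterministic at
#' temperature 0 and exercise the whole pipeline offline.
#'
#' @param name Backend name.
#' @param complete Function `function(prompt_text, temperature = 0) ->
#'   character(1)`.
#' @return A `kg_backend`.
#' @export
chat_backend <- function(name, complete) {
  stopifnot(is.character(name), length(name) == 1, is.function(complete))
  structure(list(name = name, complete = complete), class = "kg_backend")
}

#' @export
print.kg_backend <- function(x, ...) {
  cat(sprintf("<kg_backend> %s\n", x$name))
  invisible(x)
}

#' Deterministic mock backends
#'
#' Three bundled mock chat models, all deterministic at temperature 0:
#'
#' * `"echo"` — returns the context block verbatim (useful for asserting
#'   exactly what reached the model);
#' * `"mcq-lookup"` — parses the option list out of the question (the text
#'   after `"Given list is:"`), answers with the first option that occurs as
#'   a word in the context block, and falls back to the first listed option
#'   when none does; returns `{"answer": "<option>"}`;
#' * `"tf-lookup"` — answers `{"answer": "True"}` exactly when the asserted
#'   sentence (the question text after `"True or False:"`) occurs,
#'   case-insensitively, in the context block, else `"False"`.
#'
#' The lookup mocks answer from the supplied context alone, so they measure
#' whether retrieval + verbalization + assembly put the right facts in front
#' of the model — the framework property the mocks exist to test.
#'
#' @param type One of `"echo"`, `"mcq-lookup"`, `"tf-lookup"`.
#' @param template The [prompt_template()] whose headers delimit the context
#'   and question blocks in the rendered prompt.
#' @return A [chat_backend()].
#' @export
mock_backend <- function(type = c("echo", "mcq-lookup", "tf-lookup"),
                         template = prompt_template()) {
  type <- match.arg(type)
  stopifnot(inherits(template, "kg_prompt_template"))
  complete <- switch(type,
    "echo" = function(prompt_text, temperature = 0) {
      split_prompt_blocks(prompt_text, template)$context
    },
    "mcq-lookup" = function(prompt_text, temperature = 0) {
      blocks <- split_prompt_blocks(prompt_text, template)
      options <- parse_option_list(blocks$question)
      if (length(options) == 0) {
        return(as.character(jsonlite::toJSON(list(answer = ""), auto_unbox = TRUE)))
      }
      hit <- options[map_lgl(options, function(o) {
        stringr::str_detect(blocks$context,
          stringr::regex(paste0("\\b", escape_regex(o), "\\b"), ignore_case = TRUE))
      })]
      answer <- if (length(hit) > 0) hit[1] else options[1]
      as.character(jsonlite::toJSON(list(answer = answer), auto_unbox = TRUE))
    },
    "tf-lookup" = function(prompt_text, temperature = 0) {
      blocks <- split_prompt_blocks(prompt_text, template)
      assertion <- stringr::str_match(blocks$question, "True or False:\\s*(.*)$")[, 2]
      assertion <- stringr::str_remove(assertion %||% "", "[.?!]\\s*$")
      found <- !is.na(assertion) && nzchar(assertion) &&
        stringr::str_detect(stringr::str_to_lower(blocks$context),
          stringr::fixed(stringr::str_to_lower(assertion)))
      as.character(jsonlite::toJSON(
        list(answer = if (found) "True" else "False"), auto_unbox = TRUE))
    }
  )
  chat_backend(paste0("mock-", type), complete)
}

escape_regex <- function(x) stringr::str_replace_all(x, "([\\\\^$.|?*+()\\[\\]{}])", "\\\\\\1")

# Split a rendered prompt back into its context block and question using the
# template headers. Missing context block yields context = "".
split_prompt_blocks <- function(prompt_text, template) {
  q_at <- stringr::str_locate(prompt_text, stringr::fixed(paste0(template$question_header, "\n")))
  question <- if (is.na(q_at[1, 1])) "" else
    substr(prompt_text, q_at[1, 2] + 1L, nchar(prompt_text))
  c_at <- stringr::str_locate(prompt_text, stringr::fixed(paste0(template$context_header, "\n")))
  context <- ""
  if (!is.na(c_at[1, 1])) {
    stop_at <- if (is.na(q_at[1, 1])) nchar(prompt_text) else q_at[1, 1] - 1L
    context <- stringr::str_trim(substr(prompt_text, c_at[1, 2] + 1L, stop_at))
  }
  list(context = context, question = question)
}

parse_option_list <- function(question) {
  m <- stringr::str_match(question, "Given list is:\\s*(.*)$")[, 2]
  if (is.na(m)) return(character())
  m <- stringr::str_remove(m, "[.?!]\\s*$")
  opts <- stringr::str_split(m, ",\\s*")[[1]]
  opts[nzchar(opts)]
}

#' Answer a question end-to-end
#'
#' Orchestrates the full pipeline: disease entity extraction, entity linking
#' against the disease-name index, filtered neighborhood retrieval,
#' verbalization, percentile-plus-floor pruning, prompt assembly, and a
#' single temperature-0 backend call. Structured answers (`json_tf`,
#' `json_mcq` templates) are parsed out of the completion; the provenance
#' strings the completion actually cites are collected; and token usage is
#' accounted as prompt estimate plus completion count under one tokenizer.
#'
#' When the disease index is empty, or when `strict = TRUE` and no context
#' sentence survives pruning, the function returns an explicit answer with
#' `status = "no_context"` instead of calling the backend.
#'
#' @param question Question text.
#' @param graph A [kg_graph()].
#' @param backend A [chat_backend()].
#' @param embedder The [embedder()] for linking and pruning (default
#'   [reference_embedder()]).
#' @param disease_index Optional prebuilt [disease_name_index()]; built from
#'   the graph when `NULL`.
#' @param extractor Optional [extractor()]; defaults to a dictionary
#'   extractor over the graph's disease names.
#' @param template A [prompt_template()].
#' @param filter A [context_filter()].
#' @param pruning A [pruning_config()], or `NULL` to skip pruning (all
#'   retrieved context enters the prompt).
#' @param include_provenance,include_evidence Clause flags forwarded to
#'   prompt assembly.
#' @param fallback_k Whole-prompt fallback size for entity linking.
#' @param temperature Forwarded to the backend (0 everywhere by default).
#' @param tokenizer Optional tokenizer (see [count_tokens()]).
#' @param strict Return a `no_context` answer instead of calling the backend
#'   when no context survives.
#' @return A `kg_answer`: `text`, `parsed`, `status` (`"ok"` or
#'   `"no_context"`), `cited_provenance`, `token_usage`, plus the assembled
#'   `prompt` and the `matches` used.
#' @export
answer_question <- function(question, graph, backend,
                            embedder = reference_embedder(),
                            disease_index = NULL,
                            extractor = NULL,
                            template = prompt_template(),
                            filter = context_filter(),
                            pruning = pruning_config(),
                            include_provenance = TRUE,
                            include_evidence = FALSE,
                            fallback_k = 5L,
                            temperature = 0,
                            tokenizer = NULL,
                            strict = FALSE) {
  stopifnot(inherits(graph, "kg_graph"), inherits(backend, "kg_backend"))
  if (is.null(extractor)) {
    extractor <- dictionary_extractor(
      graph$nodes$name[graph$nodes$node_type == "Disease"])
  }
  if (is.null(disease_index)) {
    disease_index <- disease_name_index(graph, embedder)
  }
  no_context <- function(reason) {
    structure(
      list(text = "", parsed = NULL, status = "no_context", reason = reason,
        cited_provenance = character(), token_usage = 0L,
        prompt = NULL, matches = NULL),
      class = "kg_answer"
    )
  }
  if (nrow(disease_index$entries) == 0) {
    return(no_context("the graph has no indexed disease nodes"))
  }

  entities <- extract_disease_entities(question, extractor)
  matches <- link_entities(entities, question, disease_index, embedder,
    fallback_k = fallback_k)
  contexts <- retrieve_context(graph, matches, filter = filter)
  if (!is.null(pruning)) {
    contexts <- prune_context(question, contexts, embedder, pruning)
  } else if (nrow(contexts) > 0) {
    pv <- embed_texts(embedder, question)[1, ]
    contexts$similarity <- cosine_against(embed_texts(embedder, contexts$sentence), pv)
  }
  if (strict && nrow(contexts) == 0) {
    return(no_context("no context survived retrieval and pruning"))
  }

  prompt <- assemble_prompt(question, contexts, template = template,
    include_provenance = include_provenance,
    include_evidence = include_evidence, tokenizer = tokenizer)
  completion <- backend$complete(prompt$rendered_text, temperature = temperature)

  parsed <- parse_structured_answer(completion, template$answer_format)
  prov_pool <- if ("provenance" %in% names(contexts)) {
    unique(unlist(contexts$provenance))
  } else {
    character()
  }
  cited <- prov_pool[map_lgl(prov_pool, function(p) {
    stringr::str_detect(completion, stringr::fixed(p))
  })]

  structure(
    list(
      text = completion,
      parsed = parsed,
      status = "ok",
      cited_provenance = as.character(cited),
      token_usage = prompt$token_estimate + count_tokens(completion, tokenizer = tokenizer),
      prompt = prompt,
      matches = matches
    ),
    class = "kg_answer"
  )
}

parse_structured_answer <- function(completion, answer_format) {
  if (answer_format == "free_text") return(NULL)
  parsed <- tryCatch(jsonlite::fromJSON(completion, simplifyVector = TRUE),
    error = function(e) NULL)
  if (is.null(parsed)) {
    # tolerate completions that wrap the JSON in prose
    m <- stringr::str_match(completion, "\\{[^{}]*\\}")[, 1]
    if (!is.na(m)) {
      parsed <- tryCatch(jsonlite::fromJSON(m, simplifyVector = TRUE),
        error = function(e) NULL)
    }
  }
  if (is.null(parsed)) return(NULL)
  ans <- if (is.list(parsed)) parsed$answer else parsed
  if (is.null(ans) || length(ans) == 0) return(NULL)
  ans <- as.character(ans)[1]
  if (answer_format == "json_tf") {
    low <- stringr::str_to_lower(stringr::str_trim(ans))
    if (low %in% c("true", "false")) return(low == "true")
    return(NULL)
  }
  ans
}

#' @export
print.kg_answer <- function(x, ...) {
  cat(sprintf("<kg_answer> status: %s; ~%d tokens\n", x$status, x$token_usage))
  if (nzchar(x$text)) {
    cat(strtrim(x$text, 200), if (nchar(x$text) > 200) "...\n" else "\n", sep = "")
  }
  invisible(x)
}
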