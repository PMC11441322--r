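#' Prompt templates
#'
#' A template fixes the three fixed parts of an enriched prompt: the system
#' instruction, the header introducing the context block, and the header
#' introducing the user question. `answer_format` selects the instruction
#' asking the model to answer free-form, as `{"answer": "True"/"False"}`,
#' or as `{"answer": "<option>"}`. The shipped instruction texts are
#' editable defaults, not fixed constants.
#'
#' @param answer_format One of `"free_text"`, `"json_tf"`, `"json_mcq"`.
#' @param system_instruction Override the default instruction text.
#' @param context_header,question_header Block headers.
#' @return A `kg_prompt_template`.
#' @export
prompt_template <- function(answer_format = c("free_text", "json_tf", "json_mcq"),
                            system_instruction = NULL,
                            context_header = "Context:",
                            question_header = "Question:") {
  answer_format <- match.arg(answer_format)
  if (is.null(system_instruction)) {
    system_instruction <- switch(answer_format,
      free_text = paste(
        "You are a biomedical assistant. Answer the question using only the",
        "provided context, citing the provenance of the associations you use."
      ),
      json_tf = paste(
        "You are a biomedical assistant. Based only on the provided context,",
        'answer the question as JSON of the form {"answer": "True"} or',
        '{"answer": "False"}.'
      ),
      json_mcq = paste(
        "You are a biomedical assistant. Based only on the provided context,",
        "answer the multiple-choice question as JSON of the form",
        '{"answer": "<chosen option>"}.'
      )
    )
  }
  structure(
    list(system_instruction = system_instruction,
      context_header = context_header,
      question_header = question_header,
      answer_format = answer_format),
    class = "kg_prompt_template"
  )
}

#' Count tokens in a text
#'
#' The default tokenizer splits on runs of whitespace and punctuation and
#' counts the non-empty pieces — a model-agnostic approximation adequate for
#' comparing prompt budgets. Model-specific tokenizers plug in as a function
#' from text to an integer count.
#'
#' @param text Character vector; counts are summed over its elements.
#' @param tokenizer Optional function `function(text) -> integer` applied to
#'   each element instead of the default splitter.
#' @return Non-negative integer token count.
#' @examples
#' count_tokens("disease hypertension associates Gene VHL")
#' @export
count_tokens <- function(text, tokenizer = NULL) {
  if (length(text) == 0) return(0L)
  if (!is.null(tokenizer)) {
    return(sum(map_int(as.character(text), function(t) as.integer(tokenizer(t)))))
  }
  pieces <- stringr::str_split(as.character(text), "[\\s[:punct:]]+")
  sum(map_int(pieces, function(p) sum(nzchar(p))))
}

#' Assemble an enriched prompt
#'
#' Deterministically renders system instruction, context block (one sentence
#' per line, in the pruned order, re-verbalized with the requested
#' provenance/evidence clauses) and the user question, and estimates its
#' token count.
#'
#' @param question Question text.
#' @param contexts Pruned context sentences from [prune_context()] (may have
#'   zero rows, in which case the context block is omitted).
#' @param template A [prompt_template()].
#' @param include_provenance Append provenance clauses to context lines.
#' @param include_evidence Append evidence clauses (the `-e` style option)
#'   to context lines that carry evidence.
#' @param tokenizer Optional tokenizer for the estimate (see
#'   [count_tokens()]).
#' @return A `kg_prompt`: `rendered_text`, `contexts` (with the flagged
#'   `text` column), `token_estimate`.
#' @export
assemble_prompt <- function(question, contexts = NULL,
                            template = prompt_template(),
                            include_provenance = FALSE,
                            include_evidence = FALSE,
                            tokenizer = NULL) {
  stopifnot(inherits(template, "kg_prompt_template"))
  if (is.null(contexts)) contexts <- tibble(sentence = character())
  contexts <- as_tibble(contexts)
  if (nrow(contexts) > 0) {
    line <- contexts$sentence
    has <- function(col) col %in% names(contexts)
    if (include_provenance && has("provenance_text")) {
      line <- paste0(line, contexts$provenance_text)
    }
    if (include_evidence && has("evidence_text")) {
      line <- paste0(line, contexts$evidence_text)
    }
    contexts$text <- line
    body <- paste(
      template$system_instruction,
      paste(template$context_header,
        paste(line, collapse = "\n"), sep = "\n"),
      paste(template$question_header, question, sep = "\n"),
      sep = "\n\n"
    )
  } else {
    body <- paste(
      template$system_instruction,
      paste(template$question_header, question, sep = "\n"),
      sep = "\n\n"
    )
  }
  structure(
    list(rendered_text = body, contexts = contexts,
      token_estimate = count_tokens(body, tokenizer = tokenizer),
      template = template),
    class = "kg_prompt"
  )
}

#' @export
print.kg_prompt <- function(x, ...) {
  cat(sprintf("<kg_prompt> %d context sentences, ~%d tokens\n",
    nrow(x$contexts), x$token_estimate))
  invisible(x)
}
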