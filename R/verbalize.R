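#' Verbalize attributed triples into English context sentences
#'
#' Converts each `(subject, predicate, object)` triple into the sentence
#' `"<subject type> <subject name> <predicate words> <object type> <object
#' name>"`, where the predicate words are the predicate name lower-cased with
#' underscores turned into spaces. Node types are rendered verbatim as stored
#' — a triple stored as (disease "hypertension", `ASSOCIATES_DaG`, Gene
#' "VHL") verbalizes to `"disease hypertension associates Gene VHL"`.
#'
#' Two optional clauses can be appended to the bare sentence:
#' * provenance — `" (Provenance: <source 1>, <source 2>, ...)"`, sources in
#'   stored order;
#' * evidence — `" (evidence: p-value = <p>, z-score = <z>)"`, absent fields
#'   omitted, numbers shown with 6 significant digits. Triples without
#'   evidence get no clause.
#'
#' The bare sentence (column `sentence`) is what context pruning scores
#' against the prompt; the flagged rendering (column `text`) is what enters
#' the assembled prompt.
#'
#' @param triples A tibble of attributed triples as returned by
#'   [neighborhood()] (columns `subject_type`, `subject_name`, `predicate`,
#'   `object_type`, `object_name`, `provenance`, `evidence`).
#' @param include_provenance Append the provenance clause.
#' @param include_evidence Append the evidence clause where evidence exists.
#' @param abbreviations Optional node-type abbreviation table (see
#'   [parse_predicate()]).
#' @return The input tibble with columns `sentence` (bare),
#'   `provenance_text`, `evidence_text` (clauses or `""`), and `text`
#'   (sentence plus the requested clauses).
#' @examples
#' tr <- tibble::tibble(
#'   subject_type = "disease", subject_name = "hypertension",
#'   predicate = "ASSOCIATES_DaG",
#'   object_type = "Gene", object_name = "VHL",
#'   provenance = list("GWAS Catalog"), evidence = list(NULL)
#' )
#' verbalize_triples(tr)$sentence
#' @export
verbalize_triples <- function(triples, include_provenance = FALSE,
                              include_evidence = FALSE, abbreviations = NULL) {
  triples <- as_tibble(triples)
  if (nrow(triples) == 0) {
    triples$sentence <- character()
    triples$provenance_text <- character()
    triples$evidence_text <- character()
    triples$text <- character()
    return(triples)
  }
  parts <- parse_predicate(triples$predicate, abbreviations = abbreviations)
  pred_words <- tolower(stringr::str_replace_all(parts$predicate_name, "_", " "))
  sentence <- paste(
    triples$subject_type, triples$subject_name,
    pred_words,
    triples$object_type, triples$object_name
  )
  if (!"provenance" %in% names(triples)) {
    triples$provenance <- rep(list(character()), nrow(triples))
  }
  if (!"evidence" %in% names(triples)) {
    triples$evidence <- rep(list(NULL), nrow(triples))
  }
  prov_text <- map_chr(triples$provenance, provenance_clause)
  evid_text <- map_chr(triples$evidence, evidence_clause)
  text <- sentence
  if (include_provenance) text <- paste0(text, prov_text)
  if (include_evidence) text <- paste0(text, evid_text)
  triples$sentence <- sentence
  triples$provenance_text <- prov_text
  triples$evidence_text <- evid_text
  triples$text <- text
  triples
}

provenance_clause <- function(sources) {
  if (is.null(sources) || length(sources) == 0) return("")
  sprintf(" (Provenance: %s)", paste(as.character(sources), collapse = ", "))
}

evidence_clause <- function(evidence) {
  if (is.null(evidence) || length(evidence) == 0) return("")
  bits <- character()
  if (!is.null(evidence$p_value)) {
    bits <- c(bits, sprintf("p-value = %s", format(signif(evidence$p_value, 6))))
  }
  if (!is.null(evidence$z_score)) {
    bits <- c(bits, sprintf("z-score = %s", format(signif(evidence$z_score, 6))))
  }
  if (length(bits) == 0) return("")
  sprintf(" (evidence: %s)", paste(bits, collapse = ", "))
}

#' Verbalize a single triple to a string
#'
#' Convenience scalar wrapper around [verbalize_triples()].
#'
#' @inheritParams verbalize_triples
#' @param triple A one-row triple tibble or a named list with the triple
#'   fields.
#' @return The rendered sentence string (with the requested clauses).
#' @export
verbalize_triple <- function(triple, include_provenance = FALSE,
                             include_evidence = FALSE, abbreviations = NULL) {
  if (!is.data.frame(triple)) {
    triple <- tibble(
      subject_type = triple$subject_type, subject_name = triple$subject_name,
      predicate = triple$predicate,
      object_type = triple$object_type, object_name = triple$object_name,
      provenance = list(triple$provenance %||% character()),
      evidence = list(triple$evidence)
    )
  }
  stopifnot(nrow(triple) == 1)
  verbalize_triples(triple, include_provenance = include_provenance,
    include_evidence = include_evidence, abbreviations = abbreviations)$text
}
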