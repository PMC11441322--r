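#' Parse a SPOKE-style predicate string
#'
#' SPOKE-style property graphs name every edge type with an upper-case
#' predicate name followed by a three-character suffix giving the subject-type
#' initial (upper case), the predicate initial (lower case) and the
#' object-type initial (upper case). `"ASSOCIATES_DaG"`, for instance, is the
#' ASSOCIATES predicate connecting Disease nodes to Gene nodes.
#'
#' The default grammar is strict: exactly one letter per type initial. Graphs
#' whose schema abbreviates node types with more than one letter can supply
#' `abbreviations`, a named character vector mapping node types to their
#' abbreviation strings (e.g. `c(SideEffect = "SE")`); the suffix is then
#' parsed as `<subject abbrev><lower-case predicate initial><object abbrev>`.
#'
#' @param predicate Character vector of predicate strings.
#' @param abbreviations Optional named character vector of node-type
#'   abbreviations. `NULL` (default) enforces the strict one-letter rule.
#' @return A tibble with one row per predicate and columns `predicate`,
#'   `predicate_name`, `subject_initial`, `predicate_initial`,
#'   `object_initial`.
#' @examples
#' parse_predicate("ASSOCIATES_DaG")
#' parse_predicate("TREATS_CtD")
#' @seealso [compose_predicate()]
#' @export
parse_predicate <- function(predicate, abbreviations = NULL) {
  if (length(predicate) == 0) {
    return(tibble(
      predicate = character(), predicate_name = character(),
      subject_initial = character(), predicate_initial = character(),
      object_initial = character()
    ))
  }
  if (!is.character(predicate) || anyNA(predicate)) {
    abort("`predicate` must be a character vector without missing values.")
  }
  out <- map(predicate, parse_predicate_one, abbreviations = abbreviations)
  list_rbind(out)
}

parse_predicate_one <- function(predicate, abbreviations = NULL) {
  us <- stringr::str_locate_all(predicate, stringr::fixed("_"))[[1]]
  if (nrow(us) == 0) {
    abort(sprintf(
      "Predicate %s does not match the schema: missing the `_` suffix separator.",
      encodeString(predicate, quote = '"')
    ), class = "kgrag_schema_error")
  }
  cut <- us[nrow(us), 1]
  name <- substr(predicate, 1L, cut - 1L)
  suffix <- substr(predicate, cut + 1L, nchar(predicate))

  if (!nzchar(name) || !stringr::str_detect(name, "^[A-Z][A-Z_]*$")) {
    abort(sprintf(
      "Predicate %s does not match the schema: the name part must be upper-case letters and underscores.",
      encodeString(predicate, quote = '"')
    ), class = "kgrag_schema_error")
  }

  parts <- split_suffix(suffix, abbreviations)
  if (is.null(parts)) {
    abort(sprintf(
      "Predicate %s does not match the schema: suffix %s is not <Upper><lower><Upper>%s.",
      encodeString(predicate, quote = '"'), encodeString(suffix, quote = '"'),
      if (is.null(abbreviations)) "" else " (nor a configured abbreviation pair)"
    ), class = "kgrag_schema_error")
  }
  if (parts$predicate_initial != tolower(substr(name, 1L, 1L))) {
    abort(sprintf(
      "Predicate %s is inconsistent: suffix predicate initial %s does not match the first letter of %s.",
      encodeString(predicate, quote = '"'),
      encodeString(parts$predicate_initial, quote = '"'),
      encodeString(name, quote = '"')
    ), class = "kgrag_schema_error")
  }
  tibble(
    predicate = predicate,
    predicate_name = name,
    subject_initial = parts$subject_initial,
    predicate_initial = parts$predicate_initial,
    object_initial = parts$object_initial
  )
}

# Split a predicate suffix into subject abbrev / predicate initial / object
# abbrev. Strict rule: one upper, one lower, one upper. With an abbreviation
# table, subject and object parts must each be a listed abbreviation (longest
# subject match tried first so e.g. "SEcC" with SE = SideEffect is unambiguous).
split_suffix <- function(suffix, abbreviations = NULL) {
  if (is.null(abbreviations)) {
    if (stringr::str_detect(suffix, "^[A-Z][a-z][A-Z]$")) {
      return(list(
        subject_initial = substr(suffix, 1, 1),
        predicate_initial = substr(suffix, 2, 2),
        object_initial = substr(suffix, 3, 3)
      ))
    }
    return(NULL)
  }
  abbrevs <- unique(c(unname(abbreviations), LETTERS))
  abbrevs <- abbrevs[order(-nchar(abbrevs))]
  for (sub_ab in abbrevs) {
    if (!startsWith(suffix, sub_ab)) next
    rest <- substr(suffix, nchar(sub_ab) + 1L, nchar(suffix))
    if (nchar(rest) < 2L) next
    pred_init <- substr(rest, 1, 1)
    if (!stringr::str_detect(pred_init, "^[a-z]$")) next
    obj_ab <- substr(rest, 2L, nchar(rest))
    if (obj_ab %in% abbrevs) {
      return(list(
        subject_initial = sub_ab,
        predicate_initial = pred_init,
        object_initial = obj_ab
      ))
    }
  }
  NULL
}

#' Compose a schema-compliant predicate string
#'
#' Inverse of [parse_predicate()]: builds
#' `UPPERCASE(name)_<SubjInitial><predInitial><ObjInitial>` from a predicate
#' name and the two endpoint node types.
#'
#' @param predicate_name Predicate name (letters and underscores); upper-cased
#'   in the result.
#' @param subject_type,object_type Node-type tokens; only their first letters
#'   enter the suffix.
#' @return The predicate string, e.g. `compose_predicate("ASSOCIATES",
#'   "Disease", "Gene")` gives `"ASSOCIATES_DaG"`.
#' @examples
#' compose_predicate("TREATS", "Compound", "Disease")
#' @export
compose_predicate <- function(predicate_name, subject_type, object_type) {
  ok <- function(x) is.character(x) && length(x) == 1 && !is.na(x) && nzchar(x)
  if (!ok(predicate_name) || !ok(subject_type) || !ok(object_type)) {
    abort("`predicate_name`, `subject_type` and `object_type` must be non-empty strings.")
  }
  if (!stringr::str_detect(predicate_name, "^[A-Za-z][A-Za-z_]*$")) {
    abort(sprintf(
      "`predicate_name` %s must contain only letters and underscores and start with a letter.",
      encodeString(predicate_name, quote = '"')
    ))
  }
  name <- toupper(predicate_name)
  paste0(
    name, "_",
    toupper(substr(subject_type, 1, 1)),
    tolower(substr(name, 1, 1)),
    toupper(substr(object_type, 1, 1))
  )
}
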