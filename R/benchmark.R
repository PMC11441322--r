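#' Read a benchmark question set
#'
#' Question sets are JSON arrays of objects `{id, kind, text, options?,
#' correct?, truth_set?}` (CSV with `|`-separated list fields is also
#' accepted). Three kinds exist: `"tf"` (True/False; `correct` is `"True"`
#' or `"False"`), `"mcq"` (exactly five options, one of which is `correct`)
#' and `"retrieval"` (`truth_set` holds the ground-truth association names).
#'
#' @param path Path to a `.json` or `.csv` question file.
#' @param kind Optionally restrict/validate to a single kind.
#' @return A tibble of validated question records with list columns
#'   `options` and `truth_set`.
#' @export
read_questions <- function(path, kind = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE)
    split_col <- function(x) {
      map(x, function(s) {
        if (is.na(s) || !nzchar(s)) character() else stringr::str_split(s, "\\|")[[1]]
      })
    }
    df$options <- split_col(df$options %||% rep(NA_character_, nrow(df)))
    df$truth_set <- split_col(df$truth_set %||% rep(NA_character_, nrow(df)))
    rows <- df
  } else {
    parsed <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (length(parsed) == 0) {
      return(validate_questions(empty_questions(), kind))
    }
    rows <- tibble(
      question_id = map_chr(parsed, function(r) as.character(r$id %||% r$question_id)),
      kind = map_chr(parsed, function(r) as.character(r$kind)),
      text = map_chr(parsed, function(r) as.character(r$text)),
      options = map(parsed, function(r) as.character(unlist(r$options))),
      correct = map_chr(parsed, function(r) {
        if (is.null(r$correct)) NA_character_ else as.character(r$correct)
      }),
      truth_set = map(parsed, function(r) as.character(unlist(r$truth_set)))
    )
  }
  if (!"question_id" %in% names(rows) && "id" %in% names(rows)) {
    rows$question_id <- rows$id
  }
  rows <- as_tibble(rows)[, c("question_id", "kind", "text", "options", "correct", "truth_set")]
  validate_questions(rows, kind)
}

empty_questions <- function() {
  tibble(question_id = character(), kind = character(), text = character(),
    options = list(), correct = character(), truth_set = list())
}

validate_questions <- function(questions, kind = NULL) {
  if (!is.null(kind)) {
    bad <- setdiff(unique(questions$kind), kind)
    if (length(bad) > 0) {
      abort(sprintf("Question set contains kind(s) %s but %s was requested.",
        paste(encodeString(bad, quote = '"'), collapse = ", "),
        encodeString(kind, quote = '"')), class = "kgrag_load_error")
    }
  }
  ok_kind <- questions$kind %in% c("tf", "mcq", "retrieval")
  if (any(!ok_kind)) {
    abort(sprintf("Unknown question kind %s.",
      encodeString(questions$kind[!ok_kind][1], quote = '"')),
      class = "kgrag_load_error")
  }
  is_mcq <- questions$kind == "mcq"
  n_opt <- map_int(questions$options, length)
  if (any(is_mcq & n_opt != 5L)) {
    i <- which(is_mcq & n_opt != 5L)[1]
    abort(sprintf("MCQ record %s has %d options; exactly 5 are required.",
      encodeString(questions$question_id[i], quote = '"'), n_opt[i]),
      class = "kgrag_load_error")
  }
  bad_correct <- is_mcq & !map2_lgl_(questions$correct, questions$options,
    function(c, o) !is.na(c) && c %in% o)
  if (any(bad_correct)) {
    i <- which(bad_correct)[1]
    abort(sprintf("MCQ record %s: `correct` must be one of the options.",
      encodeString(questions$question_id[i], quote = '"')),
      class = "kgrag_load_error")
  }
  is_tf <- questions$kind == "tf"
  if (any(is_tf & !questions$correct %in% c("True", "False"))) {
    abort('True/False records must have `correct` equal to "True" or "False".',
      class = "kgrag_load_error")
  }
  is_ret <- questions$kind == "retrieval"
  if (any(is_ret & map_int(questions$truth_set, length) == 0L)) {
    abort("Retrieval records must have a non-empty truth_set.",
      class = "kgrag_load_error")
  }
  questions
}

map2_lgl_ <- function(x, y, f) map_lgl(seq_along(x), function(i) f(x[[i]], y[[i]]))

#' Write a benchmark question set as JSON
#'
#' @param questions A question tibble (see [read_questions()]).
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_questions <- function(questions, path) {
  recs <- map(seq_len(nrow(questions)), function(i) {
    r <- list(id = questions$question_id[i], kind = questions$kind[i],
      text = questions$text[i])
    if (length(questions$options[[i]]) > 0) r$options <- as.list(questions$options[[i]])
    if (!is.na(questions$correct[i])) r$correct <- questions$correct[i]
    if (length(questions$truth_set[[i]]) > 0) r$truth_set <- as.list(questions$truth_set[[i]])
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Evaluate an answering system on True/False or MCQ questions
#'
#' Runs `system` on every question and scores it. For MCQ, the answer may be
#' the option text or the option letter (`A`-`E` by listed position), both
#' case-insensitive; anything unparseable counts as incorrect and is
#' reported in the `n_unparseable` attribute. For True/False, `"True"` /
#' `"False"` (any case, or a parsed logical) are accepted.
#'
#' @param questions Question tibble of kind `"tf"` and/or `"mcq"`.
#' @param system A function taking the question text (and, for MCQ, given
#'   the options are embedded in the text) and returning either a string or
#'   a `kg_answer`.
#' @return A tibble `question_id`, `kind`, `answer`, `correct_answer`,
#'   `correct` (logical), with attribute `n_unparseable`.
#' @export
evaluate_questions <- function(questions, system) {
  questions <- as_tibble(questions)
  if (nrow(questions) == 0) {
    out <- tibble(question_id = character(), kind = character(),
      answer = character(), correct_answer = character(), correct = logical())
    attr(out, "n_unparseable") <- 0L
    return(out)
  }
  stopifnot(all(questions$kind %in% c("tf", "mcq")))
  n_unparseable <- 0L
  rows <- map(seq_len(nrow(questions)), function(i) {
    res <- system(questions$text[i])
    ans <- answer_string(res)
    scored <- score_answer(ans, questions$kind[i], questions$correct[i],
      questions$options[[i]])
    tibble(question_id = questions$question_id[i], kind = questions$kind[i],
      answer = ans %||% NA_character_,
      correct_answer = questions$correct[i], correct = scored$correct,
      unparseable = scored$unparseable)
  })
  out <- list_rbind(rows)
  n_unparseable <- sum(out$unparseable)
  if (n_unparseable > 0) {
    inform(sprintf("%d answer(s) could not be parsed and were scored incorrect.",
      n_unparseable))
  }
  out$unparseable <- NULL
  attr(out, "n_unparseable") <- as.integer(n_unparseable)
  out
}

answer_string <- function(res) {
  if (inherits(res, "kg_answer")) {
    if (is.logical(res$parsed)) return(if (res$parsed) "True" else "False")
    if (!is.null(res$parsed)) return(as.character(res$parsed))
    if (identical(res$status, "no_context")) return(NULL)
    return(res$text)
  }
  if (is.logical(res)) return(if (isTRUE(res)) "True" else "False")
  if (is.null(res)) return(NULL)
  as.character(res)[1]
}

score_answer <- function(ans, kind, correct, options) {
  if (is.null(ans) || is.na(ans) || !nzchar(stringr::str_trim(ans))) {
    return(list(correct = FALSE, unparseable = TRUE))
  }
  ans_l <- stringr::str_to_lower(stringr::str_trim(ans))
  if (kind == "tf") {
    if (!ans_l %in% c("true", "false")) {
      return(list(correct = FALSE, unparseable = TRUE))
    }
    return(list(correct = ans_l == stringr::str_to_lower(correct),
      unparseable = FALSE))
  }
  # mcq: option text, or option letter by position
  opt_l <- stringr::str_to_lower(options)
  pick <- NA_integer_
  if (ans_l %in% opt_l) {
    pick <- match(ans_l, opt_l)
  } else if (ans_l %in% stringr::str_to_lower(LETTERS[seq_along(options)])) {
    pick <- match(ans_l, stringr::str_to_lower(LETTERS[seq_along(options)]))
  }
  if (is.na(pick)) return(list(correct = FALSE, unparseable = TRUE))
  list(correct = opt_l[pick] == stringr::str_to_lower(correct), unparseable = FALSE)
}

#' Bootstrap the accuracy distribution of an evaluation
#'
#' Resamples the per-question correctness vector with replacement
#' (`sample_size` draws per iteration, `iterations` times) and records each
#' resample's accuracy, giving the performance distribution used to report
#' benchmark accuracy as mean and standard deviation. A single seeded
#' generator makes the whole distribution reproducible.
#'
#' @param correctness Logical (or 0/1) vector of per-question outcomes.
#' @param sample_size Draws per iteration (default 150).
#' @param iterations Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return A `kg_bootstrap`: `accuracies`, `mean`, `std`, plus the settings.
#' @export
bootstrap_accuracy <- function(correctness, sample_size = 150L,
                               iterations = 1000L, seed = 1L) {
  if (length(correctness) == 0) {
    abort("`correctness` must be non-empty.", class = "kgrag_benchmark_error")
  }
  correctness <- as.logical(correctness)
  if (anyNA(correctness)) abort("`correctness` must not contain missing values.")
  accs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(iterations), function(i) {
      mean(correctness[sample.int(length(correctness), sample_size, replace = TRUE)])
    }, numeric(1))
  })
  structure(
    list(accuracies = accs, mean = mean(accs), std = sd(accs),
      sample_size = as.integer(sample_size), iterations = as.integer(iterations),
      seed = as.integer(seed), point_accuracy = mean(correctness)),
    class = "kg_bootstrap"
  )
}

#' @export
print.kg_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<kg_bootstrap> accuracy %.3f +/- %.3f (%d x %d resamples, seed %d)\n",
    x$mean, x$std, x$iterations, x$sample_size, x$seed))
  invisible(x)
}

#' @method tidy kg_bootstrap
#' @export
tidy.kg_bootstrap <- function(x, ...) {
  tibble(iteration = seq_along(x$accuracies), accuracy = x$accuracies)
}

#' @method glance kg_bootstrap
#' @export
glance.kg_bootstrap <- function(x, ...) {
  tibble(mean = x$mean, std = x$std, point_accuracy = x$point_accuracy,
    sample_size = x$sample_size, iterations = x$iterations, seed = x$seed)
}

#' @export
autoplot.kg_bootstrap <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(x = "Bootstrap accuracy", y = "Iterations") +
    ggplot2::theme_minimal()
}

#' Jaccard similarity of two string sets
#'
#' `|A intersect B| / |A union B|`, computed on the unique elements. Two
#' empty sets score 1 (perfect agreement on nothing).
#'
#' @param a,b Character vectors treated as sets.
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard(c("x", "y"), c("y", "z"))
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Lowercase-perturb a question set
#'
#' The robustness probe: question texts are perturbed by lower-casing either
#' the whole text (default) or just the given entity-name substrings. Ids,
#' options, answers and truth sets are untouched; the operation is
#' idempotent.
#'
#' @param questions Question tibble.
#' @param entities Optional character vector of entity names; when given,
#'   only their (case-insensitive) occurrences in the text are lower-cased.
#' @return The perturbed question tibble.
#' @export
perturb_lowercase <- function(questions, entities = NULL) {
  questions <- as_tibble(questions)
  if (is.null(entities)) {
    questions$text <- stringr::str_to_lower(questions$text)
  } else {
    for (e in entities) {
      questions$text <- stringr::str_replace_all(
        questions$text,
        stringr::regex(escape_regex(e), ignore_case = TRUE),
        stringr::str_to_lower(e)
      )
    }
  }
  questions
}

#' Score a retriever on retrieval questions, before and after perturbation
#'
#' A retriever is a function from question text to the set of association
#' names it retrieved. A question counts as correctly retrieved when its
#' ground-truth set is contained in the retrieved set (`mode = "subset"`,
#' the default) or merely overlaps it (`mode = "overlap"`). The same
#' questions are scored again after [perturb_lowercase()], giving the
#' robustness comparison between semantic and exact-match retrieval.
#'
#' @param questions Retrieval-kind question tibble.
#' @param retriever `function(question_text) -> character vector`.
#' @param mode `"subset"` or `"overlap"`.
#' @param system_name Label for reports.
#' @param perturb Also evaluate on the lower-cased questions (default TRUE).
#' @return A `kg_robustness`: accuracies and per-question outcomes.
#' @export
retrieval_accuracy <- function(questions, retriever,
                               mode = c("subset", "overlap"),
                               system_name = "retriever", perturb = TRUE) {
  mode <- match.arg(mode)
  questions <- as_tibble(questions)
  stopifnot(all(questions$kind == "retrieval"))
  if (nrow(questions) == 0) {
    abort("`questions` is empty.", class = "kgrag_benchmark_error")
  }
  hit <- function(truth, got) {
    if (mode == "subset") all(truth %in% got) else length(intersect(truth, got)) > 0
  }
  score_set <- function(qs) {
    map_lgl(seq_len(nrow(qs)), function(i) {
      hit(qs$truth_set[[i]], retriever(qs$text[i]))
    })
  }
  orig <- score_set(questions)
  pert <- if (perturb) score_set(perturb_lowercase(questions)) else NULL
  structure(
    list(
      system = system_name, mode = mode,
      accuracy_original = mean(orig),
      accuracy_perturbed = if (perturb) mean(pert) else NA_real_,
      per_question = tibble(
        question_id = questions$question_id,
        correct_original = orig,
        correct_perturbed = if (perturb) pert else NA
      )
    ),
    class = "kg_robustness"
  )
}

#' @export
print.kg_robustness <- function(x, ...) {
  cat(sprintf("<kg_robustness> %s (%s mode): %.1f%% original, %s perturbed\n",
    x$system, x$mode, 100 * x$accuracy_original,
    if (is.na(x$accuracy_perturbed)) "not run" else
      sprintf("%.1f%%", 100 * x$accuracy_perturbed)))
  invisible(x)
}

#' @method tidy kg_robustness
#' @export
tidy.kg_robustness <- function(x, ...) {
  x$per_question |> mutate(system = x$system, .before = 1)
}

#' @method glance kg_robustness
#' @export
glance.kg_robustness <- function(x, ...) {
  tibble(system = x$system, mode = x$mode,
    accuracy_original = x$accuracy_original,
    accuracy_perturbed = x$accuracy_perturbed,
    n_questions = nrow(x$per_question))
}

#' @export
autoplot.kg_robustness <- function(object, ...) {
  df <- tidyr::pivot_longer(glance(object),
    cols = c("accuracy_original", "accuracy_perturbed"),
    names_to = "condition", values_to = "accuracy")
  df$condition <- stringr::str_remove(df$condition, "accuracy_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Retrieval accuracy", title = object$system) +
    ggplot2::theme_minimal()
}

#' Compare per-question token usage across systems
#'
#' Each system is a function from question text to a token count (or to a
#' `kg_answer`, whose `token_usage` is used). Reports the per-question
#' counts and the per-system mean with its standard error.
#'
#' @param questions Question tibble.
#' @param systems Named list of system functions.
#' @return A `kg_token_report`: `per_question` tibble and `summary` tibble
#'   (`system`, `mean_tokens`, `sem`, `n`).
#' @export
token_usage_report <- function(questions, systems) {
  questions <- as_tibble(questions)
  if (nrow(questions) == 0) {
    abort("`questions` is empty.", class = "kgrag_benchmark_error")
  }
  stopifnot(is.list(systems), !is.null(names(systems)), all(nzchar(names(systems))))
  per <- imap(systems, function(fn, nm) {
    tokens <- map_dbl(questions$text, function(q) {
      res <- fn(q)
      if (inherits(res, "kg_answer")) res$token_usage else as.numeric(res)
    })
    tibble(system = nm, question_id = questions$question_id, tokens = tokens)
  })
  per <- list_rbind(per)
  if (any(per$tokens < 0)) abort("Token counts must be non-negative.")
  summary <- per |>
    group_by(.data$system) |>
    summarise(
      mean_tokens = mean(.data$tokens),
      sem = sd(.data$tokens) / sqrt(n()),
      n = n(), .groups = "drop"
    )
  structure(list(per_question = per, summary = summary),
    class = "kg_token_report")
}

#' @export
print.kg_token_report <- function(x, ...) {
  cat("<kg_token_report>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy kg_token_report
#' @export
tidy.kg_token_report <- function(x, ...) x$per_question

#' @method glance kg_token_report
#' @export
glance.kg_token_report <- function(x, ...) x$summary

#' @export
autoplot.kg_token_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
    ggplot2::aes(x = .data$system, y = .data$mean_tokens)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_tokens - .data$sem,
      ymax = .data$mean_tokens + .data$sem), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Mean token usage (+/- SEM)") +
    ggplot2::theme_minimal()
}
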