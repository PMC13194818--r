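#' Five-criterion rubric scores
#'
#' One answer's scores on the five evaluation criteria — accuracy,
#' completeness, logical consistency, clarity and conciseness, evidence
#' support — each on a 0-10 scale. Raw rater scores are integers;
#' rater-aggregated scores (means of two raters) may be half-integers, so
#' the container accepts any numeric value in \[0, 10\].
#'
#' @param accuracy,completeness,logical_consistency,clarity_conciseness,evidence_support
#'   scores in \[0, 10\].
#' @param integer_only require whole-number scores (used for single-rater
#'   and judge-emitted scores).
#' @return A named numeric vector of class `criterion_scores`.
#' @examples
#' total_score(criterion_scores(8, 7, 9, 9, 8)) # 41
#' @export
criterion_scores <- function(accuracy, completeness, logical_consistency,
                             clarity_conciseness, evidence_support,
                             integer_only = FALSE) {
  s <- c(accuracy = accuracy, completeness = completeness,
         logical_consistency = logical_consistency,
         clarity_conciseness = clarity_conciseness,
         evidence_support = evidence_support)
  if (!is.numeric(s) || anyNA(s)) {
    abort_ragvar("criterion scores must be non-missing numbers",
                 "ragvar_validation_error")
  }
  if (any(s < 0 | s > 10)) {
    bad <- names(s)[s < 0 | s > 10][1]
    abort_ragvar(sprintf("criterion '%s' score %s is outside [0, 10]",
                         bad, s[[bad]]),
                 "ragvar_validation_error")
  }
  if (integer_only && any(s != round(s))) {
    bad <- names(s)[s != round(s)][1]
    abort_ragvar(sprintf("criterion '%s' score %s is not an integer",
                         bad, s[[bad]]),
                 "ragvar_validation_error")
  }
  structure(s, class = "criterion_scores")
}

#' Total rubric score
#'
#' The total score of an answer is defined as the sum of its five criterion
#' scores, hence ranges over \[0, 50\].
#'
#' @param scores a [criterion_scores()] vector.
#' @return A single number in \[0, 50\].
#' @export
total_score <- function(scores) {
  stopifnot(inherits(scores, "criterion_scores"))
  sum(unclass(scores))
}

#' A scored answer
#'
#' Keys one rubric scoring to its question (template id + rs id), the
#' system that produced the answer, and the rater who scored it.
#'
#' @param template_id,rs_id question key.
#' @param system system name (e.g. the RAG pipeline vs a baseline model).
#' @param rater rater label; `"mean"` marks rater-aggregated scores.
#' @param scores a [criterion_scores()].
#' @return An object of class `answer_evaluation` with a `total` field equal
#'   to the sum of the criterion scores.
#' @export
answer_evaluation <- function(template_id, rs_id, system, rater, scores) {
  stopifnot(inherits(scores, "criterion_scores"))
  structure(
    list(template_id = template_id, rs_id = rs_id, system = system,
         rater = rater, scores = scores, total = total_score(scores)),
    class = "answer_evaluation"
  )
}

#' Average two raters' evaluations of the same answer
#'
#' The primary analysis uses the mean of both raters' scores per criterion
#' and for the total; means of two integers may be half-integers and are
#' kept exact (no re-rounding). The mean total always equals the sum of the
#' mean criterion scores.
#'
#' @param e1,e2 `answer_evaluation`s for the same (question, system).
#' @return An `answer_evaluation` with `rater = "mean"`.
#' @export
aggregate_raters <- function(e1, e2) {
  stopifnot(inherits(e1, "answer_evaluation"), inherits(e2, "answer_evaluation"))
  key <- function(e) paste(e$template_id, e$rs_id, e$system, sep = "\r")
  if (!identical(key(e1), key(e2))) {
    abort_ragvar(
      sprintf("rater evaluations refer to different answers: (%s, %s, %s) vs (%s, %s, %s)",
              e1$template_id, e1$rs_id, e1$system,
              e2$template_id, e2$rs_id, e2$system),
      "ragvar_validation_error"
    )
  }
  m <- (unclass(e1$scores) + unclass(e2$scores)) / 2
  answer_evaluation(
    e1$template_id, e1$rs_id, e1$system, "mean",
    do.call(criterion_scores, as.list(m))
  )
}

#' Tally uniquely highest-scoring systems per question
#'
#' A system is credited for a question only when its total score is a
#' *strict* unique maximum over all systems for that question; when the
#' maximum is shared by two or more systems the question counts as a tie
#' and is attributed to no system. Comparison is exact (no rounding is
#' applied before the strict-max test), so half-integer rater means
#' compare faithfully.
#'
#' @param totals a numeric matrix or data.frame of total scores, one row
#'   per question and one column per system. Every question must have a
#'   score for every system; missing cells are an error.
#' @return An object of class `winner_tally`: `counts` (named per-system),
#'   `ties`, and `total`, satisfying `sum(counts) + ties == total`.
#' @examples
#' m <- rbind(q1 = c(A = 45, B = 30, C = 28), q2 = c(A = 40, B = 40, C = 20))
#' winner_tally(m)
#' @export
winner_tally <- function(totals) {
  m <- as.matrix(totals)
  if (!is.numeric(m) || ncol(m) < 2L || nrow(m) < 1L) {
    abort_ragvar("totals must be a numeric question x system matrix with >= 2 systems",
                 "ragvar_validation_error")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("system", seq_len(ncol(m)))
  if (anyNA(m)) {
    abort_ragvar("totals contain missing cells: every question needs a score for every system",
                 "ragvar_validation_error")
  }
  counts <- stats::setNames(integer(ncol(m)), colnames(m))
  ties <- 0L
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    winners <- which(row == max(row))
    if (length(winners) == 1L) {
      counts[winners] <- counts[winners] + 1L
    } else {
      ties <- ties + 1L
    }
  }
  structure(list(counts = counts, ties = ties, total = nrow(m)),
            class = "winner_tally")
}

#' @export
print.winner_tally <- function(x, ...) {
  pct <- tally_percentages(x)
  cat(sprintf("Winner tally over %d questions:\n", x$total))
  for (s in names(x$counts)) {
    cat(sprintf("  %-20s %5d (%.1f%%)\n", s, x$counts[[s]], pct[[s]]))
  }
  cat(sprintf("  %-20s %5d (%.1f%%)\n", "tie (no unique winner)", x$ties,
              pct[["tie"]]))
  invisible(x)
}

# round half-up to `digits` decimals (round() rounds half to even)
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Winner tally as percentages
#'
#' Percentages are count / total x 100, rounded half-up to one decimal
#' (so 135/150 renders as 90.0 and 10/150 as 6.7). The tie share is
#' included under the name `"tie"`.
#'
#' @param tally a [winner_tally()].
#' @return Named numeric vector of percentages (systems plus `"tie"`).
#' @export
tally_percentages <- function(tally) {
  stopifnot(inherits(tally, "winner_tally"))
  if (tally$total <= 0L) {
    abort_ragvar("tally total must be positive", "ragvar_validation_error")
  }
  counts <- c(tally$counts, tie = tally$ties)
  round_half_up(100 * counts / tally$total, 1L)
}

#' The packaged judging rubric
#'
#' Instructions for an LLM acting as judge: restates the five criteria and
#' demands a strict JSON block with one integer score (0-10) per criterion.
#' This rubric is a package-authored stand-in (the production judging
#' prompt is not public); its criterion definitions are the ones the
#' rubric scores are defined by.
#'
#' @param path optional override path.
#' @return Rubric text.
#' @export
judge_rubric <- function(path = NULL) {
  if (is.null(path)) path <- ragvar_resource("judge_rubric.txt")
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}

#' Score one answer with an LLM judge
#'
#' Sends the rubric, the question and the answer to a judge backend and
#' parses the mandated JSON score block. Scores must be integers in 0-10;
#' out-of-range or unparsable output raises a judging error — it is never
#' silently clamped. The judge's raw text is retained for audit.
#'
#' @param question the question that was answered.
#' @param answer the answer text under evaluation.
#' @param llm an [llm_backend()] acting as judge.
#' @param rubric rubric text, defaults to the packaged [judge_rubric()].
#' @return A list with `scores` (a [criterion_scores()]) and `raw` (the
#'   judge's verbatim output).
#' @export
llm_judge <- function(question, answer, llm, rubric = judge_rubric()) {
  stopifnot(inherits(llm, "llm_backend"))
  bundle <- new_prompt_bundle(
    system_text = rubric,
    question_text = sprintf("Question:\n%s\n\nAnswer to evaluate:\n%s",
                            question, answer),
    retrieval_used = FALSE
  )
  raw <- llm$complete(bundle)
  if (!is_string(raw)) {
    abort_ragvar("judge backend returned a non-string output",
                 "ragvar_judging_error")
  }
  block <- regmatches(raw, regexpr("\\{[^{}]*\\}", raw))
  if (length(block) == 0L || !jsonlite::validate(block)) {
    abort_ragvar("judge output contains no parsable JSON score block",
                 "ragvar_judging_error", raw = raw)
  }
  parsed <- jsonlite::fromJSON(block)
  missing <- setdiff(RAGVAR_CRITERIA, names(parsed))
  if (length(missing) > 0L) {
    abort_ragvar(sprintf("judge score block lacks criteria: %s",
                         paste(missing, collapse = ", ")),
                 "ragvar_judging_error", raw = raw)
  }
  scores <- tryCatch(
    do.call(criterion_scores,
            c(lapply(parsed[RAGVAR_CRITERIA], as.numeric),
              list(integer_only = TRUE))),
    ragvar_validation_error = function(e) {
      abort_ragvar(sprintf("judge emitted an invalid score: %s",
                           conditionMessage(e)),
                   "ragvar_judging_error", raw = raw)
    }
  )
  list(scores = scores, raw = raw)
}

#' Deterministic stub judge backend
#'
#' Emits a fixed JSON score block regardless of input — the bookkeeping
#' scaffolding for judge-loop tests.
#'
#' @param accuracy,completeness,logical_consistency,clarity_conciseness,evidence_support
#'   the scores the stub should emit (default 9, 9, 10, 9, 8). Out-of-range
#'   values are deliberately allowed here so error paths can be exercised.
#' @return An `llm_backend` named `"stub-judge"`.
#' @export
stub_judge_backend <- function(accuracy = 9, completeness = 9,
                               logical_consistency = 10,
                               clarity_conciseness = 9,
                               evidence_support = 8) {
  payload <- sprintf(
    '{"accuracy": %s, "completeness": %s, "logical_consistency": %s, "clarity_conciseness": %s, "evidence_support": %s}',
    accuracy, completeness, logical_consistency, clarity_conciseness,
    evidence_support
  )
  llm_backend(function(bundle) {
    paste0("Rubric scores for the submitted answer follow.\n", payload, "\n")
  }, name = "stub-judge")
}

#' Read a long-format score table
#'
#' The canonical interchange format for score tables is long-format CSV,
#' UTF-8, header required, one row per (question, system, rater) with the
#' five criterion columns. A `total` column is recomputed (and verified if
#' present).
#'
#' @param path CSV path.
#' @return A data.frame with columns `template_id`, `rs_id`, `system`,
#'   `rater`, the five criteria, and `total`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("template_id", "rs_id", "system", "rater", RAGVAR_CRITERIA)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort_ragvar(sprintf("score table lacks column(s): %s",
                         paste(missing, collapse = ", ")),
                 "ragvar_validation_error")
  }
  crit <- as.matrix(df[RAGVAR_CRITERIA])
  if (anyNA(crit) || any(crit < 0 | crit > 10)) {
    abort_ragvar("criterion scores must be non-missing and within [0, 10]",
                 "ragvar_validation_error")
  }
  recomputed <- rowSums(crit)
  if ("total" %in% names(df) && any(abs(df$total - recomputed) > 1e-9)) {
    abort_ragvar("'total' column disagrees with the sum of the criteria",
                 "ragvar_validation_error")
  }
  df$total <- recomputed
  df
}

#' Average raters within a long score table
#'
#' @param scores long score table (as from [read_score_table()] or
#'   [simulate_scores()]).
#' @return The same shape with a single `rater = "mean"` row per
#'   (question, system).
#' @export
mean_rater_scores <- function(scores) {
  key <- interaction(scores$template_id, scores$rs_id, scores$system,
                     drop = TRUE)
  agg <- stats::aggregate(scores[c(RAGVAR_CRITERIA, "total")],
                          by = list(key = key), FUN = mean)
  meta <- scores[!duplicated(key), c("template_id", "rs_id", "system")]
  meta <- meta[match(agg$key, unique(key)), ]
  out <- cbind(meta, rater = "mean", agg[c(RAGVAR_CRITERIA, "total")])
  rownames(out) <- NULL
  out
}

#' Pivot a long score table to a question x system matrix
#'
#' @param scores long score table with one row per (question, system)
#'   (average raters first with [mean_rater_scores()] if needed).
#' @param value which column to pivot (default `"total"`).
#' @return Numeric matrix, rows keyed `template_id|rs_id`, columns systems.
#'   Missing cells are an error: the comparison design is fully paired.
#' @export
totals_matrix <- function(scores, value = "total") {
  q <- paste(scores$template_id, scores$rs_id, sep = "|")
  systems <- sort(unique(scores$system))
  questions <- unique(q)
  m <- matrix(NA_real_, nrow = length(questions), ncol = length(systems),
              dimnames = list(questions, systems))
  m[cbind(match(q, questions), match(scores$system, systems))] <-
    scores[[value]]
  if (anyNA(m)) {
    abort_ragvar("score table is not fully paired: some (question, system) cells are missing",
                 "ragvar_validation_error")
  }
  m
}
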