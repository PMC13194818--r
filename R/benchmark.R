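#' Load the question-template registry
#'
#' The packaged registry holds the 50 evaluation question templates, ids
#' `q1`-`q50`, grouped into 8 categories (basic information; allele
#' frequency and population distribution; clinical significance;
#' pharmacogenomics; functional impact; evolutionary context; comparison
#' with related variants; databases and bioinformatics analysis). Every
#' template contains the literal placeholder `{rs}` standing for an rs
#' number. The registry is data, not code: a TSV with columns
#' `id`, `category`, `text`.
#'
#' @param source path to an alternative registry TSV; default is the
#'   packaged registry.
#' @param strict when `TRUE` (default) enforce the canonical registry shape:
#'   exactly 50 templates and exactly 8 categories. Set to `FALSE` to load
#'   experimental registries of other sizes.
#' @return A `data.frame` (classed `question_templates`) with columns
#'   `id`, `category`, `text`.
#' @examples
#' tpl <- load_templates()
#' nrow(tpl)                 # 50
#' length(unique(tpl$category))  # 8
#' @export
load_templates <- function(source = NULL, strict = is.null(source)) {
  if (is.null(source)) source <- ragvar_resource("question_templates.tsv")
  df <- tryCatch(
    utils::read.delim(source, stringsAsFactors = FALSE, quote = "",
                      fileEncoding = "UTF-8"),
    error = function(e) {
      abort_ragvar(sprintf("cannot read template registry '%s': %s",
                           source, conditionMessage(e)),
                   "ragvar_validation_error")
    }
  )
  if (!all(c("id", "category", "text") %in% names(df))) {
    abort_ragvar("template registry needs columns id, category, text",
                 "ragvar_validation_error")
  }
  if (anyDuplicated(df$id)) {
    abort_ragvar("template ids must be unique", "ragvar_validation_error")
  }
  missing_rs <- !grepl("{rs}", df$text, fixed = TRUE)
  if (any(missing_rs)) {
    abort_ragvar(
      sprintf("template(s) without the '{rs}' placeholder: %s",
              paste(df$id[missing_rs], collapse = ", ")),
      "ragvar_validation_error"
    )
  }
  if (strict) {
    if (nrow(df) != 50L) {
      abort_ragvar(sprintf("canonical registry must hold 50 templates, found %d",
                           nrow(df)), "ragvar_validation_error")
    }
    if (length(unique(df$category)) != 8L) {
      abort_ragvar(sprintf("canonical registry must span 8 categories, found %d",
                           length(unique(df$category))),
                   "ragvar_validation_error")
    }
  }
  class(df) <- c("question_templates", "data.frame")
  df
}

#' The packaged synthetic rs list
#'
#' Thirty distinct, validly formatted rs identifiers shipped as a stand-in
#' default: the benchmark design calls for 30 variants but the concrete
#' list is an analysis input, not a constant of the method.
#'
#' @return Character vector of 30 rs ids.
#' @export
default_rs_list <- function() {
  rs <- readLines(ragvar_resource("rs_list_synthetic.txt"), warn = FALSE)
  rs[grepl("^rs[0-9]+$", rs)]
}

#' Build the full template x variant question pool
#'
#' Instantiates every template with every rs number exactly once, in
#' deterministic template-major order. With the canonical 50-template
#' registry and a 30-variant list this yields the full 1500-question pool.
#'
#' @param templates registry from [load_templates()] (or any data.frame
#'   with `id`, `category`, `text`).
#' @param rs_list character vector of distinct rs identifiers.
#' @return A `data.frame` (classed `benchmark_questions`) with columns
#'   `template_id`, `rs_id`, `category`, `question_text`.
#' @examples
#' pool <- build_pool(load_templates(), default_rs_list())
#' nrow(pool)  # 1500
#' @export
build_pool <- function(templates, rs_list) {
  stopifnot(is.data.frame(templates))
  if (!is.character(rs_list) || length(rs_list) == 0L) {
    abort_ragvar("rs_list must be a non-empty character vector",
                 "ragvar_validation_error")
  }
  bad <- !grepl("^rs[0-9]+$", rs_list)
  if (any(bad)) {
    abort_ragvar(sprintf("invalid rs identifier(s): %s",
                         paste(rs_list[bad], collapse = ", ")),
                 "ragvar_validation_error")
  }
  if (anyDuplicated(rs_list)) {
    abort_ragvar("rs_list contains duplicates", "ragvar_validation_error")
  }
  grid <- expand.grid(rs_idx = seq_along(rs_list),
                      t_idx = seq_len(nrow(templates)))
  # template-major: all rs for q1, then all rs for q2, ...
  out <- data.frame(
    template_id = templates$id[grid$t_idx],
    rs_id = rs_list[grid$rs_idx],
    category = templates$category[grid$t_idx],
    question_text = vapply(seq_len(nrow(grid)), function(i) {
      gsub("{rs}", rs_list[grid$rs_idx[i]],
           templates$text[grid$t_idx[i]], fixed = TRUE)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("benchmark_questions", "data.frame")
  out
}

#' Constrained random subsample of the question pool
#'
#' Draws exactly `n` distinct questions such that every template appears at
#' least once: first one uniformly random question per template, then the
#' remaining `n - #templates` uniformly without replacement from the rest.
#' Every pool question has positive inclusion probability and the draw is
#' reproducible for a fixed seed.
#'
#' @param pool output of [build_pool()].
#' @param n sample size; must be at least the number of distinct templates
#'   in the pool and at most the pool size.
#' @param seed integer seed controlling the draw (RNG state is restored
#'   afterwards).
#' @return A `benchmark_questions` data.frame of `n` rows.
#' @export
sample_constrained <- function(pool, n, seed = 1L) {
  stopifnot(is.data.frame(pool))
  template_ids <- unique(pool$template_id)
  if (!is_count(n)) {
    abort_ragvar("n must be a positive integer", "ragvar_validation_error")
  }
  if (n < length(template_ids)) {
    abort_ragvar(
      sprintf("n = %d is below the %d distinct templates: the every-template constraint is infeasible",
              n, length(template_ids)),
      "ragvar_infeasible_error"
    )
  }
  if (n > nrow(pool)) {
    abort_ragvar(sprintf("n = %d exceeds the pool size %d", n, nrow(pool)),
                 "ragvar_infeasible_error")
  }
  idx <- withr::with_seed(seed, {
    forced <- vapply(template_ids, function(tid) {
      rows <- which(pool$template_id == tid)
      if (length(rows) == 1L) rows else sample(rows, 1L)
    }, integer(1))
    rest <- setdiff(seq_len(nrow(pool)), forced)
    extra_n <- n - length(forced)
    extra <- if (extra_n > 0L) {
      if (length(rest) == 1L) rest else sample(rest, extra_n)
    } else integer(0)
    sort(c(forced, extra))
  })
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
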