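#' LLM backend contract
#'
#' A backend is anything with a `complete(bundle)` function mapping a
#' `prompt_bundle` to answer text, plus a name for provenance. Cloud or
#' self-hosted models plug in here; the package itself ships only
#' deterministic stubs ([stub_llm_backend()], [stub_judge_backend()]),
#' which is all the quantitative machinery requires.
#'
#' @param complete `function(bundle) -> character(1)`.
#' @param name backend name recorded in answer envelopes.
#' @return An object of class `llm_backend`.
#' @export
llm_backend <- function(complete, name = "custom") {
  stopifnot(is.function(complete), is_string(name))
  structure(list(complete = complete, name = name), class = "llm_backend")
}

#' Deterministic stub answer backend
#'
#' Renders a fixed-structure answer that walks the six required items,
#' filling each from the bundle's retrieved JSON when retrieval succeeded
#' and explicitly stating that there are no data otherwise. Identical
#' bundles always yield byte-identical text, which lets end-to-end tests
#' assert on content without any model.
#'
#' @return An `llm_backend` named `"stub"`.
#' @export
stub_llm_backend <- function() {
  llm_backend(stub_llm_answer, name = "stub")
}

# re-raise any error with the pipeline stage attached
with_stage <- function(stage, expr) {
  tryCatch(
    expr,
    error = function(e) {
      if (inherits(e, "ragvar_stage_error")) stop(e)
      abort_ragvar(
        sprintf("[stage %s] %s", stage, conditionMessage(e)),
        c("ragvar_stage_error", setdiff(class(e), c("error", "condition"))),
        stage = stage
      )
    }
  )
}

new_answer_envelope <- function(question, answer_text, retrieval_used,
                                identifier = NULL, normalized_query = NULL,
                                retrieved_json = NULL, backend = NA_character_,
                                elapsed_s = NA_real_, lookup_miss = FALSE,
                                error = NULL) {
  structure(
    list(question = question, answer_text = answer_text,
         retrieval_used = retrieval_used, identifier = identifier,
         normalized_query = normalized_query, retrieved_json = retrieved_json,
         backend = backend, elapsed_s = elapsed_s, lookup_miss = lookup_miss,
         error = error),
    class = "answer_envelope"
  )
}

#' @export
print.answer_envelope <- function(x, ...) {
  cat(sprintf("<answer_envelope backend=%s retrieval_used=%s%s>\n",
              x$backend, x$retrieval_used,
              if (isTRUE(x$lookup_miss)) " (lookup miss)" else ""))
  cat("Q: ", x$question, "\n", sep = "")
  if (!is.null(x$error)) {
    cat("error: ", x$error, "\n", sep = "")
  } else {
    cat(substr(x$answer_text, 1L, 400L), "\n")
  }
  invisible(x)
}

#' Answer one free-text variant question end to end
#'
#' Orchestrates the full pipeline: identifier extraction, normalization to
#' an rs query or GRCh38 allele, variant retrieval, prompt assembly, and
#' backend completion. Questions without any identifier skip retrieval
#' entirely (the variant client is never called) and are answered from the
#' baseline prompt; so are questions whose variant is unknown to the store,
#' with the failed lookup recorded in the envelope.
#'
#' @param question free-text question containing at most one variant
#'   identifier.
#' @param client a variant client, e.g. [mock_variant_client()].
#' @param llm an [llm_backend()].
#' @param recoder optional [fixture_recoder()]; needed only for HGVS
#'   notations that are not genomic-level SNVs.
#' @param template prompt template text.
#' @return An `answer_envelope`. When `retrieval_used` is `TRUE` the
#'   envelope always carries the identifier, the normalized query and the
#'   retrieved JSON.
#' @section Errors: failures are re-raised with the pipeline stage
#'   (`extract` / `recode` / `fetch` / `complete`) in the message and
#'   condition.
#' @examples
#' client <- mock_variant_client(system.file("extdata", "variants", package = "ragvar"))
#' env <- answer_question("Which gene is associated with rs34637584?",
#'                        client = client, llm = stub_llm_backend())
#' env$retrieval_used
#' @export
answer_question <- function(question, client, llm, recoder = NULL,
                            template = prompt_template()) {
  stopifnot(inherits(llm, "llm_backend"))
  t0 <- proc.time()[["elapsed"]]
  id <- with_stage("extract", extract_identifier(question))

  normalized <- NULL
  raw_json <- NULL
  lookup_miss <- FALSE
  if (!is.null(id)) {
    normalized <- with_stage("recode", normalize_identifier(id, recoder))
    raw_json <- with_stage("fetch", fetch_variant(client, normalized))
    lookup_miss <- is.null(raw_json)
  }

  if (!is.null(raw_json)) {
    bundle <- build_rag_prompt(question, raw_json, template = template)
  } else {
    bundle <- build_baseline_prompt(question, template = template)
  }
  answer <- with_stage("complete", llm$complete(bundle))
  if (!is_string(answer)) {
    abort_ragvar("backend returned a non-string answer", "ragvar_backend_error")
  }

  new_answer_envelope(
    question = question,
    answer_text = answer,
    retrieval_used = bundle$retrieval_used,
    identifier = id,
    normalized_query = normalized,
    retrieved_json = bundle$retrieved_json,
    backend = llm$name,
    elapsed_s = proc.time()[["elapsed"]] - t0,
    lookup_miss = lookup_miss
  )
}

#' Answer a batch of questions
#'
#' Output order always matches input order, regardless of how the work is
#' scheduled, so downstream evaluation can join on position. A failure in
#' one question yields an error envelope (with the condition message under
#' `$error`) and never aborts the batch.
#'
#' @param questions character vector of questions.
#' @param concurrency number of worker processes (forked via the parallel
#'   package when > 1; the default 1 runs serially, which with the stub
#'   backend is byte-deterministic).
#' @inheritParams answer_question
#' @return A list of `answer_envelope`s, one per question, in input order.
#' @export
answer_batch <- function(questions, client, llm, recoder = NULL,
                         template = prompt_template(), concurrency = 1L) {
  if (!is.character(questions) || length(questions) == 0L) {
    abort_ragvar("questions must be a non-empty character vector",
                 "ragvar_parse_error")
  }
  if (!is_count(concurrency)) {
    abort_ragvar("concurrency must be a positive integer", "ragvar_parse_error")
  }
  one <- function(q) {
    tryCatch(
      answer_question(q, client = client, llm = llm, recoder = recoder,
                      template = template),
      error = function(e) {
        new_answer_envelope(
          question = q, answer_text = NA_character_, retrieval_used = FALSE,
          backend = llm$name, error = conditionMessage(e)
        )
      }
    )
  }
  if (concurrency > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(questions, one, mc.cores = concurrency)
  } else {
    lapply(questions, one)
  }
}

#' Serialize answer envelopes to JSON-Lines
#'
#' @param envelopes list of `answer_envelope`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_envelopes <- function(envelopes, path) {
  lines <- vapply(envelopes, function(e) {
    as.character(jsonlite::toJSON(list(
      question = e$question,
      answer_text = e$answer_text,
      retrieval_used = e$retrieval_used,
      identifier = if (!is.null(e$identifier)) unclass(e$identifier),
      normalized_query = if (inherits(e$normalized_query, "genomic_allele")) {
        render_genomic_hgvs(e$normalized_query)
      } else e$normalized_query,
      retrieved_json = e$retrieved_json,
      backend = e$backend,
      lookup_miss = e$lookup_miss,
      error = e$error
    ), auto_unbox = TRUE, null = "null", digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
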