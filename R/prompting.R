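PLACEHOLDER <- "{togovar_response}"
SECTION3_HEADER <- "## Information Retrieved from the TogoVar API"
ROLE_SENTENCE <- "You are an expert assistant specializing in human genome variant analysis."

#' The three-section prompt template
#'
#' Stored once as a plain-text resource with the literal
#' `{togovar_response}` placeholder; both prompt builders derive from it so
#' no divergent copies can drift apart. Section 1 states the expert-assistant
#' role, section 2 lists the six items every answer must cover (variant
#' identification; disease associations; literature evidence; allele
#' frequency comparison; GWAS findings; database link), and section 3
#' carries the retrieved variant JSON.
#'
#' @param path optional override path to an alternative template file; the
#'   file must contain the placeholder exactly once.
#' @return The template as a single string.
#' @export
prompt_template <- function(path = NULL) {
  if (is.null(path)) path <- ragvar_resource("prompt_template.txt")
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  n <- count_fixed(txt, PLACEHOLDER)
  if (n != 1L) {
    abort_ragvar(
      sprintf("template must contain '%s' exactly once (found %d)",
              PLACEHOLDER, n),
      "ragvar_validation_error"
    )
  }
  txt
}

count_fixed <- function(text, pattern) {
  lengths(regmatches(text, gregexpr(pattern, text, fixed = TRUE)))
}

new_prompt_bundle <- function(system_text, question_text, retrieval_used,
                              retrieved_json = NULL) {
  structure(
    list(system_text = system_text, question_text = question_text,
         retrieval_used = retrieval_used, retrieved_json = retrieved_json),
    class = "prompt_bundle"
  )
}

#' @export
print.prompt_bundle <- function(x, ...) {
  cat(sprintf("<prompt_bundle retrieval_used=%s, %d chars system text>\n",
              x$retrieval_used, nchar(x$system_text)))
  cat("question: ", x$question_text, "\n", sep = "")
  invisible(x)
}

#' Assemble the retrieval-augmented prompt
#'
#' Substitutes the retrieved variant JSON for the `{togovar_response}`
#' placeholder in the three-section template. The JSON is embedded verbatim
#' and exactly once; the placeholder never survives into the output.
#'
#' @param question the user's question (passed through unchanged).
#' @param retrieved_json raw JSON text from the variant store. Must be
#'   syntactically valid JSON — malformed payloads are refused rather than
#'   spliced into a prompt.
#' @param template template text, defaults to the packaged resource.
#' @return A `prompt_bundle` with `retrieval_used = TRUE`.
#' @export
build_rag_prompt <- function(question, retrieved_json,
                             template = prompt_template()) {
  if (!is_string(question) || !nzchar(question)) {
    abort_ragvar("question must be a non-empty string", "ragvar_parse_error")
  }
  if (!is_string(retrieved_json) || !jsonlite::validate(retrieved_json)) {
    abort_ragvar("retrieved_json must be syntactically valid JSON text",
                 "ragvar_validation_error")
  }
  system_text <- sub(PLACEHOLDER, retrieved_json, template, fixed = TRUE)
  new_prompt_bundle(system_text, question, TRUE, retrieved_json)
}

#' Assemble the retrieval-free baseline prompt
#'
#' The baseline (used both for the comparison system without database
#' access and for pipeline runs where no identifier was found or the
#' variant was unknown) is the same template minus section 3 and minus
#' every sentence that refers to the variant-database API or to retrieved
#' results. The six answer items are retained, so baseline and RAG answers
#' are judged against the same content checklist.
#'
#' @inheritParams build_rag_prompt
#' @return A `prompt_bundle` with `retrieval_used = FALSE`.
#' @export
build_baseline_prompt <- function(question, template = prompt_template()) {
  if (!is_string(question) || !nzchar(question)) {
    abort_ragvar("question must be a non-empty string", "ragvar_parse_error")
  }
  # drop section 3 (header onwards)
  cut <- regexpr(SECTION3_HEADER, template, fixed = TRUE)
  body <- if (cut > 0L) substr(template, 1L, cut - 1L) else template
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  # headings and the numbered item list are structural; prose lines are
  # filtered sentence-by-sentence
  lines <- vapply(lines, function(line) {
    if (grepl("^#", line) || grepl("^[0-9]+\\.", line) || !nzchar(trimws(line))) {
      return(line)
    }
    sentences <- strsplit(line, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    sentences <- sentences[!grepl("TogoVar API|retriev", sentences,
                                  ignore.case = TRUE)]
    paste(sentences, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  system_text <- sub("\\s+$", "", paste(lines, collapse = "\n"))
  new_prompt_bundle(system_text, question, FALSE, NULL)
}
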