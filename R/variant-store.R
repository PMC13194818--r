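#' Integrated variant annotation record
#'
#' One variant's annotation as returned by the variant-database API:
#' identifiers, GRCh38 position and alleles, gene symbol, clinical
#' significance with conditions, most severe Sequence Ontology consequence,
#' HGVS notations at protein/cDNA/genomic level, pathogenicity predictions
#' (SIFT, PolyPhen, AlphaMissense), allele frequencies per population
#' dataset, and external resource links. The JSON layout mirrors the
#' published field roster for the worked example rs34637584; the schema
#' document ships at `inst/extdata/variant_record.schema.json`.
#'
#' Mandatory fields are the database id, chromosome, position and the two
#' alleles; everything else is optional and simply omitted from rendered
#' JSON when absent — absent annotation is never replaced by a fabricated
#' default.
#'
#' @param togovar_id database variant identifier (e.g. `"tgv45580587"`).
#' @param chromosome,position,ref,alt GRCh38 coordinates and alleles, as in
#'   [genomic_allele()].
#' @param rs_id optional dbSNP id.
#' @param gene_symbol optional gene symbol.
#' @param clinical_significance list of entries, each
#'   `list(condition =, interpretations = character())`.
#' @param most_severe_consequence optional
#'   `list(accession = "SO_...", label = ...)`.
#' @param hgvs named list with any of `protein`, `cdna`, `genomic`.
#' @param predictions named list, tool -> `list(score =, label =)`; SIFT,
#'   PolyPhen and AlphaMissense scores must lie in \[0, 1\].
#' @param allele_frequencies named numeric vector/list, dataset -> frequency
#'   in \[0, 1\]. Dataset names are free-form (ToMMo, gnomAD Genomes, ...).
#' @param external_links named character vector/list, resource -> URL.
#' @return An object of class `variant_record`.
#' @export
variant_record <- function(togovar_id, chromosome, position, ref, alt,
                           rs_id = NULL, gene_symbol = NULL,
                           clinical_significance = list(),
                           most_severe_consequence = NULL,
                           hgvs = list(), predictions = list(),
                           allele_frequencies = list(),
                           external_links = list()) {
  rec <- structure(
    list(
      togovar_id = togovar_id, rs_id = rs_id,
      chromosome = as.character(chromosome), position = position,
      ref = ref, alt = alt, gene_symbol = gene_symbol,
      clinical_significance = clinical_significance,
      most_severe_consequence = most_severe_consequence,
      hgvs = hgvs, predictions = predictions,
      allele_frequencies = as.list(allele_frequencies),
      external_links = as.list(external_links)
    ),
    class = "variant_record"
  )
  validate_variant_record(rec)
}

#' Validate a variant record against its invariants
#'
#' @param rec a `variant_record`.
#' @return `rec`, invisibly usable, after checking every invariant; a
#'   violation raises a validation error naming the offending field.
#' @export
validate_variant_record <- function(rec) {
  stopifnot(inherits(rec, "variant_record"))
  fail <- function(field, msg) {
    abort_ragvar(sprintf("invalid variant record: field '%s' %s", field, msg),
                 "ragvar_validation_error", field = field)
  }
  for (field in c("togovar_id", "chromosome", "ref", "alt")) {
    v <- rec[[field]]
    if (!is_string(v) || !nzchar(v)) fail(field, "is missing or empty")
  }
  p <- rec$position
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1 ||
      p != as.integer(p)) {
    fail("position", "must be a positive 1-based integer")
  }
  if (!rec$chromosome %in% VALID_CHROMOSOMES) fail("chromosome", "is not a valid chromosome")
  if (identical(rec$ref, rec$alt)) fail("alt", "must differ from ref")
  if (!is.null(rec$rs_id) && !grepl("^rs[0-9]+$", rec$rs_id)) {
    fail("rs_id", "is not an rs identifier")
  }
  for (entry in rec$clinical_significance) {
    if (!is.list(entry) || !is_string(entry$condition)) {
      fail("clinical_significance", "entries need a 'condition' string")
    }
  }
  msc <- rec$most_severe_consequence
  if (!is.null(msc) && (!is.list(msc) || !is_string(msc$accession) ||
                        !is_string(msc$label))) {
    fail("most_severe_consequence", "needs 'accession' and 'label'")
  }
  if (length(rec$hgvs) > 0L) {
    bad <- setdiff(names(rec$hgvs), c("protein", "cdna", "genomic"))
    if (length(bad) > 0L) {
      fail("hgvs", sprintf("has unknown level(s): %s", paste(bad, collapse = ", ")))
    }
  }
  bounded_tools <- c("SIFT", "PolyPhen", "AlphaMissense")
  for (tool in names(rec$predictions)) {
    pr <- rec$predictions[[tool]]
    if (!is.list(pr) || !is.numeric(pr$score)) {
      fail("predictions", sprintf("entry '%s' needs a numeric 'score'", tool))
    }
    if (tool %in% bounded_tools && (pr$score < 0 || pr$score > 1)) {
      fail("predictions", sprintf("%s score %s is outside [0, 1]", tool, pr$score))
    }
  }
  for (ds in names(rec$allele_frequencies)) {
    f <- rec$allele_frequencies[[ds]]
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
      fail("allele_frequencies",
           sprintf("dataset '%s' has frequency outside [0, 1]", ds))
    }
  }
  rec
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record %s (%s) chr%s:%d %s>%s gene=%s>\n",
              x$togovar_id, x$rs_id %||% "no rs", x$chromosome, x$position,
              x$ref, x$alt, x$gene_symbol %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse variant-record JSON
#'
#' Maps every field of the record schema; absent optional fields stay empty.
#' Out-of-range values (a frequency outside \[0,1\], position below 1) and
#' missing mandatory identifiers raise a validation error naming the field.
#'
#' @param json_text a JSON document as text.
#' @return A [variant_record()].
#' @export
parse_record <- function(json_text) {
  if (!jsonlite::validate(json_text)) {
    abort_ragvar("record text is not syntactically valid JSON",
                 "ragvar_parse_error")
  }
  x <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  need <- function(field) {
    if (is.null(x[[field]])) {
      abort_ragvar(
        sprintf("invalid variant record: field '%s' is missing", field),
        "ragvar_validation_error", field = field
      )
    }
    x[[field]]
  }
  cs <- lapply(x$clinical_significance %||% list(), function(e) {
    list(condition = e$condition,
         interpretations = as.character(unlist(e$interpretations)))
  })
  preds <- lapply(x$predictions %||% list(), function(p) {
    list(score = as.numeric(p$score), label = p$label)
  })
  variant_record(
    togovar_id = need("togovar_id"),
    rs_id = x$rs_id,
    chromosome = need("chromosome"),
    position = need("position"),
    ref = need("ref"),
    alt = need("alt"),
    gene_symbol = x$gene_symbol,
    clinical_significance = cs,
    most_severe_consequence = x$most_severe_consequence,
    hgvs = x$hgvs %||% list(),
    predictions = preds,
    allele_frequencies = lapply(x$allele_frequencies %||% list(), as.numeric),
    external_links = lapply(x$external_links %||% list(), as.character)
  )
}

#' Render a variant record as JSON
#'
#' Round-trip inverse of [parse_record()]: absent optional fields are
#' omitted from the output rather than serialized as null.
#'
#' @param record a [variant_record()].
#' @param pretty pretty-print the JSON.
#' @return JSON text (a plain character scalar).
#' @export
render_record <- function(record, pretty = TRUE) {
  validate_variant_record(record)
  out <- list(togovar_id = record$togovar_id)
  if (!is.null(record$rs_id)) out$rs_id <- record$rs_id
  out$chromosome <- record$chromosome
  out$position <- record$position
  out$ref <- record$ref
  out$alt <- record$alt
  if (!is.null(record$gene_symbol)) out$gene_symbol <- record$gene_symbol
  if (length(record$clinical_significance) > 0L) {
    out$clinical_significance <- lapply(record$clinical_significance, function(e) {
      list(condition = e$condition, interpretations = as.list(e$interpretations))
    })
  }
  if (!is.null(record$most_severe_consequence)) {
    out$most_severe_consequence <- record$most_severe_consequence
  }
  if (length(record$hgvs) > 0L) out$hgvs <- record$hgvs
  if (length(record$predictions) > 0L) out$predictions <- record$predictions
  if (length(record$allele_frequencies) > 0L) {
    out$allele_frequencies <- record$allele_frequencies
  }
  if (length(record$external_links) > 0L) out$external_links <- record$external_links
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                pretty = pretty))
}

#' Mock variant-database client backed by a fixture directory
#'
#' Implements the variant-client contract — fetch raw JSON for an rs query
#' or a GRCh38 genomic allele — as a deterministic read of a fixture
#' directory holding one `<rs>.json` (or `<chrom>-<pos>-<ref>-<alt>.json`)
#' per variant. Every fetch is appended to an in-memory call log so tests
#' can assert that the no-identifier pipeline path never touches the store.
#'
#' @param fixture_dir directory of fixture JSON files.
#' @return An object of class `variant_client`.
#' @seealso [fetch_variant()], [client_calls()]
#' @export
mock_variant_client <- function(fixture_dir) {
  log <- new.env(parent = emptyenv())
  log$calls <- list()
  structure(list(fixture_dir = fixture_dir, log = log),
            class = "variant_client")
}

#' Retrieve raw variant JSON for a normalized query
#'
#' The raw JSON text is preserved verbatim (it is substituted byte-for-byte
#' into the prompt later). A variant absent from the store returns `NULL` —
#' "not found" is a normal outcome, distinct from a transport/IO failure,
#' which raises a retrieval error.
#'
#' @param client a `variant_client`.
#' @param query an rs string or a [genomic_allele()], as produced by
#'   [normalize_identifier()].
#' @return Raw JSON text, or `NULL` when the variant is unknown.
#' @export
fetch_variant <- function(client, query) {
  stopifnot(inherits(client, "variant_client"))
  key <- if (inherits(query, "genomic_allele")) {
    paste(query$chromosome, query$position, query$ref, query$alt, sep = "-")
  } else if (is_string(query) && grepl("^rs[0-9]+$", query)) {
    query
  } else {
    abort_ragvar("query must be an rs string or a genomic_allele",
                 "ragvar_parse_error")
  }
  client$log$calls <- c(client$log$calls, list(key))
  dir <- client$fixture_dir
  if (!dir.exists(dir) || file.access(dir, 4) != 0L) {
    abort_ragvar(
      sprintf("fixture directory '%s' is missing or unreadable", dir),
      "ragvar_retrieval_error"
    )
  }
  path <- file.path(dir, paste0(key, ".json"))
  if (!file.exists(path) && inherits(query, "genomic_allele")) {
    # fall back to scanning rs-keyed fixtures for a coordinate match
    for (f in list.files(dir, pattern = "\\.json$", full.names = TRUE)) {
      rec <- tryCatch(parse_record(paste(readLines(f, warn = FALSE),
                                         collapse = "\n")),
                      ragvar_error = function(e) NULL)
      if (!is.null(rec) &&
          identical(rec$chromosome, query$chromosome) &&
          identical(rec$position, query$position) &&
          identical(rec$ref, query$ref) && identical(rec$alt, query$alt)) {
        path <- f
        break
      }
    }
  }
  if (!file.exists(path)) {
    return(NULL)
  }
  raw <- tryCatch(
    paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n"),
    error = function(e) {
      abort_ragvar(sprintf("cannot read fixture '%s': %s", path,
                           conditionMessage(e)),
                   "ragvar_retrieval_error")
    }
  )
  raw
}

#' Call log of a mock variant client
#'
#' @param client a `variant_client`.
#' @return Character vector of query keys, in call order.
#' @export
client_calls <- function(client) {
  stopifnot(inherits(client, "variant_client"))
  as.character(unlist(client$log$calls))
}
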