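#' Variant identifier found in a question
#'
#' A lightweight tagged value: `kind` is `"rs"` (dbSNP reference SNP id,
#' e.g. `rs34637584`) or `"hgvs"` (any HGVS notation, which always contains
#' a `:` separating the reference sequence from the variant description).
#'
#' @param kind `"rs"` or `"hgvs"`.
#' @param raw the identifier text as matched in the question (rs ids are
#'   stored in canonical lowercase).
#' @return An object of class `variant_identifier`.
#' @examples
#' variant_identifier("rs", "rs34637584")
#' @export
variant_identifier <- function(kind, raw) {
  kind <- match.arg(kind, c("rs", "hgvs"))
  if (!is_string(raw) || !nzchar(raw)) {
    abort_ragvar("identifier 'raw' must be a non-empty string", "ragvar_parse_error")
  }
  if (kind == "rs" && !grepl("^rs[0-9]+$", raw)) {
    abort_ragvar(
      sprintf("not a valid rs identifier: '%s'", raw),
      "ragvar_parse_error"
    )
  }
  if (kind == "hgvs" && !grepl(":", raw, fixed = TRUE)) {
    abort_ragvar(
      sprintf("HGVS notation must contain ':': '%s'", raw),
      "ragvar_parse_error"
    )
  }
  structure(list(kind = kind, raw = raw), class = "variant_identifier")
}

#' @export
print.variant_identifier <- function(x, ...) {
  cat(sprintf("<variant_identifier %s: %s>\n", x$kind, x$raw))
  invisible(x)
}

VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")

#' GRCh38 genomic allele
#'
#' The normalized representation used to query a variant database when the
#' question carries an HGVS notation instead of an rs number: chromosome,
#' 1-based GRCh38 position, reference allele and alternate allele.
#'
#' @param chromosome chromosome name, one of 1-22, X, Y, MT (a leading
#'   `"chr"` prefix is stripped).
#' @param position 1-based genomic position (positive integer).
#' @param ref,alt non-empty uppercase nucleotide strings; must differ.
#' @return An object of class `genomic_allele`.
#' @examples
#' genomic_allele("12", 40340400, "G", "A")
#' @export
genomic_allele <- function(chromosome, position, ref, alt) {
  chromosome <- sub("^chr", "", as.character(chromosome))
  if (!chromosome %in% VALID_CHROMOSOMES) {
    abort_ragvar(
      sprintf("invalid chromosome '%s'", chromosome),
      "ragvar_parse_error"
    )
  }
  if (!is.numeric(position) || length(position) != 1L || is.na(position) ||
      position < 1 || position != as.integer(position)) {
    abort_ragvar(
      sprintf("position must be a positive 1-based integer, got '%s'", position),
      "ragvar_parse_error"
    )
  }
  ref <- toupper(ref); alt <- toupper(alt)
  for (allele in list(c("ref", ref), c("alt", alt))) {
    if (!is_string(allele[[2]]) || !grepl("^[ACGT]+$", allele[[2]])) {
      abort_ragvar(
        sprintf("%s allele must be a non-empty A/C/G/T string, got '%s'",
                allele[[1]], allele[[2]]),
        "ragvar_parse_error"
      )
    }
  }
  if (identical(ref, alt)) {
    abort_ragvar("ref and alt alleles must differ", "ragvar_parse_error")
  }
  structure(
    list(chromosome = chromosome, position = as.integer(position),
         ref = ref, alt = alt),
    class = "genomic_allele"
  )
}

#' @export
print.genomic_allele <- function(x, ...) {
  cat(sprintf("<genomic_allele %s>\n", render_genomic_hgvs(x)))
  invisible(x)
}

#' @export
format.genomic_allele <- function(x, ...) render_genomic_hgvs(x)

RS_PATTERN <- "\\brs[0-9]+\\b"
# HGVS-ish token: reference sequence, ':', a level prefix (g./c./p./n./m./r.)
# and a description. Deliberately permissive — full HGVS is out of scope;
# anything matched here is either parsed locally (genomic SNVs) or handed to
# the recoder contract.
HGVS_PATTERN <- "\\b[A-Za-z][A-Za-z0-9_.]*:[gcpnmr]\\.[A-Za-z0-9_*+>=-]+"

#' Extract the single variant identifier from a question
#'
#' Scans free text for a dbSNP rs number (word-bounded, case-insensitive
#' `rs[0-9]+`, canonicalized to lowercase) or an HGVS notation. When both
#' kinds are present the rs number wins: it can be sent to the variant
#' database directly, with no recoding step. Repeated mentions of the *same*
#' rs number are deduplicated; two *distinct* rs numbers (or two distinct
#' HGVS notations) raise an ambiguity error, since the pipeline is scoped to
#' questions about a single variant.
#'
#' @param question non-empty free-text question.
#' @return A [variant_identifier()] or `NULL` when no identifier is present.
#' @examples
#' extract_identifier("What is the clinical significance of rs34637584 in ClinVar?")
#' extract_identifier("Tell me about Parkinson disease.") # NULL
#' @export
extract_identifier <- function(question) {
  if (!is_string(question) || !nzchar(question)) {
    abort_ragvar("question must be a non-empty string", "ragvar_parse_error")
  }
  rs_hits <- regmatches(
    question,
    gregexpr(RS_PATTERN, question, perl = TRUE, ignore.case = TRUE)
  )[[1]]
  rs_hits <- unique(tolower(rs_hits))
  if (length(rs_hits) > 1L) {
    abort_ragvar(
      sprintf("question contains %d distinct rs numbers (%s); only a single variant identifier is supported",
              length(rs_hits), paste(rs_hits, collapse = ", ")),
      "ragvar_ambiguity_error"
    )
  }
  if (length(rs_hits) == 1L) {
    return(variant_identifier("rs", rs_hits))
  }
  hgvs_hits <- regmatches(
    question,
    gregexpr(HGVS_PATTERN, question, perl = TRUE)
  )[[1]]
  hgvs_hits <- unique(hgvs_hits)
  if (length(hgvs_hits) > 1L) {
    abort_ragvar(
      sprintf("question contains %d distinct HGVS notations (%s); only a single variant identifier is supported",
              length(hgvs_hits), paste(hgvs_hits, collapse = ", ")),
      "ragvar_ambiguity_error"
    )
  }
  if (length(hgvs_hits) == 1L) {
    return(variant_identifier("hgvs", hgvs_hits))
  }
  NULL
}

GENOMIC_SNV_PATTERN <- "^chr([0-9XYMT]+):g\\.([0-9]+)([ACGTacgt]+)>([ACGTacgt]+)$"

#' Parse a genomic-level HGVS single-nucleotide substitution locally
#'
#' Only the `chr{C}:g.{POS}{REF}>{ALT}` single-nucleotide substitution
#' grammar is handled here, so that the common case needs no external
#' recoding. Everything else — transcript (`c.`) and protein (`p.`) level
#' notations, `NC_`-style reference sequences, indels, duplications —
#' returns `NULL` and is expected to go through the recoder contract.
#'
#' @param hgvs an HGVS-like string.
#' @return A [genomic_allele()], or `NULL` when the notation is not a
#'   locally parseable genomic SNV. A string that *matches* the SNV grammar
#'   but violates an invariant (position 0, identical alleles, unknown
#'   chromosome) raises a parse error naming the offending fragment.
#' @examples
#' parse_genomic_hgvs("chr12:g.40340400G>A")
#' parse_genomic_hgvs("ENSP00000298910.7:p.Gly2019Ser") # NULL: protein level
#' @export
parse_genomic_hgvs <- function(hgvs) {
  if (!is_string(hgvs)) {
    abort_ragvar("hgvs must be a string", "ragvar_parse_error")
  }
  m <- regmatches(hgvs, regexec(GENOMIC_SNV_PATTERN, hgvs))[[1]]
  if (length(m) == 0L) {
    return(NULL)
  }
  chrom <- m[2]; pos <- m[3]; ref <- m[4]; alt <- m[5]
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    # multi-nucleotide substitution: outside the local SNV grammar
    return(NULL)
  }
  pos_num <- suppressWarnings(as.numeric(pos))
  if (is.na(pos_num) || pos_num < 1) {
    abort_ragvar(
      sprintf("invalid genomic position in '%s': position must be >= 1 (got '%s')",
              hgvs, pos),
      "ragvar_parse_error"
    )
  }
  tryCatch(
    genomic_allele(chrom, pos_num, toupper(ref), toupper(alt)),
    ragvar_parse_error = function(e) {
      abort_ragvar(
        sprintf("cannot parse '%s': %s", hgvs, conditionMessage(e)),
        "ragvar_parse_error"
      )
    }
  )
}

#' Render a genomic allele as canonical genomic HGVS
#'
#' Inverse of [parse_genomic_hgvs()] on the accepted grammar:
#' `render_genomic_hgvs(parse_genomic_hgvs(s)) == s` for canonical inputs.
#'
#' @param allele a [genomic_allele()].
#' @return A string like `"chr12:g.40340400G>A"`.
#' @export
render_genomic_hgvs <- function(allele) {
  stopifnot(inherits(allele, "genomic_allele"))
  sprintf("chr%s:g.%d%s>%s", allele$chromosome, allele$position,
          allele$ref, allele$alt)
}

#' Fixture HGVS recoder backed by a lookup table
#'
#' The recoder contract maps an HGVS text to zero or more GRCh38 genomic
#' alleles. The live equivalent would be a REST recoding service; the
#' shipped implementation is a pure, deterministic lookup table, which is
#' all the test surface needs.
#'
#' @param mapping either a named list/vector mapping HGVS text to one or
#'   more `"chrom:pos:ref:alt"` strings, or a path to a two-column TSV
#'   (columns `hgvs`, `allele`) or a JSON object file with the same shape.
#' @return An object of class `variant_recoder`.
#' @examples
#' rec <- fixture_recoder(c("ENST00000298910.12:c.6055G>A" = "12:40340400:G:A"))
#' resolve_hgvs(rec, "ENST00000298910.12:c.6055G>A")
#' @export
fixture_recoder <- function(mapping = character()) {
  if (is.character(mapping) && length(mapping) == 1L && is.null(names(mapping)) &&
      file.exists(mapping)) {
    mapping <- read_recoder_table(mapping)
  }
  mapping <- as.list(mapping)
  if (length(mapping) > 0L && is.null(names(mapping))) {
    abort_ragvar("recoder mapping must be named by HGVS text", "ragvar_parse_error")
  }
  table <- lapply(mapping, function(vals) {
    lapply(as.character(vals), function(v) {
      parts <- strsplit(v, ":", fixed = TRUE)[[1]]
      if (length(parts) != 4L) {
        abort_ragvar(
          sprintf("recoder table value must be 'chrom:pos:ref:alt', got '%s'", v),
          "ragvar_parse_error"
        )
      }
      genomic_allele(parts[1], as.numeric(parts[2]), parts[3], parts[4])
    })
  })
  structure(list(table = table), class = "variant_recoder")
}

read_recoder_table <- function(path) {
  if (grepl("\\.json$", path)) {
    return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (!all(c("hgvs", "allele") %in% names(df))) {
    abort_ragvar("recoder TSV needs columns 'hgvs' and 'allele'", "ragvar_parse_error")
  }
  split(df$allele, df$hgvs)
}

#' Resolve an HGVS text through a recoder
#'
#' @param recoder a `variant_recoder`.
#' @param hgvs HGVS text.
#' @return A list of [genomic_allele()] (possibly empty).
#' @export
resolve_hgvs <- function(recoder, hgvs) {
  stopifnot(inherits(recoder, "variant_recoder"))
  hits <- recoder$table[[hgvs]]
  if (is.null(hits)) list() else hits
}

#' Normalize a variant identifier to the query the variant client expects
#'
#' rs identifiers pass through unchanged (the variant database is keyed by
#' rs number, so no recoding and no network activity is needed). HGVS
#' identifiers are resolved locally when they are genomic-level SNVs;
#' anything else goes through the recoder contract.
#'
#' @param id a [variant_identifier()].
#' @param recoder a `variant_recoder`; only consulted for non-genomic HGVS.
#' @return For rs identifiers, the rs string; for HGVS identifiers, a
#'   [genomic_allele()].
#' @section Errors: a recoder miss raises an unresolvable-identifier error;
#'   a recoder returning more than one allele raises an ambiguity error
#'   listing every candidate.
#' @export
normalize_identifier <- function(id, recoder = NULL) {
  stopifnot(inherits(id, "variant_identifier"))
  if (id$kind == "rs") {
    return(id$raw)
  }
  local <- parse_genomic_hgvs(id$raw)
  if (!is.null(local)) {
    return(local)
  }
  if (is.null(recoder)) {
    abort_ragvar(
      sprintf("'%s' is not a genomic-level SNV and no recoder was supplied", id$raw),
      "ragvar_unresolvable_error"
    )
  }
  hits <- resolve_hgvs(recoder, id$raw)
  if (length(hits) == 0L) {
    abort_ragvar(
      sprintf("recoder returned no GRCh38 allele for '%s'", id$raw),
      "ragvar_unresolvable_error"
    )
  }
  if (length(hits) > 1L) {
    abort_ragvar(
      sprintf("recoder returned %d candidate alleles for '%s': %s",
              length(hits), id$raw,
              paste(vapply(hits, render_genomic_hgvs, character(1)),
                    collapse = ", ")),
      "ragvar_ambiguity_error",
      candidates = hits
    )
  }
  hits[[1]]
}
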