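SYNTH_GENES <- c(
  "LRRK2", "BRCA1", "BRCA2", "TP53", "CFTR", "APOE", "ALDH2", "CYP2D6",
  "CYP2C19", "MTHFR", "HBB", "F5", "HFE", "PAH", "SLCO1B1", "VKORC1",
  "ABCB1", "TPMT", "G6PD", "KCNQ1", "SCN5A", "PCSK9", "LDLR", "FTO",
  "TCF7L2", "HLA-B", "IL6", "TNF", "EGFR", "KRAS"
)

SYNTH_CONDITIONS <- c(
  "Autosomal dominant Parkinson disease 8", "Hereditary breast and ovarian cancer",
  "Cystic fibrosis", "Familial hypercholesterolemia", "Long QT syndrome",
  "Hemochromatosis", "Phenylketonuria", "Alcohol flush reaction",
  "Type 2 diabetes susceptibility", "Drug response"
)

SYNTH_INTERPRETATIONS <- c(
  "pathogenic", "likely pathogenic", "uncertain significance",
  "likely benign", "benign", "risk factor", "drug response"
)

SYNTH_CONSEQUENCES <- list(
  list(accession = "SO_0001583", label = "missense variant"),
  list(accession = "SO_0001587", label = "stop gained"),
  list(accession = "SO_0001819", label = "synonymous variant"),
  list(accession = "SO_0001627", label = "intron variant"),
  list(accession = "SO_0001624", label = "3 prime UTR variant")
)

SYNTH_FREQ_DATASETS <- c("ToMMo", "gnomAD Genomes", "gnomAD Exomes",
                         "GEM-J WGA", "NCBN")

#' Generate a synthetic, internally consistent variant record
#'
#' Produces a record that passes every validator: allele frequencies in
#' \[0, 1\], prediction scores within their tool ranges, and a genomic
#' HGVS string consistent with the generated (chromosome, position, ref,
#' alt). Deterministic for a fixed `(seed, rs_id)`.
#'
#' @param seed integer seed.
#' @param rs_id rs identifier to embed.
#' @return A [variant_record()].
#' @export
generate_variant_record <- function(seed, rs_id) {
  if (!grepl("^rs[0-9]+$", rs_id)) {
    abort_ragvar(sprintf("invalid rs id '%s'", rs_id), "ragvar_parse_error")
  }
  withr::with_seed(seed, {
    chrom <- sample(c(as.character(1:22), "X", "Y"), 1L)
    pos <- sample.int(2.4e8, 1L)
    ref <- sample(c("A", "C", "G", "T"), 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    gene <- sample(SYNTH_GENES, 1L)
    tgv <- sprintf("tgv%08d", sample.int(99999999L, 1L))
    n_cond <- sample(0:2, 1L)
    cs <- lapply(seq_len(n_cond), function(i) {
      list(condition = sample(SYNTH_CONDITIONS, 1L),
           interpretations = sample(SYNTH_INTERPRETATIONS,
                                    sample(1:2, 1L)))
    })
    msc <- SYNTH_CONSEQUENCES[[sample.int(length(SYNTH_CONSEQUENCES), 1L)]]
    transcript <- sprintf("ENST%011d.%d", sample.int(1e6, 1L), sample(1:15, 1L))
    protein <- sprintf("ENSP%011d.%d", sample.int(1e6, 1L), sample(1:10, 1L))
    aa <- sample(c("Gly", "Ala", "Ser", "Arg", "Cys", "Leu"), 2L)
    hgvs <- list(
      protein = sprintf("%s:p.%s%d%s", protein, aa[1],
                        sample.int(2000L, 1L), aa[2]),
      cdna = sprintf("%s:c.%d%s>%s", transcript, sample.int(6000L, 1L),
                     ref, alt),
      genomic = sprintf("chr%s:g.%d%s>%s", chrom, pos, ref, alt)
    )
    sift <- round(stats::runif(1), 3)
    polyphen <- round(stats::runif(1), 3)
    am <- round(stats::runif(1), 3)
    predictions <- list(
      SIFT = list(score = sift,
                  label = if (sift < 0.05) "deleterious" else "tolerated"),
      PolyPhen = list(score = polyphen,
                      label = if (polyphen > 0.9) "probably damaging"
                              else if (polyphen > 0.45) "possibly damaging"
                              else "benign"),
      AlphaMissense = list(score = am,
                           label = if (am > 0.56) "likely pathogenic"
                                   else if (am > 0.34) "ambiguous"
                                   else "likely benign")
    )
    freqs <- stats::setNames(
      as.list(signif(10^stats::runif(length(SYNTH_FREQ_DATASETS), -6, -0.5), 2)),
      SYNTH_FREQ_DATASETS
    )
    links <- list(
      dbSNP = sprintf("https://identifiers.org/dbsnp/%s", rs_id),
      TogoVar = sprintf("https://grch38.togovar.org/variant/%s", tgv),
      gnomAD = sprintf("https://gnomad.broadinstitute.org/variant/%s-%d-%s-%s",
                       chrom, pos, ref, alt)
    )
    variant_record(
      togovar_id = tgv, rs_id = rs_id, chromosome = chrom, position = pos,
      ref = ref, alt = alt, gene_symbol = gene,
      clinical_significance = cs, most_severe_consequence = msc,
      hgvs = hgvs, predictions = predictions,
      allele_frequencies = freqs, external_links = links
    )
  })
}

#' Write a directory of variant fixtures for the mock client
#'
#' One `<rs>.json` per rs id. The canonical worked-example record
#' (rs34637584, transcribed field-for-field from the public annotation of
#' the Parkinson-disease LRRK2 p.Gly2019Ser variant) is copied from the
#' package resources; every other id gets a synthetic record generated
#' deterministically from `seed`.
#'
#' @param dir output directory (created if needed).
#' @param rs_ids rs identifiers; defaults to the packaged synthetic list.
#' @param seed integer seed for the synthetic records.
#' @return `dir`, invisibly.
#' @export
write_variant_fixtures <- function(dir, rs_ids = default_rs_list(), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  canonical <- ragvar_resource("variants", "rs34637584.json")
  for (i in seq_along(rs_ids)) {
    rs <- rs_ids[i]
    path <- file.path(dir, paste0(rs, ".json"))
    if (identical(rs, "rs34637584")) {
      file.copy(canonical, path, overwrite = TRUE)
    } else {
      rec <- generate_variant_record(seed + i, rs)
      writeLines(render_record(rec), path, useBytes = TRUE)
    }
  }
  invisible(dir)
}

#' Configuration for the score-table simulator
#'
#' @param n_questions number of questions to simulate.
#' @param systems named list: system name -> per-criterion mean quality on
#'   the 0-10 scale (length 5, or a scalar recycled across criteria).
#' @param rater_noise_sd standard deviation of the independent Gaussian
#'   noise each rater adds on top of the latent quality.
#' @param between_sd standard deviation of the per-question latent-quality
#'   draw around the system's criterion mean.
#' @param seed integer seed.
#' @return An object of class `score_sim_config`.
#' @export
score_sim_config <- function(n_questions, systems, rater_noise_sd = 1,
                             between_sd = 1.5, seed = 1L) {
  if (!is_count(n_questions)) {
    abort_ragvar("n_questions must be a positive integer",
                 "ragvar_validation_error")
  }
  if (!is.list(systems) || is.null(names(systems)) ||
      any(!nzchar(names(systems)))) {
    abort_ragvar("systems must be a named list of mean-quality vectors",
                 "ragvar_validation_error")
  }
  systems <- lapply(systems, function(mu) {
    mu <- rep_len(as.numeric(mu), 5L)
    if (anyNA(mu) || any(mu < 0 | mu > 10)) {
      abort_ragvar("system mean qualities must lie within [0, 10]",
                   "ragvar_validation_error")
    }
    stats::setNames(mu, RAGVAR_CRITERIA)
  })
  if (!is.numeric(rater_noise_sd) || rater_noise_sd < 0 ||
      !is.finite(rater_noise_sd) ||
      !is.numeric(between_sd) || between_sd < 0 || !is.finite(between_sd)) {
    abort_ragvar("noise standard deviations must be finite and >= 0",
                 "ragvar_validation_error")
  }
  structure(
    list(n_questions = as.integer(n_questions), systems = systems,
         rater_noise_sd = rater_noise_sd, between_sd = between_sd,
         seed = as.integer(seed)),
    class = "score_sim_config"
  )
}

#' Simulate a two-rater score table with known ground truth
#'
#' For each (question, system, criterion) a latent quality is drawn as the
#' system's criterion mean plus Gaussian between-question variation; each
#' of the two raters then observes the latent quality plus independent
#' Gaussian noise, rounded to an integer and clipped to the 0-10 score
#' range. With `rater_noise_sd = 0` the two raters are identical. The
#' output is the canonical long score table, ready for
#' [mean_rater_scores()], [totals_matrix()], [winner_tally()] and the
#' statistical battery.
#'
#' @param config a [score_sim_config()].
#' @return Long-format data.frame: `template_id`, `rs_id`, `system`,
#'   `rater` (`"r1"`, `"r2"`), the five criterion columns, and `total`.
#' @export
simulate_scores <- function(config) {
  stopifnot(inherits(config, "score_sim_config"))
  nq <- config$n_questions
  withr::with_seed(config$seed, {
    per_system <- lapply(names(config$systems), function(s) {
      mu <- config$systems[[s]]
      latent <- matrix(rep(mu, each = nq), nrow = nq) +
        matrix(stats::rnorm(nq * 5L, 0, config$between_sd), nrow = nq)
      per_rater <- lapply(c("r1", "r2"), function(r) {
        obs <- latent +
          matrix(stats::rnorm(nq * 5L, 0, config$rater_noise_sd), nrow = nq)
        obs <- round(obs)
        obs[obs < 0] <- 0
        obs[obs > 10] <- 10
        colnames(obs) <- RAGVAR_CRITERIA
        cbind(
          data.frame(template_id = sprintf("q%d", seq_len(nq)),
                     rs_id = sprintf("rs%d", seq_len(nq)),
                     system = s, rater = r, stringsAsFactors = FALSE),
          as.data.frame(obs)
        )
      })
      do.call(rbind, per_rater)
    })
    out <- do.call(rbind, per_system)
    out$total <- rowSums(out[RAGVAR_CRITERIA])
    rownames(out) <- NULL
    out
  })
}

#' Closed-form expected ICC(2,2) for a simulation configuration
#'
#' Under the simulator's generative model the reliability of the mean of
#' the two raters' *total* scores is
#' \deqn{ICC(2,2) = s^2 / (s^2 + (\sigma^2 + 1/12) / 2)}
#' per criterion, where `s` is the between-question sd, `sigma` the rater
#' noise sd, and 1/12 the variance added by rounding scores to integers
#' (uniform rounding error); criteria are independent so the ratio carries
#' over to totals. Clipping at 0 and 10 is ignored, which is accurate for
#' mid-range mean qualities.
#'
#' @param config a [score_sim_config()].
#' @return Expected ICC(2,2), a number in \[0, 1\].
#' @export
expected_icc_2_2 <- function(config) {
  stopifnot(inherits(config, "score_sim_config"))
  s2 <- config$between_sd^2
  e2 <- config$rater_noise_sd^2 + 1 / 12
  s2 / (s2 + e2 / 2)
}

#' Deterministic stub answer text
#'
#' Walks the six required answer items, filling each from the bundle's
#' retrieved JSON when retrieval succeeded and explicitly stating that
#' there are no data otherwise. Identical bundles yield byte-identical
#' text.
#'
#' @param bundle a `prompt_bundle`.
#' @return A single answer string.
#' @export
stub_llm_answer <- function(bundle) {
  stopifnot(inherits(bundle, "prompt_bundle"))
  no_data <- "There are no data available for this item."
  rec <- NULL
  if (isTRUE(bundle$retrieval_used)) {
    rec <- tryCatch(parse_record(bundle$retrieved_json),
                    ragvar_error = function(e) NULL)
  }
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  item <- function(n, title, body) sprintf("%d. %s: %s", n, title, body)

  if (is.null(rec)) {
    titles <- c("Variant identification", "Disease associations",
                "Literature evidence", "Allele frequency comparison",
                "GWAS findings", "TogoVar link")
    lines <- vapply(seq_along(titles), function(i) {
      item(i, titles[i],
           "There are no data available: no database record was retrieved for this question.")
    }, character(1))
    return(paste(
      c(sprintf("Answer to: %s", bundle$question_text), "", lines),
      collapse = "\n"
    ))
  }

  ident <- sprintf("%s (%s), chr%s:%d %s>%s%s%s",
                   rec$rs_id %||% rec$togovar_id, rec$togovar_id,
                   rec$chromosome, rec$position, rec$ref, rec$alt,
                   if (!is.null(rec$gene_symbol)) {
                     sprintf(", gene %s", rec$gene_symbol)
                   } else "",
                   if (!is.null(rec$hgvs$cdna)) {
                     sprintf(", %s", rec$hgvs$cdna)
                   } else "")
  disease <- if (length(rec$clinical_significance) > 0L) {
    paste(vapply(rec$clinical_significance, function(e) {
      sprintf("%s (%s)", e$condition,
              paste(e$interpretations, collapse = ", "))
    }, character(1)), collapse = "; ")
  } else no_data
  preds <- if (length(rec$predictions) > 0L) {
    paste(vapply(names(rec$predictions), function(tool) {
      p <- rec$predictions[[tool]]
      sprintf("%s %s (%s)", tool, fmt_num(p$score), p$label)
    }, character(1)), collapse = ", ")
  } else NULL
  if (!is.null(preds)) {
    disease <- if (identical(disease, no_data)) {
      sprintf("No curated condition; predictions: %s", preds)
    } else {
      sprintf("%s; predictions: %s", disease, preds)
    }
  }
  freqs <- if (length(rec$allele_frequencies) > 0L) {
    paste(vapply(names(rec$allele_frequencies), function(ds) {
      sprintf("%s %s", ds, fmt_num(rec$allele_frequencies[[ds]]))
    }, character(1)), collapse = ", ")
  } else no_data
  link <- rec$external_links$TogoVar %||%
    sprintf("https://grch38.togovar.org/variant/%s", rec$togovar_id)

  lines <- c(
    item(1, "Variant identification", ident),
    item(2, "Disease associations", disease),
    item(3, "Literature evidence", no_data),
    item(4, "Allele frequency comparison", freqs),
    item(5, "GWAS findings", no_data),
    item(6, "TogoVar link", link)
  )
  paste(c(sprintf("Answer to: %s", bundle$question_text), "", lines),
        collapse = "\n")
}
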