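#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the supplied values (questions are the resampling unit in the
#' comparison reports) with replacement and returns percentile quantiles of
#' the resampled means. Deterministic for a fixed seed; the RNG state of
#' the caller is left untouched.
#'
#' @param values non-empty numeric vector.
#' @param level confidence level in (0, 1); default 0.95.
#' @param reps number of bootstrap resamples; default 10000.
#' @param seed optional integer seed.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' bootstrap_ci(c(7, 7, 7, 7), seed = 1) # degenerate: c(7, 7)
#' @export
bootstrap_ci <- function(values, level = 0.95, reps = 10000L, seed = NULL) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values)) {
    abort_ragvar("values must be a non-empty numeric vector without NAs",
                 "ragvar_validation_error")
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort_ragvar("level must lie strictly between 0 and 1",
                 "ragvar_validation_error")
  }
  if (!is_count(reps)) {
    abort_ragvar("reps must be a positive integer", "ragvar_validation_error")
  }
  run <- function() {
    n <- length(values)
    means <- vapply(seq_len(reps), function(i) {
      mean(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    stats::quantile(means, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE)
  }
  q <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  c(low = q[1], high = q[2])
}

as_paired_matrix <- function(matrix) {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || anyNA(m)) {
    abort_ragvar("paired score matrix must be numeric with no missing cells",
                 "ragvar_validation_error")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort_ragvar("paired score matrix needs >= 2 questions and >= 2 systems",
                 "ragvar_validation_error")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("system", seq_len(ncol(m)))
  m
}

#' Friedman test with Kendall's W effect size
#'
#' Nonparametric comparison of k systems paired within questions. Scores
#' are converted to within-question mid-ranks; the tie-corrected statistic
#' is
#' \deqn{\chi^2 = (k-1) \sum_j (R_j - n(k+1)/2)^2 / (A - C)}
#' with \eqn{R_j} the rank sums, \eqn{A} the sum of squared ranks and
#' \eqn{C = nk(k+1)^2/4}; the p-value uses the chi-square approximation
#' with k-1 degrees of freedom, and Kendall's coefficient of concordance is
#' reported through the identity \eqn{W = \chi^2 / (n(k-1))}, so
#' \eqn{W \in [0, 1]} with 1 meaning every question ranks the systems
#' identically.
#'
#' @param matrix question x system matrix of scores (no missing cells).
#' @return A list of class `friedman_w`: `chi2`, `df`, `p`, `W`, `n`, `k`.
#' @section Errors: a matrix whose every row is constant has no rank
#'   information; the statistic is undefined and an error is raised.
#' @export
friedman_w <- function(matrix) {
  m <- as_paired_matrix(matrix)
  n <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1L, rank))  # mid-ranks for ties
  A <- sum(ranks^2)
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  if (denom <= 1e-12) {
    abort_ragvar(
      "Friedman statistic undefined: every question assigns all systems the same score",
      "ragvar_undefined_statistic_error"
    )
  }
  Rj <- colSums(ranks)
  chi2 <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
  W <- chi2 / (n * (k - 1))
  structure(
    list(chi2 = chi2, df = k - 1L,
         p = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE),
         W = W, n = n, k = k),
    class = "friedman_w"
  )
}

#' @export
print.friedman_w <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4f, df = %d, p = %.3g; Kendall's W = %.3f (n = %d, k = %d)\n",
              x$chi2, x$df, x$p, x$W, x$n, x$k))
  invisible(x)
}

#' Holm step-down adjustment
#'
#' @param p numeric vector of raw p-values (one family).
#' @return Adjusted p-values in the input order: sorted raw p-values are
#'   multiplied by m, m-1, ..., 1, cumulative-maxed, and capped at 1, so
#'   adjusted values are always >= raw and monotone in the raw ordering.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03, 0.06, 0.06
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p) || any(p < 0 | p > 1)) {
    abort_ragvar("p must be a vector of probabilities", "ragvar_validation_error")
  }
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1L) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise paired Wilcoxon signed-rank tests with Holm adjustment
#'
#' All k(k-1)/2 system pairs are tested on their within-question score
#' differences. Zero differences are handled by Wilcoxon's original rule —
#' dropped before ranking — or by Pratt's rule (rank with zeros, then drop
#' their ranks) when `zero_method = "pratt"`. The exact signed-rank
#' distribution is used when at most 25 nonzero pairs remain (falling back
#' to the normal approximation when ties make the exact distribution
#' unavailable); larger samples use the normal approximation with
#' continuity correction. The Holm family is the set of pairs in this call.
#'
#' @param matrix question x system matrix of scores.
#' @param zero_method `"wilcox"` (default) or `"pratt"`.
#' @param exact_max largest number of nonzero pairs for which the exact
#'   distribution is attempted.
#' @return A data.frame with one row per pair: `system_a`, `system_b`,
#'   `n_nonzero`, `median_diff` (median of a - b over all questions),
#'   `p_raw`, `p_holm`, `degenerate` (all differences zero; p reported
#'   as 1).
#' @export
wilcoxon_holm <- function(matrix, zero_method = c("wilcox", "pratt"),
                          exact_max = 25L) {
  m <- as_paired_matrix(matrix)
  zero_method <- match.arg(zero_method)
  systems <- colnames(m)
  pairs <- utils::combn(seq_along(systems), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    d <- m[, a] - m[, b]
    nz <- d != 0
    if (!any(nz)) {
      return(data.frame(system_a = systems[a], system_b = systems[b],
                        n_nonzero = 0L, median_diff = 0,
                        p_raw = 1, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    p <- if (zero_method == "wilcox") {
      dd <- d[nz]
      use_exact <- sum(nz) <= exact_max
      suppressWarnings(
        stats::wilcox.test(dd, exact = use_exact, correct = TRUE)$p.value
      )
    } else {
      pratt_p(d)
    }
    data.frame(system_a = systems[a], system_b = systems[b],
               n_nonzero = sum(nz), median_diff = stats::median(d),
               p_raw = p, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p_raw)
  out[c("system_a", "system_b", "n_nonzero", "median_diff",
        "p_raw", "p_holm", "degenerate")]
}

# Pratt's zero-handling: rank |d| including zeros, discard zero ranks,
# normal approximation with tie and continuity corrections.
pratt_p <- function(d) {
  r <- rank(abs(d))
  n0 <- sum(d == 0)
  N <- length(d)
  Wplus <- sum(r[d > 0])
  mu <- (N * (N + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r[d != 0])
  sigma2 <- (N * (N + 1) * (2 * N + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  z <- (Wplus - mu - sign(Wplus - mu) * 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' ICC(2,2): two-way random effects, absolute agreement, average measures
#'
#' Reliability of the mean of two raters' scores, from the two-way ANOVA
#' mean squares (questions as rows, raters as columns):
#' \deqn{ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)}
#' with \eqn{MS_R} the between-question, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square. The estimate can be negative when
#' raters agree less than chance.
#'
#' @param ratings n x 2 numeric matrix (or data.frame) of the two raters'
#'   total scores for the same n >= 3 items; no missing cells.
#' @return A single number <= 1.
#' @section Errors: with no between-question variance the coefficient is
#'   undefined (0/0) and an error is raised.
#' @export
icc_2_2 <- function(ratings) {
  m <- as.matrix(ratings)
  if (!is.numeric(m) || anyNA(m)) {
    abort_ragvar("ratings must be numeric with no missing cells",
                 "ragvar_validation_error")
  }
  if (ncol(m) != 2L || nrow(m) < 3L) {
    abort_ragvar("ICC(2,2) needs an n x 2 matrix with n >= 3",
                 "ragvar_validation_error")
  }
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  SSR <- k * sum((row_means - grand)^2)
  SSC <- n * sum((col_means - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR < 1e-12 && MSE < 1e-12 && MSC < 1e-12) {
    abort_ragvar("ICC undefined: no variance anywhere in the ratings",
                 "ragvar_undefined_statistic_error")
  }
  denom <- MSR + (MSC - MSE) / n
  if (abs(denom) < 1e-12) {
    abort_ragvar("ICC undefined: zero between-question variance",
                 "ragvar_undefined_statistic_error")
  }
  (MSR - MSE) / denom
}

#' Quadratic-weighted Cohen's kappa
#'
#' Agreement between two raters on an ordinal scale, with disagreement
#' penalized by squared category distance: weights
#' \eqn{w_{ij} = 1 - (i-j)^2/(K-1)^2} over the K ordered categories,
#' expected agreement from the observed marginals. Total scores are
#' treated as the 51 ordinal categories 0-50; half-integer rater means are
#' doubled (scale 0-100) before binning so they remain exact.
#'
#' @param r1,r2 equal-length numeric vectors of ordinal scores.
#' @param categories the ordered category values (default `0:50`); doubled
#'   automatically alongside the data when half-integers are present.
#' @return Kappa, a single number <= 1.
#' @section Errors: when both raters use one single category the expected
#'   agreement is 1 and kappa is undefined.
#' @export
weighted_kappa <- function(r1, r2, categories = 0:50) {
  if (length(r1) != length(r2) || length(r1) == 0L) {
    abort_ragvar("r1 and r2 must be non-empty vectors of equal length",
                 "ragvar_validation_error")
  }
  if (anyNA(r1) || anyNA(r2)) {
    abort_ragvar("ratings must not contain NAs", "ragvar_validation_error")
  }
  if (any(c(r1, r2) %% 1 != 0)) {
    r1 <- 2 * r1; r2 <- 2 * r2
    categories <- seq(2 * min(categories), 2 * max(categories))
  }
  idx1 <- match(r1, categories)
  idx2 <- match(r2, categories)
  if (anyNA(idx1) || anyNA(idx2)) {
    abort_ragvar("ratings fall outside the category range",
                 "ragvar_validation_error")
  }
  if (length(unique(c(idx1, idx2))) < 2L) {
    abort_ragvar("kappa undefined: both raters used a single category",
                 "ragvar_undefined_statistic_error")
  }
  K <- length(categories)
  w <- 1 - (outer(seq_len(K), seq_len(K), "-"))^2 / (K - 1)^2
  n <- length(r1)
  po <- mean(w[cbind(idx1, idx2)])
  p1 <- tabulate(idx1, nbins = K) / n
  p2 <- tabulate(idx2, nbins = K) / n
  pe <- sum(outer(p1, p2) * w)
  if (abs(1 - pe) < 1e-12) {
    abort_ragvar("kappa undefined: expected weighted agreement is 1",
                 "ragvar_undefined_statistic_error")
  }
  (po - pe) / (1 - pe)
}

#' Summaries of absolute between-rater differences
#'
#' @param r1,r2 equal-length numeric vectors.
#' @return Named vector: `median`, `mean`, `max` of `|r1 - r2|`.
#' @examples
#' abs_diff_summary(c(10, 20), c(12, 16)) # 3, 3, 4
#' @export
abs_diff_summary <- function(r1, r2) {
  if (length(r1) != length(r2) || length(r1) == 0L) {
    abort_ragvar("r1 and r2 must be non-empty vectors of equal length",
                 "ragvar_validation_error")
  }
  d <- abs(r1 - r2)
  c(median = stats::median(d), mean = mean(d), max = max(d))
}

#' Inter-rater agreement report
#'
#' Bundles the three agreement statistics computed on two raters' total
#' scores: ICC(2,2), quadratic-weighted kappa, and the absolute-difference
#' summary.
#'
#' @param r1,r2 the two raters' total scores (same items, same order).
#' @param categories ordinal categories for kappa (default `0:50`).
#' @return List of class `agreement_report` with `icc_2_2`,
#'   `quadratic_weighted_kappa`, `abs_diff`, `n`.
#' @export
agreement_report <- function(r1, r2, categories = 0:50) {
  structure(
    list(
      icc_2_2 = icc_2_2(cbind(r1, r2)),
      quadratic_weighted_kappa = weighted_kappa(r1, r2, categories),
      abs_diff = abs_diff_summary(r1, r2),
      n = length(r1)
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Inter-rater agreement (n = %d):\n", x$n))
  cat(sprintf("  ICC(2,2)                 %.3f\n", x$icc_2_2))
  cat(sprintf("  quadratic-weighted kappa %.3f\n", x$quadratic_weighted_kappa))
  cat(sprintf("  |rater difference|       median %.3g, mean %.3g, max %.3g\n",
              x$abs_diff[["median"]], x$abs_diff[["mean"]],
              x$abs_diff[["max"]]))
  invisible(x)
}

#' Full multi-system comparison report
#'
#' For each block — one per criterion (plus the total score), or one per
#' question category — computes per-system means with percentile bootstrap
#' CIs, the Friedman test with Kendall's W, and Holm-adjusted pairwise
#' Wilcoxon signed-rank tests. The bootstrap resamples questions; the Holm
#' family is the set of system pairs within the block.
#'
#' @param scores long score table with one row per (question, system)
#'   (pass per-rater tables through [mean_rater_scores()] first).
#' @param by `"criterion"` (default) or `"category"`; category blocks
#'   require a `category` column and compare total scores.
#' @param level,reps,seed bootstrap parameters, see [bootstrap_ci()].
#' @return List of class `comparison_report`, one element per block, each
#'   holding `means` (data.frame system/mean/ci_low/ci_high), `friedman`
#'   and `wilcoxon`.
#' @export
compare_systems <- function(scores, by = c("criterion", "category"),
                            level = 0.95, reps = 10000L, seed = 1L) {
  by <- match.arg(by)
  blocks <- if (by == "criterion") {
    values <- c("total", RAGVAR_CRITERIA)
    stats::setNames(lapply(values, function(v) list(rows = scores, value = v)),
                    values)
  } else {
    if (!"category" %in% names(scores)) {
      abort_ragvar("category blocks need a 'category' column",
                   "ragvar_validation_error")
    }
    cats <- unique(scores$category)
    stats::setNames(lapply(cats, function(cc) {
      list(rows = scores[scores$category == cc, , drop = FALSE],
           value = "total")
    }), cats)
  }
  out <- lapply(seq_along(blocks), function(i) {
    blk <- blocks[[i]]
    m <- totals_matrix(blk$rows, value = blk$value)
    means <- do.call(rbind, lapply(colnames(m), function(s) {
      ci <- bootstrap_ci(m[, s], level = level, reps = reps,
                         seed = seed + i)
      data.frame(system = s, mean = mean(m[, s]),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 stringsAsFactors = FALSE)
    }))
    fr <- tryCatch(friedman_w(m),
                   ragvar_undefined_statistic_error = function(e) NULL)
    list(block = names(blocks)[i], n = nrow(m), means = means,
         friedman = fr, wilcoxon = wilcoxon_holm(m))
  })
  names(out) <- names(blocks)
  structure(out, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  for (blk in x) {
    cat(sprintf("== %s (n = %d) ==\n", blk$block, blk$n))
    for (i in seq_len(nrow(blk$means))) {
      r <- blk$means[i, ]
      cat(sprintf("  %-16s %6.2f (%.2f-%.2f)\n", r$system, r$mean,
                  r$ci_low, r$ci_high))
    }
    if (!is.null(blk$friedman)) {
      cat(sprintf("  Friedman p = %.3g, Kendall's W = %.3f\n",
                  blk$friedman$p, blk$friedman$W))
    }
    for (i in seq_len(nrow(blk$wilcoxon))) {
      r <- blk$wilcoxon[i, ]
      cat(sprintf("  %s vs %s: median diff %+.2f, p = %.3g (Holm %.3g)%s\n",
                  r$system_a, r$system_b, r$median_diff, r$p_raw, r$p_holm,
                  if (r$degenerate) " [degenerate]" else ""))
    }
  }
  invisible(x)
}
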