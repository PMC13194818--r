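test_that("bootstrap CI: degeneracy, coverage of the mean, determinism", {
  expect_equal(unname(bootstrap_ci(c(7, 7, 7, 7), seed = 1)), c(7, 7))

  ci <- bootstrap_ci(c(0, 10), reps = 10000, seed = 2)
  expect_lte(ci[["low"]], 5)
  expect_gte(ci[["high"]], 5)
  # with n = 2 the resampled mean takes values {0, 5, 10} with binomial
  # weights 1/4, 1/2, 1/4, so the 95% percentile interval spans 0..10
  expect_equal(unname(ci), c(0, 10))

  vals <- withr::with_seed(44, rnorm(20))
  expect_identical(bootstrap_ci(vals, seed = 3), bootstrap_ci(vals, seed = 3))

  expect_error(bootstrap_ci(numeric(0)), class = "ragvar_validation_error")
  expect_error(bootstrap_ci(1:5, level = 1), class = "ragvar_validation_error")
})

test_that("bootstrap CI width shrinks as n grows", {
  width <- function(n) {
    vals <- withr::with_seed(n, rnorm(n, mean = 30, sd = 8))
    ci <- bootstrap_ci(vals, reps = 2000, seed = 7)
    ci[["high"]] - ci[["low"]]
  }
  expect_lt(width(400), width(25))
})

test_that("Friedman chi-squared matches the independent rank oracle", {
  m0 <- matrix(c(9, 5, 3,
                 8, 6, 2,
                 10, 4, 3,
                 7, 7, 1), nrow = 4, byrow = TRUE,
               dimnames = list(NULL, c("A", "B", "C")))
  f <- friedman_w(m0)
  expect_equal(f$chi2, oracle_friedman_chi2(m0), tolerance = 1e-10)

  withr::with_seed(23, {
    for (i in 1:15) {
      n <- sample(4:12, 1); k <- sample(2:5, 1)
      m <- matrix(sample(0:10, n * k, replace = TRUE), nrow = n)
      if (all(apply(m, 1, function(r) length(unique(r))) == 1L)) next
      f <- friedman_w(m)
      expect_equal(f$chi2, oracle_friedman_chi2(m), tolerance = 1e-10)
      # mid-ranks agree with the counting definition
      expect_equal(t(apply(m, 1, rank))[1, ], oracle_midranks(m[1, ]))
      # identity chi2 = n (k-1) W
      expect_equal(f$chi2, f$n * (f$k - 1) * f$W, tolerance = 1e-12)
      expect_gte(f$W, 0); expect_lte(f$W, 1)
    }
  })
})

test_that("Friedman W hits 1 under perfect concordance and ~0 under noise", {
  m <- matrix(rep(c(3, 2, 1), 10), ncol = 3, byrow = TRUE)
  f <- friedman_w(m)
  expect_equal(f$W, 1)

  shuffled <- withr::with_seed(8, {
    t(replicate(500, sample(1:3)))
  })
  expect_lt(friedman_w(shuffled)$W, 0.05)

  constant <- matrix(5, nrow = 4, ncol = 3)
  expect_error(friedman_w(constant), class = "ragvar_undefined_statistic_error")
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(0.04), 0.04)  # family of one: identity
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  withr::with_seed(12, {
    for (i in 1:20) {
      p <- runif(sample(1:8, 1))
      adj <- holm_adjust(p)
      expect_equal(adj, stats::p.adjust(p, method = "holm"))
      expect_true(all(adj >= p))
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
})

test_that("pairwise Wilcoxon matches exact enumeration and flags degeneracy", {
  withr::with_seed(14, {
    x <- rnorm(9, 1); y <- rnorm(9)
  })
  m <- cbind(A = x, B = y)
  res <- wilcoxon_holm(m)
  expect_equal(nrow(res), 1L)
  expect_equal(res$p_holm, res$p_raw)   # family of one
  expect_equal(res$p_raw, oracle_signed_rank_p(x - y), tolerance = 1e-12)
  expect_equal(res$median_diff, median(x - y))

  same <- cbind(A = 1:5, B = 1:5)
  res2 <- wilcoxon_holm(same)
  expect_true(res2$degenerate)
  expect_equal(res2$p_raw, 1)

  # three systems: 3 pairs, Holm family over the trio
  m3 <- cbind(A = x, B = y, C = y - 2)
  res3 <- wilcoxon_holm(m3)
  expect_equal(nrow(res3), 3L)
  expect_equal(res3$p_holm, holm_adjust(res3$p_raw))

  # Pratt variant runs and keeps zeros in the ranking
  d <- cbind(A = c(5, 5, 7, 9, 3, 6, 8), B = c(5, 5, 4, 5, 6, 2, 3))
  pr <- wilcoxon_holm(d, zero_method = "pratt")
  expect_equal(pr$n_nonzero, 5L)
  expect_true(pr$p_raw > 0 && pr$p_raw <= 1)
})

test_that("large-sample Wilcoxon agrees with the normal-approximation route", {
  withr::with_seed(15, {
    x <- rnorm(60, 0.4); y <- rnorm(60)
  })
  res <- wilcoxon_holm(cbind(A = x, B = y))
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  )$p.value
  expect_equal(res$p_raw, ref, tolerance = 1e-12)
})

test_that("ICC(2,2) equals the two-way ANOVA oracle", {
  withr::with_seed(16, {
    for (i in 1:10) {
      n <- sample(4:30, 1)
      quality <- rnorm(n, 25, 6)
      m <- cbind(quality + rnorm(n, 0, 3), quality + rnorm(n, 1, 3))
      expect_equal(icc_2_2(m), oracle_icc_2_2(m), tolerance = 1e-10)
      expect_lte(icc_2_2(m), 1)
    }
  })

  # perfect agreement
  r <- c(10, 20, 30, 40)
  expect_equal(icc_2_2(cbind(r, r)), 1)

  # no information
  expect_error(icc_2_2(matrix(5, 4, 2)),
               class = "ragvar_undefined_statistic_error")
  expect_error(icc_2_2(cbind(1:5, 2:6, 3:7)), class = "ragvar_validation_error")
})

test_that("ICC(2,2) can be negative when rater offset dominates", {
  # no between-question spread, constant rater offset: agreement below chance
  m <- cbind(c(5, 6, 5, 6), c(9, 8, 9, 8))
  expect_lt(icc_2_2(m), 0)
  expect_equal(icc_2_2(m), oracle_icc_2_2(m), tolerance = 1e-10)
})

test_that("quadratic-weighted kappa matches the hand-computed toy table", {
  # r1 = (0,1,2,1), r2 = (0,2,2,0) on categories 0..2:
  # po = (1 + 0.75 + 1 + 0.75)/4 = 0.875, pe = 0.625, kappa = 0.25/0.375
  expect_equal(weighted_kappa(c(0, 1, 2, 1), c(0, 2, 2, 0), categories = 0:2),
               2 / 3, tolerance = 1e-12)

  r <- c(0, 10, 25, 50, 37)
  expect_equal(weighted_kappa(r, r), 1)
  # relabeling raters leaves kappa unchanged
  r2 <- c(5, 12, 20, 48, 30)
  expect_equal(weighted_kappa(r, r2), weighted_kappa(r2, r))

  # half-integer means are doubled, not rounded
  expect_equal(weighted_kappa(c(1.5, 2, 3), c(1.5, 2, 3), categories = 0:50), 1)

  expect_error(weighted_kappa(c(5, 5, 5), c(5, 5, 5)),
               class = "ragvar_undefined_statistic_error")
  expect_error(weighted_kappa(c(1, 2), c(1, 60)),
               class = "ragvar_validation_error")
})

test_that("independent uniform raters give kappa near zero", {
  withr::with_seed(18, {
    r1 <- sample(0:50, 2000, replace = TRUE)
    r2 <- sample(0:50, 2000, replace = TRUE)
  })
  expect_lt(abs(weighted_kappa(r1, r2)), 0.05)
})

test_that("absolute rater-difference summary", {
  expect_equal(unname(abs_diff_summary(c(3, 4), c(3, 4))), c(0, 0, 0))
  expect_equal(unname(abs_diff_summary(c(10, 20), c(12, 16))), c(3, 3, 4))
  r1 <- c(40, 22, 35, 18); r2 <- c(33, 30, 35, 46)
  expect_equal(abs_diff_summary(r1, r2), abs_diff_summary(r2, r1))
})

test_that("comparison and agreement reports assemble the battery", {
  cfg <- score_sim_config(40, list(A = 8, B = 5, C = 4),
                          rater_noise_sd = 1, between_sd = 1.5, seed = 19)
  sc <- simulate_scores(cfg)
  msc <- mean_rater_scores(sc)
  rep <- compare_systems(msc, reps = 500, seed = 3)
  expect_named(rep, c("total", RAGVAR_CRITERIA))
  blk <- rep[["total"]]
  expect_equal(blk$n, 40L)
  expect_true(all(blk$means$ci_low <= blk$means$mean + 1e-9))
  expect_true(all(blk$means$mean <= blk$means$ci_high + 1e-9))
  expect_true(all(blk$wilcoxon$p_holm >= blk$wilcoxon$p_raw - 1e-15))
  expect_equal(blk$friedman$chi2,
               blk$friedman$n * (blk$friedman$k - 1) * blk$friedman$W)
  best <- blk$means$system[which.max(blk$means$mean)]
  expect_equal(best, "A")

  r1 <- sc$total[sc$rater == "r1"]
  r2 <- sc$total[sc$rater == "r2"]
  ar <- agreement_report(r1, r2)
  expect_lte(ar$icc_2_2, 1)
  expect_lte(ar$quadratic_weighted_kappa, 1)
  expect_equal(unname(ar$abs_diff), unname(abs_diff_summary(r1, r2)))
})
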