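test_that("total score is the sum of the five criteria, bounded by [0, 50]", {
  expect_equal(total_score(criterion_scores(10, 10, 10, 10, 10)), 50)
  expect_equal(total_score(criterion_scores(0, 0, 0, 0, 0)), 0)
  expect_equal(total_score(criterion_scores(8, 7, 9, 9, 8)), 41)
  expect_error(criterion_scores(11, 0, 0, 0, 0), class = "ragvar_validation_error")
  expect_error(criterion_scores(-1, 0, 0, 0, 0), class = "ragvar_validation_error")
  expect_error(criterion_scores(1.5, 0, 0, 0, 0, integer_only = TRUE),
               class = "ragvar_validation_error")
})

test_that("rater aggregation means criteria exactly and commutes with totals", {
  e1 <- answer_evaluation("q1", "rs1", "ragvar", "r1",
                          criterion_scores(8, 8, 8, 8, 8))
  e2 <- answer_evaluation("q1", "rs1", "ragvar", "r2",
                          criterion_scores(9, 9, 8, 9, 9))
  m <- aggregate_raters(e1, e2)
  expect_equal(m$rater, "mean")
  expect_equal(unclass(m$scores)[["accuracy"]], 8.5)
  expect_equal(m$total, (e1$total + e2$total) / 2)
  expect_equal(m$total, 42)

  same <- aggregate_raters(e1, e1)
  expect_equal(unclass(same$scores), unclass(e1$scores))

  e3 <- answer_evaluation("q2", "rs1", "ragvar", "r2",
                          criterion_scores(9, 9, 8, 9, 9))
  expect_error(aggregate_raters(e1, e3), class = "ragvar_validation_error")

  # property: mean-of-criteria sums equal mean-of-totals
  withr::with_seed(31, {
    for (i in 1:25) {
      s1 <- do.call(criterion_scores, as.list(sample(0:10, 5, replace = TRUE)))
      s2 <- do.call(criterion_scores, as.list(sample(0:10, 5, replace = TRUE)))
      a <- answer_evaluation("q", "rs1", "s", "r1", s1)
      b <- answer_evaluation("q", "rs1", "s", "r2", s2)
      expect_equal(aggregate_raters(a, b)$total,
                   (total_score(s1) + total_score(s2)) / 2)
    }
  })
})

test_that("winner tally credits strict unique maxima only", {
  t1 <- winner_tally(rbind(q1 = c(A = 45, B = 30, C = 28)))
  expect_equal(t1$counts[["A"]], 1L)
  expect_equal(t1$ties, 0L)

  t2 <- winner_tally(rbind(q1 = c(A = 40, B = 40, C = 20)))
  expect_equal(sum(t2$counts), 0L)
  expect_equal(t2$ties, 1L)

  # half-integer means compare exactly: 40.5 beats 40
  t3 <- winner_tally(rbind(q1 = c(A = 40.5, B = 40, C = 0)))
  expect_equal(t3$counts[["A"]], 1L)

  expect_error(winner_tally(rbind(c(A = 1, B = NA))),
               class = "ragvar_validation_error")
})

test_that("winner tally matches the brute-force oracle and conserves counts", {
  withr::with_seed(17, {
    for (i in 1:20) {
      m <- random_totals_matrix(sample(2:12, 1))
      wt <- winner_tally(m)
      oracle <- oracle_winner_tally(m)
      expect_equal(wt$counts, oracle$counts)
      expect_equal(wt$ties, oracle$ties)
      expect_equal(sum(wt$counts) + wt$ties, wt$total)
      # invariance under a per-question constant shift
      shifted <- m + sample(0:5, nrow(m), replace = TRUE)
      wt2 <- winner_tally(shifted)
      expect_equal(wt2$counts, wt$counts)
      expect_equal(wt2$ties, wt$ties)
    }
  })
})

test_that("tally percentages round half-up to one decimal", {
  manual <- structure(list(counts = c(ragvar = 135L, baseline = 3L, vartool = 10L),
                           ties = 2L, total = 150L), class = "winner_tally")
  pct <- tally_percentages(manual)
  expect_equal(pct[["ragvar"]], 90.0)
  expect_equal(pct[["baseline"]], 2.0)
  expect_equal(pct[["vartool"]], 6.7)
  expect_equal(pct[["tie"]], 1.3)

  solo <- winner_tally(rbind(c(A = 5, B = 4)))
  expect_equal(tally_percentages(solo)[["A"]], 100.0)

  # half-up, not half-even: 0.05% of 2000 questions -> 0.1
  odd <- structure(list(counts = c(A = 1L, B = 1999L), ties = 0L,
                        total = 2000L), class = "winner_tally")
  expect_equal(tally_percentages(odd)[["A"]], 0.1)
})

test_that("llm_judge round-trips stub scores and refuses bad output", {
  j <- llm_judge("a question", "an answer",
                 stub_judge_backend(9, 9, 10, 9, 8))
  expect_s3_class(j$scores, "criterion_scores")
  expect_equal(unname(unclass(j$scores)), c(9, 9, 10, 9, 8))
  expect_match(j$raw, "Rubric scores")

  expect_error(
    llm_judge("q", "a", stub_judge_backend(accuracy = 11)),
    class = "ragvar_judging_error"
  )
  expect_error(
    llm_judge("q", "a", stub_judge_backend(accuracy = 7.5)),
    class = "ragvar_judging_error"
  )
  word_salad <- llm_backend(function(b) "no scores here", name = "bad-judge")
  expect_error(llm_judge("q", "a", word_salad), class = "ragvar_judging_error")
})

test_that("batch judging keys evaluations correctly", {
  systems <- c("ragvar", "baseline", "vartool")
  questions <- list(c("q1", "rs1"), c("q2", "rs2"))
  judges <- list(
    ragvar = stub_judge_backend(9, 9, 10, 9, 8),
    baseline = stub_judge_backend(4, 5, 7, 7, 3),
    vartool = stub_judge_backend(6, 4, 8, 7, 8)
  )
  evals <- list()
  for (qk in questions) {
    for (s in systems) {
      res <- llm_judge(qk[1], sprintf("answer from %s", s), judges[[s]])
      evals[[length(evals) + 1L]] <-
        answer_evaluation(qk[1], qk[2], s, "judge", res$scores)
    }
  }
  expect_length(evals, 6L)
  df <- do.call(rbind, lapply(evals, function(e) {
    data.frame(template_id = e$template_id, rs_id = e$rs_id,
               system = e$system, total = e$total)
  }))
  expect_equal(df$total[df$system == "ragvar"], c(45, 45))
  m <- totals_matrix(df)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(winner_tally(m)$counts[["ragvar"]], 2L)
})

test_that("score tables round-trip through CSV with validation", {
  cfg <- score_sim_config(6, list(A = 8, B = 5), seed = 13)
  sc <- simulate_scores(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sc, path, row.names = FALSE)
  back <- read_score_table(path)
  expect_equal(back$total, sc$total)

  bad <- sc
  bad$accuracy[1] <- 12
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_score_table(path), class = "ragvar_validation_error")

  # unpaired tables are rejected at pivot
  msc <- mean_rater_scores(sc)
  expect_error(totals_matrix(msc[-1, ]), class = "ragvar_validation_error")
})
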