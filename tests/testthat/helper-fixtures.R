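# Shared fixtures: every test input is built in code at run time.

canonical_fixture_json <- function() {
  paste(readLines(system.file("extdata", "variants", "rs34637584.json",
                              package = "ragvar"),
                  warn = FALSE, encoding = "UTF-8"),
        collapse = "\n")
}

# temp fixture directory with the canonical record plus synthetic ones
local_fixture_dir <- function(rs_ids = c("rs34637584", "rs671", "rs429358"),
                              seed = 11L, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  write_variant_fixtures(dir, rs_ids, seed = seed)
  dir
}

packaged_recoder <- function() {
  fixture_recoder(system.file("extdata", "recoder_table.tsv",
                              package = "ragvar"))
}

# independent Friedman oracle: textbook rank-sum route via stats::friedman.test
oracle_friedman_chi2 <- function(m) {
  unname(stats::friedman.test(as.matrix(m))$statistic)
}

# independent mid-rank computation from the counting definition
oracle_midranks <- function(row) {
  vapply(row, function(v) sum(row < v) + (sum(row == v) + 1) / 2, numeric(1))
}

# exact two-sided signed-rank p by enumerating every sign assignment
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# ICC(2,2) oracle: mean squares taken from a two-way aov decomposition
oracle_icc_2_2 <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    q = factor(rep(seq_len(nrow(m)), ncol(m))),
    r = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  a <- stats::anova(stats::aov(y ~ q + r, data = df))
  MSR <- a["q", "Mean Sq"]; MSC <- a["r", "Mean Sq"]
  MSE <- a["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (MSC - MSE) / nrow(m))
}

# brute-force per-question argmax-with-tie tally
oracle_winner_tally <- function(m) {
  counts <- stats::setNames(integer(ncol(m)), colnames(m))
  ties <- 0L
  for (i in seq_len(nrow(m))) {
    mx <- max(m[i, ])
    hits <- colnames(m)[m[i, ] == mx]
    if (length(hits) == 1L) counts[hits] <- counts[hits] + 1L else ties <- ties + 1L
  }
  list(counts = counts, ties = ties)
}

random_totals_matrix <- function(n, systems = c("A", "B", "C")) {
  m <- matrix(sample(0:50, n * length(systems), replace = TRUE),
              nrow = n, dimnames = list(NULL, systems))
  m
}
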