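test_that("vote aggregation follows the majority rule with EQUIV ties", {
  expect_identical(aggregate_votes(c("ARIR", "ARIR", "HRIR")), "ARIR")
  expect_identical(aggregate_votes(c("ARIR", "HRIR", "EQUIV")), "EQUIV")
  expect_identical(aggregate_votes(c("HRIR", "HRIR", "HRIR")), "HRIR")
  expect_identical(aggregate_votes(c("EQUIV", "ARIR", "EQUIV")), "EQUIV")
  # order invariance
  expect_identical(aggregate_votes(c("HRIR", "ARIR", "ARIR")), "ARIR")
  expect_error(aggregate_votes(c("ARIR", "HRIR")), "three votes")
  expect_error(aggregate_votes(c("ARIR", "HRIR", "MAYBE")), "votes must be")
})

test_that("Clopper-Pearson reproduces the study interval and boundaries", {
  ci <- clopper_pearson(21, 28)
  expect_equal(round(unname(ci), 2), c(0.55, 0.89))
  expect_identical(unname(clopper_pearson(28, 28)["high"]), 1)
  expect_identical(unname(clopper_pearson(0, 28)["low"]), 0)
  expect_error(clopper_pearson(29, 28), "successes")
})

test_that("Clopper-Pearson agrees with binomial tail bisection", {
  for (n in c(5, 28, 40)) {
    for (k in unique(c(0, 1, floor(n / 3), floor(3 * n / 4), n))) {
      expect_equal(unname(clopper_pearson(k, n)), unname(cp_oracle(k, n)),
                   tolerance = 1e-9)
    }
  }
})

test_that("interval endpoints are monotone in the success count", {
  ci <- t(vapply(0:28, function(k) clopper_pearson(k, 28), numeric(2)))
  expect_true(all(diff(ci[, "low"]) >= 0))
  expect_true(all(diff(ci[, "high"]) >= 0))
})

test_that("exact interval coverage is at least nominal", {
  set.seed(91)
  k <- stats::rbinom(5000, 28, 0.75)
  covered <- vapply(k, function(ki) {
    ci <- clopper_pearson(ki, 28)
    ci["low"] <= 0.75 && 0.75 <= ci["high"]
  }, logical(1))
  expect_gte(mean(covered), 0.95 - 0.01)
})

test_that("non-inferiority test reproduces the blinded-review outcome", {
  # 17 A-RIR, 4 equivalent, 7 H-RIR via unanimous per-case votes
  records <- c(rep(list(rep("ARIR", 3)), 17),
               rep(list(rep("EQUIV", 3)), 4),
               rep(list(rep("HRIR", 3)), 7))
  res <- noninferiority_test(records, margin = 0.45)
  expect_identical(c(res$n_arir, res$n_equiv, res$n_hrir), c(17L, 4L, 7L))
  expect_equal(res$proportion, 0.75)
  expect_equal(round(res$ci_low, 2), 0.55)
  expect_equal(round(res$ci_high, 2), 0.89)
  expect_true(res$non_inferior)

  # strict inequality: a margin equal to the lower limit fails
  res2 <- noninferiority_test(records, margin = res$ci_low)
  expect_false(res2$non_inferior)

  all_h <- noninferiority_test(rep(list(rep("HRIR", 3)), 28), margin = 0.45)
  expect_equal(all_h$proportion, 0)
  expect_false(all_h$non_inferior)
})

test_that("paired one-sided t-test behaves on shifts and degenerate input", {
  set.seed(101)
  y <- rnorm(10)
  # a positive shift (with measurement jitter, so differences are not
  # literally constant) is detected one-sided
  res <- paired_t_one_sided(y + 1 + rnorm(10, 0, 0.1), y, "greater")
  expect_lt(res$p, 0.05)
  expect_equal(res$df, 9)
  expect_error(paired_t_one_sided(c(1, 2, 3), c(0, 1, 2)), "degenerate")
  expect_error(paired_t_one_sided(1, 2), "length")
})

test_that("paired t-test type-I error is calibrated at the 5% level", {
  set.seed(111)
  rej <- mean(replicate(2000, {
    x <- rnorm(28); y <- rnorm(28)
    paired_t_one_sided(x, y, "greater")$p < 0.05
  }))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("ANOVA with gated Tukey mirrors the study's comparison pattern", {
  g <- c(1, 2, 3, 4)
  same <- anova_tukey(list(a = g, b = g, c = g))
  expect_equal(same$F, 0)
  expect_equal(same$p_overall, 1)
  expect_false(same$tukey_run)
  expect_null(same$tukey)

  set.seed(121)
  noise <- rnorm(4, 0, 0.1)
  sep <- anova_tukey(list(a = c(0, 0, 0, 0) + noise,
                          b = c(0, 0, 0, 0) + rnorm(4, 0, 0.1),
                          c = c(10, 10, 10, 10) + rnorm(4, 0, 0.1)))
  expect_lt(sep$p_overall, 0.001)
  expect_true(sep$tukey_run)
  p_ab <- sep$tukey$p_adj[sep$tukey$comparison == "b-a"]
  expect_gt(p_ab, 0.05)
  expect_lt(max(sep$tukey$p_adj[sep$tukey$comparison != "b-a"]), 0.001)
  expect_error(anova_tukey(list(a = g, b = g)), "three groups")
})

test_that("ANOVA F and Tukey p match closed-form oracles", {
  groups <- list(a = c(1.1, 2.3, 0.7, 1.9), b = c(2.0, 2.8, 3.1, 2.2),
                 c = c(0.4, 0.9, 1.5, 0.2))
  res <- anova_tukey(groups)
  # hand-computed one-way ANOVA
  k <- length(groups); n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 1) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  Fo <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$F, Fo, tolerance = 1e-6)
  expect_equal(res$p_overall, stats::pf(Fo, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-6)
  if (res$tukey_run) {
    mse <- ssw / (n - k)
    q_ba <- abs(mean(groups$b) - mean(groups$a)) / sqrt(mse / 4)
    p_ba <- stats::ptukey(q_ba, k, n - k, lower.tail = FALSE)
    expect_equal(res$tukey$p_adj[res$tukey$comparison == "b-a"], p_ba,
                 tolerance = 1e-6)
  }
})

test_that("paired sample-size formula follows the z arithmetic", {
  res <- sample_size_paired(sd = 1, mean_diff = 1)
  expect_identical(res$n, 7)
  expect_equal(res$n_raw, (stats::qnorm(0.95) + stats::qnorm(0.8))^2,
               tolerance = 1e-12)
  # doubling the SD quadruples the raw size
  expect_equal(sample_size_paired(sd = 2, mean_diff = 1)$n_raw,
               4 * res$n_raw, tolerance = 1e-12)
  # the study's stated inputs, exposed for audit
  study <- sample_size_paired(sd = 0.11, mean_diff = 0.03, margin = 0.05)
  expect_equal(study$effect, 0.08)
  expect_error(sample_size_paired(sd = 0, mean_diff = 1), "positive")
  expect_error(sample_size_paired(sd = 1, mean_diff = -2, margin = 1),
               "effect")
})
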