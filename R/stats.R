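VOTE_LABELS <- c("ARIR", "HRIR", "EQUIV")

#' Aggregate three blinded evaluator votes into one case label
#'
#' Majority vote over exactly three labels from `ARIR`, `HRIR`, `EQUIV`; a
#' three-way split is scored `EQUIV`.
#'
#' @param votes Character vector of exactly 3 labels.
#' @return A single label.
#' @export
aggregate_votes <- function(votes) {
  votes <- toupper(as.character(votes))
  if (length(votes) != 3L)
    stop("exactly three votes per case are required", call. = FALSE)
  if (!all(votes %in% VOTE_LABELS))
    stop("votes must be one of ", paste(VOTE_LABELS, collapse = ", "),
         call. = FALSE)
  tab <- table(factor(votes, levels = VOTE_LABELS))
  if (max(tab) == 1L) return("EQUIV")
  names(tab)[which.max(tab)]
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval obtained from beta-distribution quantiles; the
#' lower bound is 0 when `successes = 0` and the upper bound 1 when
#' `successes = n`.
#'
#' @param successes,n Non-negative counts, `successes <= n`, `n >= 1`.
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric `c(low, high)`.
#' @export
clopper_pearson <- function(successes, n, confidence = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    stop("need 0 <= successes <= n and n >= 1", call. = FALSE)
  alpha <- 1 - confidence
  low <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  high <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(low = low, high = high)
}

#' Non-inferiority test on blinded-review votes
#'
#' Aggregates per-case votes, counts the cases preferring the automated
#' registration or judged equivalent, and computes the exact two-sided 95%
#' interval for that proportion. The automated method is non-inferior when
#' the interval's lower limit strictly exceeds the margin.
#'
#' @param records A list of 3-vote character vectors, or a data.frame whose
#'   non-`case_id` columns hold one evaluator's votes each.
#' @param margin Non-inferiority margin on the proportion scale
#'   (default 0.45).
#' @param confidence Confidence level for the exact interval.
#' @return A list of class `noninferiority_result`: counts `n_arir`,
#'   `n_equiv`, `n_hrir`, the `proportion`, `ci_low`, `ci_high`, `margin`,
#'   and the `non_inferior` flag.
#' @export
noninferiority_test <- function(records, margin = 0.45, confidence = 0.95) {
  if (is.data.frame(records)) {
    cols <- setdiff(names(records), "case_id")
    records <- lapply(seq_len(nrow(records)),
                      function(i) as.character(unlist(records[i, cols])))
  }
  if (length(records) < 1L)
    stop("at least one vote record is required", call. = FALSE)
  labels <- vapply(records, aggregate_votes, character(1))
  tab <- table(factor(labels, levels = VOTE_LABELS))
  n <- length(labels)
  successes <- as.integer(tab[["ARIR"]] + tab[["EQUIV"]])
  ci <- clopper_pearson(successes, n, confidence)
  structure(list(n_arir = as.integer(tab[["ARIR"]]),
                 n_equiv = as.integer(tab[["EQUIV"]]),
                 n_hrir = as.integer(tab[["HRIR"]]),
                 n = n, successes = successes,
                 proportion = successes / n,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 margin = margin,
                 non_inferior = unname(ci["low"]) > margin),
            class = "noninferiority_result")
}

#' @export
print.noninferiority_result <- function(x, ...) {
  cat(sprintf("Blinded review: A-RIR %d, equivalent %d, H-RIR %d (n = %d)\n",
              x$n_arir, x$n_equiv, x$n_hrir, x$n))
  cat(sprintf("A-RIR preferable or equivalent: %.2f (95%% CI %.2f-%.2f)\n",
              x$proportion, x$ci_low, x$ci_high))
  cat(sprintf("Non-inferior at margin %.2f: %s\n", x$margin,
              if (x$non_inferior) "yes" else "no"))
  invisible(x)
}

#' One-sided paired t-test
#'
#' Classic paired t statistic on the differences `x - y` with `n - 1` degrees
#' of freedom and a one-sided p-value for the stated alternative.
#'
#' @param x,y Equal-length numeric series (n >= 2).
#' @param alternative `"greater"` (mean of x - y > 0) or `"less"`.
#' @return A list with `t`, `df`, `p`, and the mean difference `estimate`.
#' @export
paired_t_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate test: all paired differences are equal", call. = FALSE)
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, estimate = unname(ht$estimate))
}

#' One-way ANOVA with gated Tukey HSD
#'
#' One-way analysis of variance across three or more groups; Tukey's honestly
#' significant difference post-hoc comparisons are computed only when the
#' overall p-value is below `gate` (otherwise marked not run).
#'
#' @param groups Named list of >= 3 numeric vectors, each of length >= 2.
#' @param gate Overall p-value threshold gating the post-hoc test.
#' @return A list with `F`, `p_overall`, `tukey_run`, and `tukey` (a
#'   data.frame of pairwise adjusted p-values and mean differences, or NULL).
#' @export
anova_tukey <- function(groups, gate = 0.05) {
  if (length(groups) < 3L)
    stop("at least three groups are required", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs >= 2 observations", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, 1L)),
                                  levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  Fval <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  tukey <- NULL
  run <- is.finite(p) && p < gate
  if (run) {
    tk <- stats::TukeyHSD(fit)$group
    tukey <- data.frame(comparison = rownames(tk),
                        diff = tk[, "diff"], lwr = tk[, "lwr"],
                        upr = tk[, "upr"], p_adj = tk[, "p adj"],
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(F = Fval, p_overall = p, tukey_run = run, tukey = tukey)
}

#' Paired sample size for a non-inferiority margin (normal approximation)
#'
#' `n = ceiling( ((z_{1-alpha} + z_{power}) * sd / effect)^2 )` with
#' `effect = mean_diff + margin`, the standard paired non-inferiority
#' formulation. All inputs are echoed back so the arithmetic is auditable.
#'
#' @param sd Standard deviation of the paired differences.
#' @param mean_diff Expected mean difference favouring the new method.
#' @param margin Non-inferiority margin on the same scale (default 0).
#' @param alpha One-sided type-I error (default 0.05).
#' @param power Target power (default 0.8).
#' @return A list with `n` and the formula inputs (`effect`, `z_alpha`,
#'   `z_power`, `sd`, `mean_diff`, `margin`, `alpha`, `power`).
#' @export
sample_size_paired <- function(sd, mean_diff, margin = 0, alpha = 0.05,
                               power = 0.8) {
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  effect <- mean_diff + margin
  if (effect <= 0)
    stop("effect (mean_diff + margin) must be positive", call. = FALSE)
  z_alpha <- stats::qnorm(1 - alpha)
  z_power <- stats::qnorm(power)
  n_raw <- ((z_alpha + z_power) * sd / effect)^2
  list(n = ceiling(n_raw), n_raw = n_raw, effect = effect,
       z_alpha = z_alpha, z_power = z_power, sd = sd,
       mean_diff = mean_diff, margin = margin, alpha = alpha, power = power)
}
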