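#' Two-sided variance-ratio F-test for homoscedasticity
#'
#' The statistic is the larger sample variance over the smaller, so F >= 1;
#' the two-sided p-value is twice the upper-tail probability of the F
#' distribution with the matching degrees of freedom, capped at 1.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return list with `statistic`, `p_value`, `df1`, `df2` (numerator and
#'   denominator degrees of freedom).
#' @export
f_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0)
    stop("a sample has zero variance; the variance-ratio F-test is ",
         "degenerate", call. = FALSE)
  if (vx >= vy) {
    f <- vx / vy
    df1 <- length(x) - 1L; df2 <- length(y) - 1L
  } else {
    f <- vy / vx
    df1 <- length(y) - 1L; df2 <- length(x) - 1L
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  list(statistic = f, p_value = p, df1 = df1, df2 = df2)
}

#' Gated two-sample comparison: F-test, then Student or Welch t-test
#'
#' Homoscedasticity is first checked with the two-sided variance-ratio
#' [f_test()]. If its p-value is at least `alpha_gate` the samples are
#' treated as homoscedastic and compared with Student's pooled-variance
#' two-sided t-test; otherwise with Welch's t-test using the
#' Welch–Satterthwaite degrees of freedom. Both the F and t branches are
#' recorded in the result.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param alpha_gate significance level of the homoscedasticity gate.
#' @return a `comparison_result`: list with `test_used` ("student" or
#'   "welch"), `f_statistic`, `f_p_value`, `t_statistic`, `t_p_value`, `df`,
#'   `n1`, `n2`, `mean_diff`, `alpha_gate`.
#' @export
gated_t_test <- function(x, y, alpha_gate = 0.05) {
  ft <- f_test(x, y)
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  diff <- mean(x) - mean(y)
  if (ft$p_value >= alpha_gate) {
    test_used <- "student"
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    test_used <- "welch"
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- if (se == 0 && diff == 0) 0 else diff / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(
    list(test_used = test_used, f_statistic = ft$statistic,
         f_p_value = ft$p_value, t_statistic = t_stat, t_p_value = p,
         df = df, n1 = n1, n2 = n2, mean_diff = diff,
         alpha_gate = alpha_gate),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s t-test: t = %.4g, df = %.4g, p = %.4g (%s); F gate: F = %.4g, p = %.4g\n",
    x$test_used, x$t_statistic, x$df, x$t_p_value,
    significance_tier(x$t_p_value), x$f_statistic, x$f_p_value))
  invisible(x)
}

#' Significance tier labels
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

#' Run gated comparisons over a tidy group/value table
#'
#' @param data data.frame with columns `group` and `value`.
#' @param pairings list of length-2 character vectors naming the groups to
#'   compare; default all pairs.
#' @param alpha_gate homoscedasticity-gate level.
#' @param bonferroni apply Bonferroni correction across the pairings
#'   (off by default, matching per-pair reporting).
#' @return data.frame with one row per pairing: the two group names, sample
#'   sizes, F and t statistics and p-values, the branch used, and the
#'   significance tier.
#' @export
compare_groups <- function(data, pairings = NULL, alpha_gate = 0.05,
                           bonferroni = FALSE) {
  stopifnot(all(c("group", "value") %in% names(data)))
  groups <- split(data$value, data$group)
  if (is.null(pairings))
    pairings <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- lapply(pairings, function(pr) {
    r <- gated_t_test(groups[[pr[1]]], groups[[pr[2]]],
                      alpha_gate = alpha_gate)
    data.frame(group1 = pr[1], group2 = pr[2], n1 = r$n1, n2 = r$n2,
               f_statistic = r$f_statistic, f_p_value = r$f_p_value,
               test_used = r$test_used, t_statistic = r$t_statistic,
               df = r$df, t_p_value = r$t_p_value)
  })
  out <- do.call(rbind, rows)
  if (bonferroni)
    out$t_p_value <- pmin(1, out$t_p_value * nrow(out))
  out$tier <- significance_tier(out$t_p_value)
  out
}
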