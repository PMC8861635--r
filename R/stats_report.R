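#' Select a two-sample test by normality and variance diagnostics
#'
#' Both samples are tested for normality (Shapiro-Wilk) and for equal
#' variances (Levene's test, mean-centered). The comparison test is then:
#' both normal and equal variance, Student's t; both normal and unequal
#' variance, Welch's t; non-normal with equal variance, Mann-Whitney U;
#' non-normal with unequal variance, Kolmogorov-Smirnov. All tests are
#' two-sided; `alpha` governs the diagnostics and the final call alike.
#'
#' @param a,b numeric samples, each of length >= 3.
#' @param alpha significance level for the diagnostic tests (default 0.05).
#' @return object of class `ct_test_decision`: list with `test` (one of
#'   `"student_t"`, `"welch_t"`, `"mann_whitney_u"`,
#'   `"kolmogorov_smirnov"`), `normality_p` (length 2), `variance_p`, and
#'   the two-sided `p` of the chosen test with its `statistic`.
#' @export
choose_test <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L) stop("each sample needs n >= 3")
  norm_p <- c(stats::shapiro.test(a)$p.value, stats::shapiro.test(b)$p.value)
  lev <- car::leveneTest(c(a, b),
                         factor(rep(c("a", "b"), c(length(a), length(b)))),
                         center = "mean")
  var_p <- lev[["Pr(>F)"]][1L]
  normal <- all(norm_p > alpha)
  equal_var <- var_p > alpha
  if (normal && equal_var) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test <- "student_t"
  } else if (normal) {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    test <- "welch_t"
  } else if (equal_var) {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    test <- "mann_whitney_u"
  } else {
    ht <- suppressWarnings(stats::ks.test(a, b))
    test <- "kolmogorov_smirnov"
  }
  structure(list(test = test, normality_p = norm_p, variance_p = var_p,
                 statistic = unname(ht$statistic), p = ht$p.value,
                 alpha = alpha),
            class = "ct_test_decision")
}

#' @export
print.ct_test_decision <- function(x, ...) {
  cat(sprintf("<ct_test_decision> %s: p = %.4g (normality p = %.3g/%.3g, variance p = %.3g)\n",
              x$test, x$p, x$normality_p[1L], x$normality_p[2L], x$variance_p))
  invisible(x)
}

#' Compare two groups with the auto-selected test
#'
#' Runs [choose_test()] and reports, for each group, the mean with a 95%
#' t-distribution confidence interval alongside the chosen test's two-sided
#' p value.
#'
#' @inheritParams choose_test
#' @param conf confidence level for the mean CIs (default 0.95).
#' @return list with the decision, per-group `mean`, `ci_lower`, `ci_upper`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, conf = 0.95) {
  dec <- choose_test(a, b, alpha = alpha)
  ci <- function(x) {
    m <- mean(x)
    half <- stats::qt(1 - (1 - conf) / 2, df = length(x) - 1L) *
      stats::sd(x) / sqrt(length(x))
    c(mean = m, lower = m - half, upper = m + half)
  }
  list(decision = dec, test = dec$test, statistic = dec$statistic, p = dec$p,
       group_a = ci(a), group_b = ci(b), conf = conf)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
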