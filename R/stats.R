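#' Normality-gated paired comparison of per-subject metrics
#'
#' Compares two matched per-subject metric vectors with the protocol used
#' throughout the evaluation: a Shapiro-Wilk test is applied to *each
#' sample*; if both return p > 0.05 the samples are compared with a paired
#' t-test, otherwise with a Wilcoxon signed-rank test. (Gating on the two
#' samples rather than on the paired differences follows the stated
#' protocol; the textbook alternative of testing the differences is noted
#' as a limitation.) All tests are two-sided.
#'
#' Zero differences are dropped before signed-ranking (the classical
#' Wilcoxon treatment); if every difference is zero the comparison is
#' degenerate and an error is raised.
#'
#' @param a,b Matched numeric vectors (same subjects, same order),
#'   length >= 3, finite.
#' @return A list of class `paired_comparison`: `test_used`
#'   (`"paired_t"` or `"wilcoxon_signed_rank"`), `statistic` (t, or the
#'   signed-rank V), `df` (t only), `p_value`, `gate_p_values`
#'   (Shapiro-Wilk p for `a` and `b`), `n`.
#' @examples
#' set.seed(1)
#' a <- rnorm(16, 2); compare_paired(a, a + rnorm(16, 0.3, 0.2))
#' @export
compare_paired <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("samples must have matched lengths")
  if (length(a) < 3L) stop("need at least 3 matched pairs")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite metric values")
  if (all(a == b)) stop("degenerate comparison: all paired differences are zero")
  gate <- c(a = shapiro.test(a)$p.value, b = shapiro.test(b)$p.value)
  if (all(gate > 0.05)) {
    tt <- t.test(a, b, paired = TRUE)
    out <- list(test_used = "paired_t",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  } else {
    d <- a - b
    d <- d[d != 0]
    if (length(d) == 0L) {
      stop("degenerate comparison: all paired differences are zero")
    }
    wt <- wilcox.test(d)
    out <- list(test_used = "wilcoxon_signed_rank",
                statistic = unname(wt$statistic), df = NA_real_,
                p_value = wt$p.value)
  }
  structure(c(out, list(gate_p_values = gate, n = length(a),
                        sample_a = a, sample_b = b)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  lab <- if (x$test_used == "paired_t") {
    sprintf("paired t-test: t = %.4g, df = %g", x$statistic, x$df)
  } else {
    sprintf("Wilcoxon signed-rank test: V = %g", x$statistic)
  }
  cat(sprintf("%s, p value = %.4g (n = %d)\n", lab, x$p_value, x$n))
  cat(sprintf("  normality gate (Shapiro-Wilk p): a = %.3g, b = %.3g\n",
              x$gate_p_values[["a"]], x$gate_p_values[["b"]]))
  invisible(x)
}

# Classical (mean-centred) Levene statistic: one-way ANOVA on absolute
# deviations from the group mean.
levene_test <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("Levene test needs at least 2 groups")
  if (any(tabulate(group) < 2L)) stop("each group needs at least 2 values")
  mu <- ave(values, group)
  z <- abs(values - mu)
  an <- anova(lm(z ~ group))
  list(F_statistic = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
       p_value = an$`Pr(>F)`[1])
}

#' Levene comparison of pre- versus post-calibration variance
#'
#' Tests whether calibration reduces the spread of a metric *between
#' subjects* — the robustness claim — with a classical mean-centred Levene
#' test for homoscedasticity between two groups: the uncalibrated
#' per-subject values, and the post-calibration values pooled across both
#' calibration methods (so with n subjects the post group has 2n values).
#' Reported degrees of freedom are (k-1, N-k) = (1, N-2).
#'
#' @param pre Per-subject metric values without calibration.
#' @param post_linear,post_svr Matched per-subject values after linear and
#'   SVR calibration. `post_svr` may be `NULL` to compare against a single
#'   method.
#' @return A list of class `variance_comparison`: `F_statistic`, `df`,
#'   `p_value`, `n_pre`, `n_post`.
#' @export
compare_variance <- function(pre, post_linear, post_svr = NULL) {
  pre <- as.numeric(pre)
  post <- c(as.numeric(post_linear), as.numeric(post_svr))
  if (length(pre) < 3L) stop("need at least 3 subjects")
  if (!is.null(post_svr) && length(post_svr) != length(post_linear)) {
    stop("post-calibration samples must have matched lengths")
  }
  if (!all(is.finite(pre)) || !all(is.finite(post))) stop("non-finite metric values")
  lev <- levene_test(c(pre, post),
                     rep(c("pre", "post"), c(length(pre), length(post))))
  structure(c(lev, list(n_pre = length(pre), n_post = length(post))),
            class = "variance_comparison")
}

#' @export
print.variance_comparison <- function(x, ...) {
  cat(sprintf("Levene test (mean-centred): F = %.4g, df = (%d, %d), p value = %.4g\n",
              x$F_statistic, x$df[1], x$df[2], x$p_value))
  cat(sprintf("  groups: %d pre vs %d pooled post-calibration values\n",
              x$n_pre, x$n_post))
  invisible(x)
}
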