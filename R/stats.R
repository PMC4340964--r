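#' Inferential statistics for the decoding pipeline
#'
#' One-sample, paired and Welch t tests plus the Bonferroni and
#' Benjamini-Hochberg multiple-testing rules, implemented from their
#' definitions. Group decoding significance is a one-tailed one-sample t of
#' per-subject accuracies against chance (0.5); percent-signal-change
#' comparisons use the paired two-tailed t; stimulus-similarity comparisons
#' use the unequal-variance (Welch) t.
#'
#' @name pipeline-stats
NULL

# Upper-tail probability of |t| for Student's t via the regularized
# incomplete beta function I_x(a, b) (pbeta is exactly that function).
t_tail_prob <- function(statistic, df) {
  x <- df / (df + statistic^2)
  0.5 * pbeta(x, df / 2, 0.5)
}

t_pvalue <- function(statistic, df, tail) {
  tail <- match.arg(tail, c("one", "two"))
  if (!is.finite(statistic)) {
    p <- if (statistic > 0) 0 else 1
    return(if (tail == "two") 0 else p)
  }
  upper <- t_tail_prob(abs(statistic), df)
  if (tail == "two") {
    2 * upper
  } else {
    # one-tailed against the alternative mean > null
    if (statistic >= 0) upper else 1 - upper
  }
}

new_test_result <- function(statistic, df, p, tail, flagged = FALSE) {
  structure(
    list(statistic = statistic, df = df, p = p, tail = tail, flagged = flagged),
    class = "facemvpa_test"
  )
}

#' @export
print.facemvpa_test <- function(x, ...) {
  cat(sprintf(
    "t(%s) = %.4g, %s-tailed p = %.4g%s\n",
    format(round(x$df, 2)), x$statistic, x$tail, x$p,
    if (x$flagged) " [flagged: degenerate variance]" else ""
  ))
  invisible(x)
}

#' One-sample t test
#'
#' @param values numeric vector, n >= 2.
#' @param null_mean mean under the null hypothesis.
#' @param tail `"one"` (alternative: mean greater than `null_mean`) or `"two"`.
#' @return list with `statistic`, `df`, `p`, `tail`, `flagged`.
#' @examples
#' one_sample_t(c(0.55, 0.62, 0.58, 0.61), null_mean = 0.5, tail = "one")
#' @export
one_sample_t <- function(values, null_mean = 0, tail = c("one", "two")) {
  tail <- match.arg(tail)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("one_sample_t requires n >= 2", call. = FALSE)
  s <- sd(values)
  df <- n - 1
  if (s == 0) {
    d <- mean(values) - null_mean
    stat <- if (d == 0) 0 else sign(d) * Inf
    return(new_test_result(stat, df, t_pvalue(stat, df, tail), tail,
      flagged = TRUE
    ))
  }
  stat <- (mean(values) - null_mean) / (s / sqrt(n))
  new_test_result(stat, df, t_pvalue(stat, df, tail), tail)
}

#' Paired t test
#'
#' One-sample t test on elementwise differences `x - y`.
#' @param x,y paired numeric vectors of equal length.
#' @inheritParams one_sample_t
#' @export
paired_t <- function(x, y, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("paired_t requires equal lengths", call. = FALSE)
  one_sample_t(x - y, null_mean = 0, tail = tail)
}

#' Welch two-sample t test (unequal variances)
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom, the test the
#' stimulus-similarity analysis uses to compare within- and between-set pixel
#' correlation distributions.
#' @param x,y numeric vectors, each n >= 2.
#' @inheritParams one_sample_t
#' @export
welch_t <- function(x, y, tail = c("one", "two")) {
  tail <- match.arg(tail)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t requires n >= 2 in both samples", call. = FALSE)
  }
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  if (vx + vy == 0) {
    d <- mean(x) - mean(y)
    stat <- if (d == 0) 0 else sign(d) * Inf
    df <- length(x) + length(y) - 2
    return(new_test_result(stat, df, t_pvalue(stat, df, tail), tail, flagged = TRUE))
  }
  stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  new_test_result(stat, df, t_pvalue(stat, df, tail), tail)
}

#' Bonferroni-corrected per-test level
#'
#' @param alpha family-wise level.
#' @param m number of tests (for the ROI analyses, 12 regions).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 12) # 0.004 to three decimals
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Benjamini-Hochberg step-up FDR rule
#'
#' Finds the largest k with p_(k) <= k q / m and declares all p-values at or
#' below p_(k) significant (independence/PRDS assumption, no
#' Benjamini-Yekutieli factor).
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with logical `significant` (aligned with input order) and the
#'   data-dependent `threshold` (`p_(k)`, or 0 when nothing is rejected).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  pvals <- as.numeric(pvals)
  m <- length(pvals)
  if (m == 0) {
    return(list(significant = logical(0), threshold = 0))
  }
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ord <- sort(pvals)
  ok <- which(ord <= seq_len(m) * q / m)
  if (length(ok) == 0) {
    return(list(significant = rep(FALSE, m), threshold = 0))
  }
  thr <- ord[max(ok)]
  list(significant = pvals <= thr, threshold = thr)
}
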