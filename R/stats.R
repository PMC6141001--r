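# Shared statistical primitives. Standard tests are delegated to stats::
# machinery; thin wrappers add a uniform tibble result and explicit handling
# of degenerate (zero-variance / fully tied) inputs.

test_result <- function(method, statistic, p_value, n, alternative,
                        degenerate = FALSE) {
  tibble::tibble(method = method, statistic = statistic, p_value = p_value,
                 n = as.integer(n), alternative = alternative,
                 degenerate = degenerate)
}

#' One-sample t test against zero
#'
#' @param values Numeric vector, length >= 2.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param mu Null mean (default 0).
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `n`,
#'   `alternative`, `degenerate`. Zero-variance input is flagged degenerate:
#'   mean equal to `mu` gives t = 0 with p = 0.5 (one-tailed) or 1; otherwise
#'   p = 1 with a warning.
#' @examples
#' one_sample_t(c(-0.1, -0.2, -0.3), alternative = "less")
#' @export
one_sample_t <- function(values, alternative = c("two.sided", "less", "greater"),
                         mu = 0) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    if (mean(values) == mu) {
      p <- if (alternative == "two.sided") 1 else 0.5
      return(test_result("one-sample t", 0, p, n, alternative, TRUE))
    }
    warning("zero-variance sample with nonzero mean; degenerate t test",
            call. = FALSE)
    return(test_result("one-sample t", NA_real_, 1, n, alternative, TRUE))
  }
  ht <- stats::t.test(values, mu = mu, alternative = alternative)
  test_result("one-sample t", unname(ht$statistic), ht$p.value, n, alternative)
}

#' Paired and unpaired two-sample t tests
#'
#' Two-tailed by default, matching the reporting convention for whole-fiber
#' (unpaired) and matched subcellular region (paired) comparisons.
#'
#' @param a,b Numeric vectors; equal length required for the paired test.
#' @param alternative Alternative hypothesis.
#' @return A one-row result tibble (see [one_sample_t()]). A paired test with
#'   constant differences is degenerate: zero difference gives t = 0, p = 1.
#' @export
paired_t <- function(a, b, alternative = "two.sided") {
  if (length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  res <- one_sample_t(a - b, alternative = alternative)
  res$method <- "paired t"
  res
}

#' @rdname paired_t
#' @export
unpaired_t <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  n <- length(a) + length(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(test_result("unpaired t", 0, 1, n, alternative, TRUE))
    }
    warning("both groups constant; degenerate t test", call. = FALSE)
    return(test_result("unpaired t", NA_real_, 1, n, alternative, TRUE))
  }
  ht <- stats::t.test(a, b, alternative = alternative)
  test_result("unpaired t", unname(ht$statistic), ht$p.value, n, alternative)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For `min(n) <= 8` with no
#' ties the exact two-sided p value is used (via the exact Wilcoxon rank-sum
#' distribution); otherwise a normal approximation with average-rank tie
#' correction and no continuity correction is applied.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return A one-row result tibble; `statistic` is the U statistic of `a`.
#'   Fully tied pooled data is degenerate with p = 1.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  n <- n1 + n2
  if (length(ties) == 1) {
    return(test_result("Mann-Whitney", u1, 1, n, "two.sided", TRUE))
  }
  if (min(n1, n2) <= 8 && !has_ties) {
    u_min <- min(u1, n1 * n2 - u1)
    p <- min(1, 2 * stats::pwilcox(u_min, n1, n2))
    return(test_result("Mann-Whitney (exact)", u1, p, n, "two.sided"))
  }
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(test_result("Mann-Whitney", u1, 1, n, "two.sided", TRUE))
  }
  z <- (u1 - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  test_result("Mann-Whitney (normal approx.)", u1, min(1, p), n, "two.sided")
}

#' Exact binomial test against 50:50
#'
#' Two-sided exact binomial test of `k` successes in `n` trials against a null
#' proportion of 0.5 (the method behind "Wilson/Brown" binomial comparisons in
#' common graphing software): the p value sums all outcome probabilities not
#' exceeding that of the observed count.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @return A one-row result tibble; `statistic` is `k`.
#' @examples
#' binomial_vs_half(5, 5)  # p = 2 * 0.5^5 = 0.0625
#' @export
binomial_vs_half <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  ht <- stats::binom.test(k, n, p = 0.5)
  test_result("exact binomial vs 0.5", k, ht$p.value, n, "two.sided")
}
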