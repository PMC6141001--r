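# Focus-perinucleus overlap: observed fractions, multiplicative independence
# null, and the cohort one-tailed t test.

#' Perimeter fractions P, F and observed overlap
#'
#' Computes the fraction of perimeter samples that are perinuclear (P), focal
#' (F) and both (observed overlap), from two masks of equal length.
#'
#' @param perinuclear,focal Logical masks over the same perimeter sampling grid.
#' @return A one-row tibble with `P`, `F`, `O_obs`.
#' @export
overlap_fractions <- function(perinuclear, focal) {
  stopifnot(is.logical(perinuclear), is.logical(focal),
            length(perinuclear) == length(focal))
  tibble::tibble(P = mean(perinuclear), F = mean(focal),
                 O_obs = mean(perinuclear & focal))
}

#' Predicted overlap under independence
#'
#' Multiplication rule for two independent events: if perinuclear domains and
#' focal deficiency were placed independently, the expected overlap fraction
#' of the perimeter would be the exact product `P * F`.
#'
#' @param P,F Perimeter fractions in \[0, 1\].
#' @return `P * F` (vectorised).
#' @examples
#' predicted_overlap(0.262, 0.200)  # 0.0524
#' @export
predicted_overlap <- function(P, F) {
  stopifnot(all(P >= 0 & P <= 1), all(F >= 0 & F <= 1))
  P * F
}

#' Per-fiber overlap records
#'
#' Builds the per-fiber record table of the overlap analysis: P, F, observed
#' overlap, predicted overlap under independence and their difference.
#'
#' @param annotations A `domain_annotation` tibble ([annotate_cohort()] or
#'   [annotate_from_truth()]).
#' @return A tibble with `fiber_id`, `P`, `F`, `O_obs`, `O_pred = P * F` and
#'   `diff = O_pred - O_obs`.
#' @export
overlap_records <- function(annotations) {
  dplyr::transmute(annotations,
                   fiber_id = .data$fiber_id, P = .data$P, F = .data$F,
                   O_obs = .data$O_obs,
                   O_pred = predicted_overlap(.data$P, .data$F),
                   diff = .data$O_pred - .data$O_obs)
}

#' Cohort test of focus-perinucleus association
#'
#' One-sample t test of the per-fiber differences `O_pred - O_obs` against
#' zero. The default alternative is `"less"`: observed overlap exceeding the
#' independence prediction drives the differences below zero, the signature of
#' perinuclear enrichment of foci. Also counts foci overlapping a perinuclear
#' domain in at least one sample.
#'
#' @param records Per-fiber record tibble from [overlap_records()], or a
#'   `domain_annotation` tibble (converted automatically).
#' @param alternative Direction of the one-tailed test (flag to flip), or
#'   `"two.sided"`.
#' @return An object of class `overlap_test_result`: the records plus
#'   `mean_diff`, `statistic`, `df`, `p_value`, `n`, `n_foci`,
#'   `n_foci_overlapping`, `alternative`, `degenerate`. Has
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#'   methods.
#' @export
overlap_test <- function(records, alternative = c("less", "greater",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  if (!"diff" %in% names(records)) records <- overlap_records(records)
  n <- nrow(records)
  if (n < 2) stop("need at least 2 fibers for the overlap test", call. = FALSE)
  tt <- one_sample_t(records$diff, alternative = alternative)
  if (tt$degenerate[1] && mean(records$diff) != 0) {
    # constant nonzero differences: flagged, p = 1 rather than an error
    tt$p_value <- 1
  }
  with_focus <- records$F > 0
  structure(
    list(records = records, mean_diff = mean(records$diff),
         statistic = tt$statistic, df = n - 1L, p_value = tt$p_value,
         n = n, n_foci = sum(with_focus),
         n_foci_overlapping = sum(with_focus & records$O_obs > 0),
         alternative = alternative, degenerate = tt$degenerate[1]),
    class = "overlap_test_result")
}

#' Cohort-aggregate perimeter fractions
#'
#' Aggregates per-fiber fractions two ways: the unweighted mean across fibers
#' and, when perimeter lengths are available, the pooled perimeter-length-
#' weighted fraction (the default headline, equivalent to classifying the
#' concatenated perimeter of the whole cohort).
#'
#' @param annotations A `domain_annotation` tibble, optionally with a
#'   `perimeter_px` column.
#' @return A tibble with one row per aggregation (`weighting`), and columns
#'   `P`, `F`, `O_obs`, `O_pred_from_means` (product of aggregate P and F) and
#'   `mean_O_pred` (mean of per-fiber products).
#' @export
cohort_overlap_summary <- function(annotations) {
  rec <- overlap_records(annotations)
  w <- if ("perimeter_px" %in% names(annotations)) {
    annotations$perimeter_px
  } else {
    rep(1, nrow(annotations))
  }
  agg <- function(weights, label) {
    tibble::tibble(
      weighting = label,
      P = stats::weighted.mean(rec$P, weights),
      F = stats::weighted.mean(rec$F, weights),
      O_obs = stats::weighted.mean(rec$O_obs, weights),
      O_pred_from_means = stats::weighted.mean(rec$P, weights) *
        stats::weighted.mean(rec$F, weights),
      mean_O_pred = stats::weighted.mean(rec$O_pred, weights))
  }
  dplyr::bind_rows(agg(w, "perimeter_weighted"), agg(rep(1, nrow(rec)), "mean_of_fibers"))
}

#' @export
print.overlap_test_result <- function(x, ...) {
  cat("Focus-perinucleus overlap test\n")
  cat(sprintf("  fibers: %d, foci: %d (%d overlapping a perinuclear domain)\n",
              x$n, x$n_foci, x$n_foci_overlapping))
  cat(sprintf("  mean(O_pred - O_obs) = %.4g\n", x$mean_diff))
  cat(sprintf("  t = %.4g on %d df, one-sided (%s) p = %.3g%s\n",
              x$statistic, x$df, x$alternative, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
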