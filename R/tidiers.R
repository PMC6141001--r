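# broom-style tidiers and ggplot2 autoplot methods for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for standard curves
#'
#' `tidy()` returns the regression terms; `glance()` a one-row model summary
#' with efficiency and QC status.
#'
#' @param x A `standard_curve` from [fit_standard_curve()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(target = x$target, term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(target = x$target, slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency,
                 qc_pass = x$qc_pass, n_points = nrow(x$data))
}

#' Plot a standard curve
#'
#' Dilution points and the fitted log-linear regression, annotated with the
#' amplification efficiency.
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.standard_curve <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(log10(.data$copies), .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(
      x = "log10(template copies)", y = "Cq (cycles)",
      title = sprintf("%s standard curve", object$target),
      subtitle = sprintf("slope %.3f, efficiency %.1f%%%s", object$slope,
                         100 * object$efficiency,
                         if (object$qc_pass) "" else " (QC fail)")) +
    ggplot2::theme_minimal()
}

#' Tidiers for the overlap test
#'
#' `tidy()` returns the per-fiber records; `glance()` the cohort statistic.
#'
#' @param x An `overlap_test_result` from [overlap_test()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.overlap_test_result <- function(x, ...) x$records

#' @rdname tidy.overlap_test_result
#' @export
glance.overlap_test_result <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, statistic = x$statistic,
                 df = x$df, p_value = x$p_value, n = x$n, n_foci = x$n_foci,
                 n_foci_overlapping = x$n_foci_overlapping,
                 alternative = x$alternative, degenerate = x$degenerate)
}

#' Histogram of predicted minus observed overlap
#'
#' Frequency histogram of the per-fiber `O_pred - O_obs` differences with the
#' independence reference at zero; mass below zero indicates observed overlap
#' in excess of chance.
#'
#' @param object An `overlap_test_result`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_test_result <- function(object, bins = 20, ...) {
  ggplot2::ggplot(object$records, ggplot2::aes(.data$diff)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "predicted - observed overlap (perimeter fraction)",
                  y = "fibers",
                  subtitle = sprintf("t = %.3g, one-tailed p = %.3g (n = %d)",
                                     object$statistic, object$p_value,
                                     object$n)) +
    ggplot2::theme_minimal()
}

#' Tidiers for the paired region analysis
#'
#' `tidy()` returns per-fiber fold changes; `glance()` mean folds and test
#' p values.
#'
#' @param x A `paired_region_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.paired_region_analysis <- function(x, ...) x$pairs

#' @rdname tidy.paired_region_analysis
#' @export
glance.paired_region_analysis <- function(x, ...) {
  pt <- x$paired_tests
  gp <- function(metric) {
    if (is.null(pt)) NA_real_ else pt$p_value[pt$metric == metric]
  }
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    mean_dloop_fold = mean(x$pairs$dloop_fold),
    mean_nd1_fold = mean(x$pairs$nd1_fold),
    mean_deletion_diff = mean(x$pairs$deletion_diff),
    p_dloop = gp("dloop_copies"), p_nd1 = gp("nd1_copies"),
    p_deletion = gp("deletion_level"), n_excluded = length(x$excluded))
}

#' Paired fold-change plot
#'
#' Focus versus matched-region values connected per fiber, one panel per
#' metric, on a log scale.
#'
#' @param object A `paired_region_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paired_region_analysis <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(fiber_id = object$pairs$fiber_id, metric = "D-Loop copies",
                   focus = object$pairs$focus_dloop,
                   matched = object$pairs$matched_dloop),
    tibble::tibble(fiber_id = object$pairs$fiber_id, metric = "ND1 copies",
                   focus = object$pairs$focus_nd1,
                   matched = object$pairs$matched_nd1)) |>
    tidyr::pivot_longer(c("focus", "matched"), names_to = "region",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$region, .data$value,
                                     group = .data$fiber_id)) +
    ggplot2::geom_line(alpha = 0.4) + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "copy number (per region)") +
    ggplot2::theme_minimal()
}

#' Plot perimeter intensity profiles
#'
#' Corrected intensity along the fiber perimeter per channel, optionally
#' shading the annotated perinuclear and focal domains.
#'
#' @param profiles Long corrected profile tibble ([profile_cohort()]).
#' @param fiber Fiber id to plot.
#' @param annotations Optional `domain_annotation` tibble used to shade
#'   perinuclear (blue) and focal (red) domains.
#' @return A ggplot.
#' @export
plot_perimeter_profile <- function(profiles, fiber, annotations = NULL) {
  d <- profiles[profiles$fiber_id == fiber, ]
  if (nrow(d) == 0) stop("no profile for fiber ", fiber, call. = FALSE)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$arc_fraction, .data$corrected,
                                       colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc position (fraction of perimeter)",
                  y = "corrected intensity", colour = NULL,
                  title = paste("Fiber", fiber)) +
    ggplot2::theme_minimal()
  if (!is.null(annotations)) {
    a <- annotations[annotations$fiber_id == fiber, ]
    if (nrow(a) == 1) {
      shade <- function(mask, fill) {
        runs <- cyclic_runs(mask[[1]])
        n <- length(mask[[1]])
        if (nrow(runs) == 0) return(NULL)
        segs <- purrr::pmap(runs, function(start, end, length) {
          if (end >= start) {
            tibble::tibble(xmin = (start - 1) / n, xmax = end / n)
          } else {
            tibble::tibble(xmin = c((start - 1) / n, 0), xmax = c(1, end / n))
          }
        })
        ggplot2::annotate("rect", xmin = dplyr::bind_rows(segs)$xmin,
                          xmax = dplyr::bind_rows(segs)$xmax,
                          ymin = -Inf, ymax = Inf, alpha = 0.15, fill = fill)
      }
      p <- p + shade(a$perinuclear, "blue") + shade(a$focal, "red")
    }
  }
  p
}
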