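# Perinuclear-domain detection, COX-deficiency classification and prevalence.

#' Cohort-wide DAPI threshold for perinuclear domains
#'
#' Pools corrected DAPI intensities over every perimeter sample of every fiber
#' in the cohort and returns their `q`-quantile (linear interpolation between
#' order statistics, `stats::quantile` type 7). Perimeter positions whose
#' corrected DAPI exceeds this threshold are called perinuclear.
#'
#' @param profiles Long corrected profile tibble (see [profile_cohort()]).
#' @param q Quantile in (0, 1); default 0.85.
#' @return The intensity threshold (scalar).
#' @export
cohort_dapi_threshold <- function(profiles, q = 0.85) {
  stopifnot(q > 0, q < 1)
  v <- profiles$corrected[profiles$channel == "dapi"]
  if (length(v) == 0) stop("no corrected DAPI values in profiles", call. = FALSE)
  if (length(v) < 20) {
    stop("pooled DAPI sample too small (< 20 values) for a cohort quantile",
         call. = FALSE)
  }
  unname(stats::quantile(v, q, type = 7, names = FALSE))
}

#' Perinuclear perimeter mask from corrected DAPI
#'
#' Marks samples with corrected DAPI intensity strictly greater than the
#' cohort threshold, then removes runs shorter than `min_run` samples; runs
#' are cyclic, so a domain spanning the arc origin counts once.
#'
#' @param corrected_dapi Numeric vector of corrected DAPI along the perimeter.
#' @param threshold Intensity threshold from [cohort_dapi_threshold()].
#' @param min_run Minimum run length kept (samples).
#' @return Logical mask of the same length.
#' @export
annotate_perinuclear <- function(corrected_dapi, threshold, min_run = 3L) {
  drop_short_runs(corrected_dapi > threshold, min_run)
}

#' Automated COX-deficiency mask along a perimeter profile
#'
#' Surrogate for point-wise visual annotation: a perimeter sample is called
#' COX-deficient when its corrected MTCOI/SDHA ratio falls below
#' `deficiency_fraction` of the fiber's median ratio *and* SDHA exceeds the
#' fiber median (the SDH-positive requirement that distinguishes respiratory
#' deficiency from mere absence of mitochondria). Runs shorter than `min_run`
#' are removed cyclically. Manual annotations, when supplied to
#' [annotate_cohort()], take precedence over this rule.
#'
#' @param mtcoi,sdha Corrected intensity vectors along the perimeter.
#' @param deficiency_fraction Ratio cutoff as a fraction of the median ratio.
#' @param min_run Minimum run length kept (samples).
#' @param epsilon Guard added to SDHA in the denominator.
#' @return Logical focal mask.
#' @export
classify_deficient_points <- function(mtcoi, sdha, deficiency_fraction = 0.5,
                                      min_run = 3L, epsilon = 1e-6) {
  stopifnot(length(mtcoi) == length(sdha))
  if (all(sdha == 0)) {
    stop("all-zero SDHA profile; fiber cannot be classified", call. = FALSE)
  }
  ratio <- mtcoi / (sdha + epsilon)
  deficient <- ratio < deficiency_fraction * stats::median(ratio) &
    sdha > stats::median(sdha)
  drop_short_runs(deficient, min_run)
}

#' Annotate a cohort of perimeter profiles
#'
#' Runs the full annotation stage: computes the cohort DAPI quantile threshold
#' (unless supplied), builds per-fiber perinuclear masks and focal-deficiency
#' masks (automated rule, or manual interval annotations where provided) and
#' derives the perimeter fractions P, F and observed overlap.
#'
#' @param profiles Long corrected profile tibble from [profile_cohort()].
#' @param config An [analysis_config()].
#' @param threshold Optional pre-computed DAPI threshold.
#' @param manual Optional manual annotation tibble (see
#'   [read_manual_annotation()]); fibers present there use the manual focal
#'   mask verbatim.
#' @return A `domain_annotation` tibble: `fiber_id`, `n_samples`, list-columns
#'   `perinuclear` and `focal`, fractions `P`, `F`, `O_obs`, and
#'   `perimeter_px`. The DAPI threshold used is kept in attribute
#'   `dapi_threshold`.
#' @export
annotate_cohort <- function(profiles, config = analysis_config(),
                            threshold = NULL, manual = NULL) {
  if (is.null(threshold)) {
    threshold <- cohort_dapi_threshold(profiles, config$quantile_q)
  }
  manual_ids <- if (is.null(manual) || nrow(manual) == 0) {
    character()
  } else {
    unique(manual$fiber_id)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(profiles, "fiber_id", "idx", "arc_fraction", "channel",
                  "corrected", dplyr::any_of("perimeter_px")),
    names_from = "channel", values_from = "corrected")
  out <- wide |>
    dplyr::group_by(.data$fiber_id) |>
    dplyr::group_map(function(g, key) {
      g <- dplyr::arrange(g, .data$idx)
      peri <- annotate_perinuclear(g$dapi, threshold, config$min_run)
      focal <- if (key$fiber_id %in% manual_ids) {
        manual_focal_mask(manual[manual$fiber_id == key$fiber_id, ], nrow(g))
      } else {
        classify_deficient_points(g$mtcoi, g$sdha,
                                  config$deficiency_fraction,
                                  config$min_run, config$ratio_epsilon)
      }
      row <- domain_annotation_row(key$fiber_id, peri, focal)
      if ("perimeter_px" %in% names(g)) row$perimeter_px <- g$perimeter_px[1]
      row
    }) |>
    dplyr::bind_rows()
  attr(out, "dapi_threshold") <- threshold
  out
}

#' Classify a fiber from its focal perimeter fraction
#'
#' A fiber is fully COX-deficient when at least `deficient_cover` of its
#' perimeter samples are deficient; it carries a COX-deficient focus when the
#' focal fraction is positive but below `focus_max_fraction` (a circumscribed
#' deficiency within an otherwise COX-positive fiber); larger partial coverage
#' is an intermediate fiber; zero focal fraction is COX-positive.
#'
#' @param focal_fraction Fraction of perimeter samples classified deficient.
#' @param config An [analysis_config()].
#' @return A tibble with `label` (`COX-positive`, `intermediate`,
#'   `COX-deficient`) and `has_focus`.
#' @export
classify_fiber <- function(focal_fraction, config = analysis_config()) {
  stopifnot(all(focal_fraction >= 0 & focal_fraction <= 1))
  label <- dplyr::case_when(
    focal_fraction >= config$deficient_cover ~ "COX-deficient",
    focal_fraction == 0 ~ "COX-positive",
    focal_fraction < config$focus_max_fraction ~ "COX-positive",
    TRUE ~ "intermediate")
  tibble::tibble(label = label,
                 has_focus = focal_fraction > 0 &
                   focal_fraction < config$focus_max_fraction)
}

#' Foci prevalence summary
#'
#' Cohort counts, percentages and `1:x` prevalence ratios of COX-deficient
#' foci and fully COX-deficient fibers.
#'
#' @param classes Tibble with columns `label` and `has_focus` (one row per
#'   fiber; see [classify_fiber()]).
#' @return One-row tibble: `n_fibers`, `n_fully_deficient`, `n_foci`,
#'   `pct_fully_deficient`, `pct_foci`, and ratio strings `foci_to_total`,
#'   `foci_to_deficient` (`"undefined"` when there are no foci).
#' @export
prevalence_summary <- function(classes) {
  stopifnot(nrow(classes) >= 1)
  n <- nrow(classes)
  n_def <- sum(classes$label == "COX-deficient")
  n_foci <- sum(classes$has_focus)
  ratio <- function(num) {
    if (n_foci == 0) "undefined" else sprintf("1:%g", round(num / n_foci, 1))
  }
  tibble::tibble(
    n_fibers = n, n_fully_deficient = n_def, n_foci = n_foci,
    pct_fully_deficient = 100 * n_def / n, pct_foci = 100 * n_foci / n,
    foci_to_total = ratio(n), foci_to_deficient = ratio(n_def))
}
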