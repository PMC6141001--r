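# Triplex qPCR quantification: standard curves with efficiency QC, copy
# number, deletion level, NTC margin filtering and paired region comparisons.

#' Fit a qPCR standard curve
#'
#' Least-squares regression of mean Cq on log10(copies) over a plasmid
#' dilution series. Amplification efficiency is `10^(-1/slope) - 1`; the curve
#' passes QC when efficiency lies within `efficiency_bounds` (default
#' 95-100%; the upper bound carries a 1e-4 tolerance so that the canonical
#' perfect-doubling slope -3.3219, a rounded representation of
#' -1/log10(2), passes at 100%).
#'
#' @param standards Tibble with columns `copies` and `cq` (one mean Cq per
#'   dilution point); at least 4 distinct dilution points required.
#' @param target Target label carried into the result.
#' @param efficiency_bounds Admissible efficiency fractions.
#' @return An object of class `standard_curve`: `target`, `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `qc_pass`, `data`. Has `tidy()`,
#'   `glance()` and `autoplot()` methods.
#' @examples
#' std <- tibble::tibble(copies = 10^(7:2), cq = 40 - 3.3219 * (7:2))
#' fit_standard_curve(std, "ND1")
#' @export
fit_standard_curve <- function(standards, target = "target",
                               efficiency_bounds = c(0.95, 1.00)) {
  stopifnot(all(c("copies", "cq") %in% names(standards)))
  standards <- standards[stats::complete.cases(standards[, c("copies", "cq")]), ]
  if (length(unique(standards$copies)) < 4) {
    stop("need >= 4 distinct dilution points", call. = FALSE)
  }
  if (any(standards$copies <= 0)) {
    stop("standard copies must be positive", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10(copies), data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop("non-negative standard-curve slope; Cq must fall with template",
         call. = FALSE)
  }
  # r^2 from sums of squares directly (summary.lm warns on perfect fits)
  sst <- sum((standards$cq - mean(standards$cq))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  eff <- 10^(-1 / slope) - 1
  structure(
    list(target = target, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, efficiency = eff,
         qc_pass = eff >= efficiency_bounds[1] &&
           eff <= efficiency_bounds[2] + 1e-4,
         data = tibble::as_tibble(standards[, c("copies", "cq")])),
    class = "standard_curve")
}

#' Copies from Cq via a standard curve
#'
#' Inverts the log-linear model: `copies = 10^((cq - intercept) / slope)`.
#' Refuses a curve that failed efficiency QC unless `override = TRUE`.
#'
#' @param cq Numeric Cq values (NA, meaning no amplification, gives 0 copies).
#' @param curve A `standard_curve`.
#' @param override Quantify despite a failed QC curve.
#' @return Copy numbers (same length as `cq`).
#' @export
quantify_copies <- function(cq, curve, override = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$qc_pass && !override) {
    stop(sprintf(
      "standard curve for %s failed efficiency QC (%.1f%%); use override = TRUE to force",
      curve$target, 100 * curve$efficiency), call. = FALSE)
  }
  out <- 10^((cq - curve$intercept) / curve$slope)
  out[is.na(cq)] <- 0
  out
}

#' Major-arc deletion level from ND1 and ND4 copy numbers
#'
#' `(1 - nd4/nd1) * 100` on a 0-100 scale: 0 means no ND4 deletion, 100 means
#' every mtDNA molecule carries an ND4 deletion. Negative raw values (which
#' can arise from assay noise or deletions encompassing ND1) are clipped to
#' zero; values are clipped above at 100. `nd1 = 0` is undefined and returns
#' `NA`.
#'
#' @param nd1_copies,nd4_copies Copy numbers (vectorised).
#' @return Deletion level in percent, clipped to \[0, 100\].
#' @examples
#' deletion_level(1000, 1000)  # 0
#' deletion_level(1000, 0)     # 100
#' deletion_level(1000, 1200)  # clipped to 0
#' @export
deletion_level <- function(nd1_copies, nd4_copies) {
  out <- ifelse(nd1_copies > 0,
                pmin(pmax((1 - nd4_copies / nd1_copies) * 100, 0), 100),
                NA_real_)
  unname(out)
}

#' D-Loop/ND1 consistency check
#'
#' In regions without deletions encompassing ND1, D-Loop and ND1 measure the
#' same molecule count, so a D-Loop/ND1 ratio far above unity indicates
#' triple-stranded D-Loop (or another artefact). Flags ND1-intact regions with
#' ratio above `tolerance_fold`; ND1-deleted regions are skipped.
#'
#' @param dloop_copies,nd1_copies Copy numbers (both positive; vectorised).
#' @param nd1_intact Logical, whether the region's deletions spare ND1.
#' @param tolerance_fold Ratio above which an intact region is flagged.
#' @return Tibble with `dloop_nd1_ratio` and `dloop_flag`.
#' @export
dloop_nd1_check <- function(dloop_copies, nd1_copies, nd1_intact = TRUE,
                            tolerance_fold = 2) {
  stopifnot(all(dloop_copies > 0), all(nd1_copies > 0))
  ratio <- dloop_copies / nd1_copies
  tibble::tibble(dloop_nd1_ratio = ratio,
                 dloop_flag = nd1_intact & ratio > tolerance_fold)
}

#' No-template-control margin filter
#'
#' A fiber group (a focus and its matched regions, or a whole-fiber control)
#' passes only if *every* region's mean ND1 Cq sits at least `margin` cycles
#' below the ND1 no-template control. An `NA` NTC (no amplification in the
#' control) passes any region that amplified.
#'
#' @param region_cq Tibble with columns `fiber_id`, `region_id` and
#'   `nd1_cq` (mean ND1 Cq per region; `NA` = no amplification).
#' @param ntc_cq ND1 NTC Cq (`NA` for no amplification).
#' @param margin Required margin in cycles (default 3).
#' @return Tibble with one row per fiber group: `fiber_id`, `ntc_pass`.
#' @export
ntc_filter <- function(region_cq, ntc_cq, margin = 3) {
  stopifnot(all(c("fiber_id", "nd1_cq") %in% names(region_cq)))
  region_pass <- if (is.na(ntc_cq)) {
    !is.na(region_cq$nd1_cq)
  } else {
    !is.na(region_cq$nd1_cq) & region_cq$nd1_cq <= ntc_cq - margin
  }
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(fiber_id = region_cq$fiber_id,
                                   pass = region_pass),
                    .data$fiber_id),
    ntc_pass = all(.data$pass), .groups = "drop")
}

#' Quantify a triplex qPCR plate
#'
#' Full plate workflow: per-target standard curves with efficiency QC,
#' triplicate Cq averaging (replicates are averaged before the log-linear
#' transform), copy-number quantification, deletion level, D-Loop/ND1 check
#' and the ND1 NTC margin filter applied per fiber group.
#'
#' @param plate Plate tibble (`well`, `fiber_id`, `region_id`, `region_kind`,
#'   `target`, `replicate`, `cq`; standards carry `region_kind = "standard"`
#'   and a `copies` column, NTCs `region_kind = "NTC"`).
#' @param config An [analysis_config()].
#' @param override_qc Quantify even if a standard curve fails efficiency QC.
#' @param per_replicate If `TRUE`, quantify each replicate separately and
#'   average copies instead of Cq (alternative aggregation order).
#' @return A list of class `plate_quant`:
#'   \describe{
#'     \item{curves}{Named list of `standard_curve` objects per target.}
#'     \item{regions}{Per-region tibble with mean Cq and copies per target,
#'       `nd4_nd1_ratio`, `nd1_nd4_ratio`, `deletion_level`,
#'       `dloop_nd1_ratio`, `dloop_flag`, `ntc_pass`.}
#'     \item{ntc_cq}{Named per-target NTC mean Cq.}
#'   }
#' @export
quantify_plate <- function(plate, config = analysis_config(),
                           override_qc = FALSE, per_replicate = FALSE) {
  need <- c("fiber_id", "region_id", "region_kind", "target", "replicate", "cq")
  stopifnot(all(need %in% names(plate)))
  targets <- c("DLoop", "ND1", "ND4")
  miss <- setdiff(targets, unique(plate$target))
  if (length(miss) > 0) {
    stop("plate lacks target(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }

  std <- plate[plate$region_kind == "standard", ]
  if (!"copies" %in% names(std) || nrow(std) == 0) {
    stop("plate has no standard wells with a `copies` column", call. = FALSE)
  }
  curves <- lapply(stats::setNames(targets, targets), function(tg) {
    s <- std[std$target == tg, ] |>
      dplyr::group_by(.data$copies) |>
      dplyr::summarise(cq = mean(.data$cq), .groups = "drop")
    fit_standard_curve(s, tg, config$efficiency_bounds)
  })

  ntc <- plate[plate$region_kind == "NTC", ] |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(cq = if (all(is.na(.data$cq))) NA_real_ else
      mean(.data$cq, na.rm = TRUE), .groups = "drop")
  ntc_cq <- stats::setNames(ntc$cq[match(targets, ntc$target)], targets)

  samples <- plate[!plate$region_kind %in% c("standard", "NTC"), ]
  mean_cq <- samples |>
    dplyr::group_by(.data$fiber_id, .data$region_id, .data$region_kind,
                    .data$target) |>
    dplyr::summarise(mean_cq = if (all(is.na(.data$cq))) NA_real_ else
      mean(.data$cq, na.rm = TRUE), .groups = "drop")

  copies_for <- function(tg) {
    if (per_replicate) {
      samples[samples$target == tg, ] |>
        dplyr::group_by(.data$region_id) |>
        dplyr::summarise(copies = mean(quantify_copies(.data$cq, curves[[tg]],
                                                       override_qc)),
                         .groups = "drop")
    } else {
      m <- mean_cq[mean_cq$target == tg, ]
      tibble::tibble(region_id = m$region_id,
                     copies = quantify_copies(m$mean_cq, curves[[tg]],
                                              override_qc))
    }
  }

  wide_cq <- tidyr::pivot_wider(mean_cq, names_from = "target",
                                values_from = "mean_cq",
                                names_glue = "cq_{tolower(.name)}")
  regions <- wide_cq
  for (tg in targets) {
    cp <- copies_for(tg)
    names(cp)[2] <- paste0("copies_", tolower(tg))
    regions <- dplyr::left_join(regions, cp, by = "region_id")
  }
  regions <- dplyr::mutate(
    regions,
    nd4_nd1_ratio = ifelse(.data$copies_nd1 > 0,
                           .data$copies_nd4 / .data$copies_nd1, NA_real_),
    nd1_nd4_ratio = ifelse(.data$copies_nd4 > 0,
                           .data$copies_nd1 / .data$copies_nd4, NA_real_),
    deletion_level = deletion_level(.data$copies_nd1, .data$copies_nd4),
    deletion_undefined = .data$copies_nd1 <= 0)
  chk <- dloop_nd1_check(pmax(regions$copies_dloop, .Machine$double.xmin),
                         pmax(regions$copies_nd1, .Machine$double.xmin),
                         nd1_intact = !is.na(regions$deletion_level),
                         tolerance_fold = config$dloop_tolerance_fold)
  regions <- dplyr::bind_cols(regions, chk)

  nd1cq <- mean_cq[mean_cq$target == "ND1",
                   c("fiber_id", "region_id", "mean_cq")]
  names(nd1cq)[3] <- "nd1_cq"
  groups <- ntc_filter(nd1cq, ntc_cq[["ND1"]], config$ntc_margin_cycles)
  regions <- dplyr::left_join(regions, groups, by = "fiber_id")

  structure(list(curves = curves, regions = regions, ntc_cq = ntc_cq),
            class = "plate_quant")
}

#' Paired focus versus matched-region analysis
#'
#' For every fiber group passing the NTC filter, compares the focus region to
#' the mean of its matched COX-positive regions: per-fiber fold changes in
#' D-Loop and ND1 copy number, the deletion-level difference, paired
#' two-tailed t tests across fibers, and (when whole-fiber controls are
#' present) unpaired two-tailed comparisons of fully COX-deficient versus
#' COX-positive fibers.
#'
#' @param quant A `plate_quant` from [quantify_plate()], or its `regions`
#'   tibble.
#' @param apply_ntc_filter Drop fiber groups failing the NTC margin (default
#'   `TRUE`).
#' @return A list of class `paired_region_analysis`:
#'   \describe{
#'     \item{pairs}{Per-fiber tibble: folds `dloop_fold`, `nd1_fold`, deletion
#'       levels and their difference.}
#'     \item{paired_tests}{Tests of focus vs matched regions per metric.}
#'     \item{whole_fiber}{Unpaired whole-fiber comparison (may be empty).}
#'     \item{excluded}{Fiber ids dropped by the NTC filter or unmatched.}
#'   }
#' @export
paired_region_analysis <- function(quant, apply_ntc_filter = TRUE) {
  regions <- if (inherits(quant, "plate_quant")) quant$regions else quant
  excluded <- character()
  if (apply_ntc_filter && "ntc_pass" %in% names(regions)) {
    excluded <- unique(regions$fiber_id[!regions$ntc_pass &
                                          regions$region_kind %in%
                                          c("focus", "matched_positive")])
    regions <- regions[is.na(regions$ntc_pass) | regions$ntc_pass, ]
  }
  foci <- regions[regions$region_kind == "focus", ]
  matched <- regions[regions$region_kind == "matched_positive", ] |>
    dplyr::group_by(.data$fiber_id) |>
    dplyr::summarise(m_dloop = mean(.data$copies_dloop),
                     m_nd1 = mean(.data$copies_nd1),
                     m_del = mean(.data$deletion_level), .groups = "drop")
  unmatched <- setdiff(foci$fiber_id, matched$fiber_id)
  if (length(unmatched) > 0) {
    warning("excluding foci without matched regions: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
    excluded <- union(excluded, unmatched)
    foci <- foci[!foci$fiber_id %in% unmatched, ]
  }
  pairs <- dplyr::inner_join(
    foci[, c("fiber_id", "copies_dloop", "copies_nd1", "deletion_level")],
    matched, by = "fiber_id") |>
    dplyr::transmute(
      fiber_id = .data$fiber_id,
      dloop_fold = .data$copies_dloop / .data$m_dloop,
      nd1_fold = .data$copies_nd1 / .data$m_nd1,
      deletion_focus = .data$deletion_level,
      deletion_matched = .data$m_del,
      deletion_diff = .data$deletion_level - .data$m_del,
      focus_dloop = .data$copies_dloop, matched_dloop = .data$m_dloop,
      focus_nd1 = .data$copies_nd1, matched_nd1 = .data$m_nd1)
  paired_tests <- NULL
  if (nrow(pairs) >= 2) {
    paired_tests <- dplyr::bind_rows(
      dplyr::mutate(paired_t(pairs$focus_dloop, pairs$matched_dloop),
                    metric = "dloop_copies", .before = 1),
      dplyr::mutate(paired_t(pairs$focus_nd1, pairs$matched_nd1),
                    metric = "nd1_copies", .before = 1),
      dplyr::mutate(paired_t(pairs$deletion_focus, pairs$deletion_matched),
                    metric = "deletion_level", .before = 1))
  }
  whole <- NULL
  wp <- regions[regions$region_kind == "whole_fiber_positive", ]
  wd <- regions[regions$region_kind == "whole_fiber_deficient", ]
  if (nrow(wp) >= 2 && nrow(wd) >= 2) {
    whole <- dplyr::bind_rows(lapply(
      c(dloop_copies = "copies_dloop", nd1_copies = "copies_nd1",
        deletion_level = "deletion_level"),
      function(col) unpaired_t(wd[[col]], wp[[col]])))
    whole$metric <- c("dloop_copies", "nd1_copies", "deletion_level")
    whole$fold_deficient_vs_positive <- c(
      mean(wd$copies_dloop) / mean(wp$copies_dloop),
      mean(wd$copies_nd1) / mean(wp$copies_nd1), NA)
    whole <- dplyr::relocate(whole, "metric")
  }
  structure(list(pairs = pairs, paired_tests = paired_tests,
                 whole_fiber = whole, excluded = excluded),
            class = "paired_region_analysis")
}

#' @export
print.paired_region_analysis <- function(x, ...) {
  cat(sprintf("Paired subcellular qPCR analysis: %d focus/matched pairs\n",
              nrow(x$pairs)))
  if (nrow(x$pairs) > 0) {
    cat(sprintf("  mean D-Loop fold %.2f (range %.1f-%.1f), mean ND1 fold %.2f (range %.1f-%.1f)\n",
                mean(x$pairs$dloop_fold), min(x$pairs$dloop_fold),
                max(x$pairs$dloop_fold), mean(x$pairs$nd1_fold),
                min(x$pairs$nd1_fold), max(x$pairs$nd1_fold)))
  }
  if (!is.null(x$paired_tests)) {
    for (i in seq_len(nrow(x$paired_tests))) {
      cat(sprintf("  %s: paired t = %.3g, p = %.3g\n",
                  x$paired_tests$metric[i], x$paired_tests$statistic[i],
                  x$paired_tests$p_value[i]))
    }
  }
  if (length(x$excluded) > 0) {
    cat("  excluded fiber groups:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
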