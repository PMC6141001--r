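# Synthetic triplex qPCR: region ground truth (copy numbers per target) and
# plate simulation from a log-linear standard-curve model.

#' Simulate ground-truth copy numbers for microdissected regions
#'
#' Generates the region layout of the subcellular mtDNA assay: per fiber one
#' COX-deficient focus plus two identically sized matched COX-positive
#' subsarcolemmal regions, and a set of whole-fiber COX-positive and
#' COX-deficient control fibers. Copy numbers follow the focal phenotype:
#' D-Loop and ND1 densities are elevated in foci by mean folds
#' `dloop_fold`/`nd1_fold` (log-normal across fibers, mean-preserving), and
#' ND4 is reduced according to the region's deletion level, so that
#' `true ND4 <= true ND1` wherever a deletion is simulated.
#'
#' @param n_fibers Number of focus-bearing fibers (default 27, the size of the
#'   paired cohort the assay is designed around).
#' @param dloop_fold,nd1_fold Mean focal fold-elevation of D-Loop and ND1 copy
#'   density relative to matched regions (defaults 2.2 and 2.5).
#' @param fold_sd SD of log fold across fibers (0 gives identical folds).
#' @param base_dloop,base_nd1 Baseline copy density of a COX-positive region.
#' @param focus_deletion,positive_deletion Mean deletion level (fraction of
#'   molecules lacking ND4) in foci and in COX-positive regions.
#' @param n_whole_positive,n_whole_deficient Whole-fiber control counts.
#' @param whole_deficient_fold Copy-number fold of fully deficient whole
#'   fibers over positive ones (default 1.9).
#' @param seed Integer seed.
#' @return A tibble with one row per region: `fiber_id`, `region_id`,
#'   `region_kind` (focus / matched_positive / whole_fiber_positive /
#'   whole_fiber_deficient) and true `dloop`, `nd1`, `nd4` copy numbers.
#' @export
simulate_qpcr_truth <- function(n_fibers = 27,
                                dloop_fold = 2.2, nd1_fold = 2.5,
                                fold_sd = 0.25,
                                base_dloop = 1000, base_nd1 = 800,
                                focus_deletion = 0.6,
                                positive_deletion = 0.05,
                                n_whole_positive = 3L,
                                n_whole_deficient = 3L,
                                whole_deficient_fold = 1.9,
                                seed = 1L) {
  stopifnot(n_fibers >= 1, dloop_fold > 0, nd1_fold > 0, fold_sd >= 0,
            focus_deletion >= 0, focus_deletion <= 1,
            positive_deletion >= 0, positive_deletion <= 1)
  with_local_seed(seed, {
    rows <- list()
    # mean-preserving log-normal folds: E[fold] equals the requested mean
    rfold <- function(mean_fold) {
      exp(stats::rnorm(1, log(mean_fold) - fold_sd^2 / 2, fold_sd))
    }
    for (i in seq_len(n_fibers)) {
      fid <- sprintf("Q%03d", i)
      fd <- rfold(dloop_fold); fn <- rfold(nd1_fold)
      del_f <- min(1, max(0, stats::rnorm(1, focus_deletion, 0.1 * (fold_sd > 0))))
      del_p <- min(1, max(0, stats::rnorm(1, positive_deletion,
                                          0.02 * (fold_sd > 0))))
      mk <- function(region, kind, dl, n1, del) {
        tibble::tibble(fiber_id = fid, region_id = paste0(fid, "_", region),
                       region_kind = kind, dloop = dl, nd1 = n1,
                       nd4 = n1 * (1 - del))
      }
      rows <- c(rows, list(
        mk("focus", "focus", base_dloop * fd, base_nd1 * fn, del_f),
        mk("pos1", "matched_positive", base_dloop, base_nd1, del_p),
        mk("pos2", "matched_positive", base_dloop, base_nd1, del_p)))
    }
    for (i in seq_len(n_whole_positive)) {
      rows <- c(rows, list(tibble::tibble(
        fiber_id = sprintf("WP%02d", i), region_id = sprintf("WP%02d_whole", i),
        region_kind = "whole_fiber_positive", dloop = base_dloop * 5,
        nd1 = base_nd1 * 5, nd4 = base_nd1 * 5 * (1 - positive_deletion))))
    }
    for (i in seq_len(n_whole_deficient)) {
      rows <- c(rows, list(tibble::tibble(
        fiber_id = sprintf("WD%02d", i), region_id = sprintf("WD%02d_whole", i),
        region_kind = "whole_fiber_deficient",
        dloop = base_dloop * 5 * whole_deficient_fold,
        nd1 = base_nd1 * 5 * whole_deficient_fold,
        nd4 = base_nd1 * 5 * whole_deficient_fold * (1 - focus_deletion))))
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate a triplex qPCR plate from region ground truth
#'
#' Generates per-well Cq values for every region/target combination in
#' triplicate, a plasmid standard dilution series (all three targets at the
#' same copy input, as for a triplex plasmid standard) and no-template
#' controls, under the log-linear model
#' `Cq = intercept + slope * log10(copies) + Normal(0, noise_sd)`.
#' Regions with zero true copies yield `NA` Cq (no amplification).
#'
#' @param truth Region tibble from [simulate_qpcr_truth()] (columns
#'   `fiber_id`, `region_id`, `region_kind`, `dloop`, `nd1`, `nd4`).
#' @param params A [qpcr_sim_params()] object.
#' @return A plate tibble: `well`, `fiber_id`, `region_id`, `region_kind`,
#'   `target` (DLoop / ND1 / ND4), `replicate`, `cq`.
#' @examples
#' plate <- simulate_qpcr_plate(simulate_qpcr_truth(n_fibers = 2),
#'                              qpcr_sim_params(noise_sd = 0))
#' head(plate)
#' @export
simulate_qpcr_plate <- function(truth, params = qpcr_sim_params()) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  need <- c("fiber_id", "region_id", "region_kind", "dloop", "nd1", "nd4")
  if (!all(need %in% names(truth))) {
    stop("`truth` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(c(truth$dloop, truth$nd1, truth$nd4) < 0)) {
    stop("true copy numbers must be >= 0", call. = FALSE)
  }
  p <- params
  targets <- c(DLoop = "dloop", ND1 = "nd1", ND4 = "nd4")
  with_local_seed(p$seed, {
    long <- tidyr::pivot_longer(truth[, need], dplyr::all_of(unname(targets)),
                                names_to = "target", values_to = "copies")
    long$target <- names(targets)[match(long$target, targets)]
    long <- tidyr::uncount(long, p$n_replicates, .id = "replicate")
    cq <- ifelse(long$copies > 0,
                 p$intercept + p$slope * log10(pmax(long$copies, .Machine$double.xmin)),
                 NA_real_)
    if (p$noise_sd > 0) {
      cq <- cq + stats::rnorm(length(cq), 0, p$noise_sd)
    }
    samples <- tibble::tibble(fiber_id = long$fiber_id,
                              region_id = long$region_id,
                              region_kind = long$region_kind,
                              target = long$target,
                              replicate = as.integer(long$replicate), cq = cq)
    std <- tidyr::expand_grid(copies = p$dilution_copies,
                              target = names(targets),
                              replicate = seq_len(p$n_replicates))
    std_cq <- p$intercept + p$slope * log10(std$copies)
    if (p$noise_sd > 0) std_cq <- std_cq + stats::rnorm(nrow(std), 0, p$noise_sd)
    standards <- tibble::tibble(
      fiber_id = NA_character_,
      region_id = sprintf("STD_%g", std$copies),
      region_kind = "standard", target = std$target,
      replicate = as.integer(std$replicate), cq = std_cq)
    standards$copies <- std$copies
    ntc <- tidyr::expand_grid(target = names(targets),
                              replicate = seq_len(p$n_replicates))
    ntcs <- tibble::tibble(fiber_id = NA_character_, region_id = "NTC",
                           region_kind = "NTC", target = ntc$target,
                           replicate = as.integer(ntc$replicate),
                           cq = p$ntc_cq)
    samples$copies <- NA_real_
    ntcs$copies <- NA_real_
    plate <- dplyr::bind_rows(standards, ntcs, samples)
    plate$well <- sprintf("W%03d", seq_len(nrow(plate)))
    dplyr::relocate(plate, "well")
  })
}
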