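---
title: "Methods: perimeter profiling, focus-perinucleus overlap and single-region mtDNA quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perimeter profiling, focus-perinucleus overlap and single-region mtDNA quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofoci)
```

## The biological question

In mtDNA maintenance disorders (and in normal ageing), mtDNA deletions
clonally expand within individual skeletal muscle fibers until respiratory
chain complexes containing mtDNA-encoded subunits — most visibly cytochrome c
oxidase (COX, complex IV) — fail. The earliest visible lesion is not a fully
COX-deficient fiber but a small circumscribed *focus* of COX deficiency in the
subsarcolemmal space of an otherwise COX-positive fiber. mitofoci quantifies
two properties of such foci:

1. **Where foci sit on the fiber perimeter.** If foci arise preferentially
   next to myonuclei, the observed overlap between focal deficiency and
   perinuclear perimeter domains should exceed what independent placement
   predicts.
2. **What foci contain.** Laser-microdissected foci are genotyped by triplex
   qPCR (D-Loop / MT-ND1 / MT-ND4) to estimate mtDNA copy number and
   major-arc deletion level relative to matched COX-positive regions of the
   same fiber.

Both analyses operate on tabular data (per-arc-sample intensity records,
per-well Cq records), so every user-facing function takes and returns tibbles
and composes with the pipe.

## Perimeter profiling

A fiber cross-section is a simple closed polygon (the boundary, from an ROI
table) over three registered channel rasters: DAPI (nuclei), SDHA
(mitochondrial mass; complex II is entirely nuclear-encoded, so it is
insensitive to mtDNA deletions) and MTCOI (COX subunit I, mtDNA-encoded).

`extract_perimeter_profile()` samples the boundary at equal arc-length steps
(`sampling_step_px`, default 1 px). The intensity at a sample is the mean of
the channel over an inward-normal band of depth `band_depth_px` (default
10 px, the package's model of the subsarcolemmal compartment). The boundary
curve itself is infinitely thin, so some averaging depth is unavoidable; band
averaging over the subsarcolemmal depth is our documented choice, and on
noise-free synthetic data the profile value equals the geometric band mean to
interpolation accuracy. Inward normals come from the local tangent (central
differences on the resampled boundary), with polygon orientation determined
by the signed area; intensities are read by bilinear interpolation, clamped
at the raster edge with a warning.

Backgrounds differ between sections, so each channel is corrected by
subtracting the *modal* intensity of non-saturated pixels of its section
raster (`estimate_modal_background()`; histogram bin width 1 intensity unit,
appropriate for integer-valued acquisitions; pixels at or above
`saturation_level` are excluded). Corrected intensities are floored at zero —
negative fluorescence is physically meaningless and flooring makes the
correction idempotent.

## Perinuclear domains and focal deficiency

Perinuclear perimeter domains are detected by thresholding corrected DAPI at
the cohort-wide `quantile_q = 0.85` quantile of all corrected DAPI values
pooled over every sample of every fiber (linear interpolation between order
statistics; `stats::quantile` type 7). The comparison is strict (`>`), so a
cohort of identical values yields an empty mask. The pool is taken across all
patients; a per-patient threshold can be obtained by calling
`annotate_cohort()` per patient subset, but the pooled form is the default
because the threshold is defined on the cohort. Runs shorter than
`min_run = 3` samples are discarded to suppress single-sample noise, and runs
are treated cyclically so a domain spanning the arc origin is one domain.

Focal COX deficiency along the perimeter was originally a manual, visual
call. mitofoci provides a reproducible surrogate: a sample is COX-deficient
when its MTCOI/SDHA ratio falls below `deficiency_fraction = 0.5` of the
fiber's median ratio *and* SDHA exceeds the fiber median — the SDH-positive
requirement that distinguishes respiratory deficiency (mitochondria present,
COX absent) from absence of mitochondria. Manual interval annotations, when
supplied, override the rule verbatim per fiber. Whole fibers are then
classified from focal coverage: at least `deficient_cover = 95%` deficient
samples is a fully COX-deficient fiber; a positive fraction below
`focus_max_fraction = 50%` within an otherwise positive fiber is a focus; in
between is intermediate. `prevalence_summary()` reports cohort counts,
percentages and 1:x ratios.

## The overlap statistic

For each fiber we record the perimeter fractions P (perinuclear), F (focal)
and O~obs~ (both). Under independent placement, the multiplication rule gives
the prediction O~pred~ = P × F. The cohort statistic is a one-sample t test
of the per-fiber differences O~pred~ − O~obs~ against zero, one-tailed in the
direction "observed exceeds predicted" (differences below zero); the
direction can be flipped or made two-sided. Cohort aggregates of P and F are
reported both perimeter-length-weighted (the default headline, equivalent to
classifying the concatenated cohort perimeter) and as unweighted means of
per-fiber fractions, and both mean(P)·mean(F) and mean(P·F) are emitted,
since the two aggregations differ in general.

Degenerate cohorts are flagged rather than raised: all-zero differences give
t = 0 and one-tailed p = 0.5 (exactly chance); constant nonzero differences
give p = 1 with a warning.

## The synthetic cohort generator

The generator exists so that every stage can be exercised end-to-end against
known ground truth; it emulates the geometry of the profiled study cohort,
not microscope physics (no PSF, vignetting or shot noise — so passing tests
demonstrate algorithmic correctness, not robustness to every real-world
artefact).

- **Fiber shape**: a perturbed circle (radius default 60 px ± 15% across
  fibers, low-order sinusoidal radial perturbation, 72 vertices) — irregular
  but simple and roughly convex, as muscle cross-sections are.
- **Nuclei**: 1–5 per fiber, uniform on the perimeter, rendered as 2-D
  Gaussian DAPI blobs (σ = 5 px, peak 600 above background) centered on the
  boundary.
- **Foci**: at most one per fiber by default (the study cohort had 75 foci
  in 74 fibers); a contiguous arc covering `focus_arc_fraction = 0.2` of the
  perimeter (matching the cohort's 20.0% focal fraction) affecting a
  subsarcolemmal band of depth 10 px. Inside the band SDHA is multiplied by
  3.3 (the mean focal elevation of the mass marker) and MTCOI by 0.1.
  `enrichment_rho` is the probability that a focus is seeded at a nucleus:
  1 reproduces the perinuclear-origin condition, 0 the independence null.
- **Signal model**: per-channel additive background (defaults 40/30/30) and
  Gaussian noise (default SD 5), rounded to integers and clipped to a 16-bit
  range.

`annotate_from_truth()` converts ground truth directly into arc-domain
annotations, attributing to each nucleus a perinuclear arc of half-width
0.04 of the perimeter — with 1–5 nuclei this puts the cohort perinuclear
fraction near the study's 26.2%. This route skips rendering and detection and
is used for large calibration studies of the overlap statistic (hundreds of
cohorts in seconds), where the quantity under test is placement geometry.
Detection fidelity itself is validated on rendered images: on noise-free
cohorts the detected focal masks reach Jaccard ≥ 0.9 against truth arcs and
every nucleus yields a perinuclear run containing its true position.

Calibration and power, as measured by the test suite under these defaults:
across 200 simulated cohorts of 74 fibers with `enrichment_rho = 0`, the
one-tailed test at α = 0.05 rejects at close to the nominal rate (the suite
requires 2–10%); with `enrichment_rho = 1`, all foci overlap a detected
perinuclear run and the cohort p value is far below 0.001.

## Triplex qPCR quantification

Cq values follow the log-linear model Cq = b + m·log10(copies). Standard
curves are fitted per target by least squares on the plasmid dilution series;
amplification efficiency is 10^(−1/m) − 1 and a plate passes QC when
efficiency lies in 95–100%. The upper bound carries a 1e-4 tolerance so that
the canonical perfect-doubling slope −3.3219 (a rounded −1/log10 2) counts as
exactly 100%; the lower bound is strict. A curve at true 100% efficiency
fitted from noisy replicates can land fractionally above the bound — that is
the gate working as specified, and `quantify_copies(..., override = TRUE)`
is the explicit escape hatch when ground truth is known good.

Replicate Cq values are averaged *before* the exponential transform (the
documented default; `per_replicate = TRUE` averages copies instead). Copies
are 10^((Cq − b)/m); a well with no amplification (sentinel `NA`) is 0
copies. The deletion level is (1 − ND4/ND1) × 100 on a 0–100 scale, clipped
below at 0 (negative raw values can arise from noise or from rare deletions
encompassing ND1) and above at 100; ND1 = 0 is undefined and flagged. The
D-Loop/ND1 ratio is reported with a flag when it exceeds `tolerance_fold = 2`
in ND1-intact regions (guarding against triple-stranded D-Loop inflating
copy estimates). Copy numbers are per-region densities: compared regions are
dissected at identical size, so no area normalisation is applied (an area
column is accepted but optional).

The NTC gate requires *every* region of a fiber group (focus plus its
matched regions) to sit at least `ntc_margin_cycles = 3` cycles below the
ND1 no-template control; one failing region excludes the whole group from
paired analyses, and exclusions are listed in the QC report. The elimination
rate is an emergent property of a dataset, never a constant.

`paired_region_analysis()` compares each focus to the mean of its two
matched regions (fold changes in D-Loop and ND1 copies, deletion-level
difference; paired two-tailed t tests) and fully deficient versus positive
whole fibers (unpaired two-tailed t). The plate generator's defaults mirror
the study conditions: 27 focus/matched pairs, mean folds 2.2 (D-Loop) and
2.5 (ND1) with log-normal between-fiber dispersion (SD 0.25 on the log,
mean-preserving), focus deletion ~60% versus ~5% in positive regions,
slope −3.3219, intercept 40, triplicates with 0.1-cycle replicate noise.

## Statistical primitives

`one_sample_t`, `paired_t` and `unpaired_t` wrap `stats::t.test` with
explicit degenerate handling. `binomial_vs_half` is the exact two-sided
binomial test (`stats::binom.test`) — the method behind "Wilson/Brown"
comparisons to 50:50 in common graphing software. `mann_whitney` uses the
exact rank-sum distribution for min(n) ≤ 8 without ties and otherwise a
normal approximation with average-rank tie correction and no continuity
correction; fully tied data returns p = 1 flagged degenerate. No
multiple-testing correction is applied anywhere.

## Numerical choices and degenerate inputs

- Quantiles: linear interpolation (type 7); thresholds compared strictly.
- Modal background: integer histogram bins; ties break to the lowest value;
  an all-saturated raster is an error.
- Polygons: consecutive duplicate vertices are dropped with a warning; fewer
  than 8 distinct vertices or self-intersection is a format error. Pixel
  coordinates are 0-based (x = column, y = row); arc positions are fractions
  of perimeter in [0, 1), origin at the first vertex.
- All cyclic mask operations (runs, minimum run length, intervals) treat the
  last sample as adjacent to the first.
- Zero-variance inputs to any test are flagged `degenerate`, never errors.

## Problem sizes

The test suite exercises the image pipeline on cohorts of 6–74 rendered
fibers (radius ~60 px) and the calibration study on 200 ground-truth-only
cohorts of 74 fibers; these sizes give stable statistics while keeping the
full suite comfortably fast on a single CPU.

## Known limitations

- The automated deficiency rule is a surrogate for expert visual annotation;
  on real images with heterogeneous SDHA elevation its two fiber-median
  thresholds may need tuning, and manual annotations then take precedence.
- Band-averaged profiling assumes the subsarcolemmal signal is within
  `band_depth_px` of the boundary; deeply internalised nuclei or foci are
  outside the model.
- The overlap null is the multiplicative independence rule, not a spatial
  permutation test; it conditions on per-fiber P and F but not on run
  structure.
- The generator does not simulate serial sections, 3-D focus extent, or
  optical artefacts.
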