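# mitofoci

Subcellular analysis of respiratory-chain-deficient foci in skeletal muscle
fibers.

In mtDNA maintenance disorders and in normal ageing, mtDNA deletions clonally
expand inside individual muscle fibers until cytochrome c oxidase (COX,
complex IV — partly mtDNA-encoded) fails. The earliest visible lesion is a
small *focus* of COX deficiency in the subsarcolemmal space of an otherwise
COX-positive fiber. mitofoci is an R package for two questions about such
foci, aimed at groups doing quantitative muscle immunofluorescence and
single-region mtDNA genotyping:

1. **Are foci perinuclear?** Along each fiber's boundary polygon, the package
   builds background-corrected DAPI/SDHA/MTCOI intensity profiles (modal
   background per section, inward band averaging), detects perinuclear
   perimeter domains as corrected DAPI above the cohort 0.85 quantile, and
   classifies COX-deficient perimeter segments (low MTCOI/SDHA ratio with
   SDHA above the fiber median, or manual annotations). For perimeter
   fractions P (perinuclear), F (focal) and O_obs (both), the independence
   null predicts

       O_pred = P × F

   and the cohort statistic is a one-tailed one-sample t test of
   O_pred − O_obs against zero (observed exceeding predicted indicates
   perinuclear enrichment of foci).

2. **What do foci contain?** From triplex D-Loop/MT-ND1/MT-ND4 qPCR plates
   the package fits per-target standard curves (efficiency
   `10^(-1/slope) − 1`, QC gate 95–100%), converts Cq to copies, computes the
   major-arc deletion level

       deletion level = (1 − ND4/ND1) × 100   (clipped to [0, 100])

   applies the no-template-control gate (every region of a fiber group ≥ 3
   cycles below the ND1 NTC) and runs paired focus versus matched-region and
   unpaired whole-fiber comparisons.

A synthetic-data module generates fiber sections (irregular polygon
boundaries, perimeter nuclei as Gaussian DAPI blobs, foci as subsarcolemmal
arcs with 3.3-fold SDHA elevation and 10-fold MTCOI loss) and qPCR plates
from a log-linear Cq model, with full ground truth, so the entire pipeline is
testable end to end. Everything is tibble-in/tibble-out with `tidy()`,
`glance()` and `autoplot()` methods for fitted results.

## Worked example

```r
library(mitofoci)

# --- imaging arm: 74 synthetic fibers with perinuclear foci ---
coh         <- simulate_cohort(cohort_sim_params(n_fibers = 74, seed = 1))
profiles    <- profile_cohort(coh$sections)
annotations <- annotate_cohort(profiles)
overlap_test(overlap_records(annotations))
#> Focus-perinucleus overlap test
#>   fibers: 74, foci: 74 (74 overlapping a perinuclear domain)
#>   mean(O_pred - O_obs) = -0.03268
#>   t = -12.43 on 73 df, one-sided (less) p = 5.41e-20
```

Every simulated focus was seeded at a nucleus (`enrichment_rho = 1`), and the
pipeline recovers that: all 74 detected foci overlap a detected perinuclear
domain, and the observed overlap exceeds the independence prediction P × F by
0.033 of the perimeter on average — decisively below zero (p ≈ 5e-20). With
`enrichment_rho = 0` the same test is calibrated (≈ 5% rejections at
α = 0.05; see the test suite).

```r
# --- qPCR arm: 27 focus/matched-region pairs ---
truth <- simulate_qpcr_truth(n_fibers = 27, seed = 2)   # mean folds 2.2 / 2.5
plate <- simulate_qpcr_plate(truth, qpcr_sim_params(seed = 3))
quant <- quantify_plate(plate, override_qc = TRUE)
glance(quant$curves$ND1)
#> # A tibble: 1 × 7
#>   target slope intercept r_squared efficiency qc_pass n_points
#>   <chr>  <dbl>     <dbl>     <dbl>      <dbl> <lgl>      <int>
#> 1 ND1    -3.32      40.0     1.000      0.999 TRUE           6

paired_region_analysis(quant)
#> Paired subcellular qPCR analysis: 27 focus/matched pairs
#>   mean D-Loop fold 2.23 (range 1.2-3.9), mean ND1 fold 2.49 (range 1.3-4.3)
#>   dloop_copies: paired t = 9.06, p = 1.58e-09
#>   nd1_copies: paired t = 9.49, p = 6.24e-10
#>   deletion_level: paired t = 24.9, p = 1.18e-19
```

The plate was simulated with true mean focal elevations of 2.2-fold (D-Loop)
and 2.5-fold (ND1) over matched COX-positive regions; the quantification
recovers 2.23 and 2.49 with decisive paired tests — copy number and deletion
level are jointly elevated in foci.

`autoplot()` on the overlap result gives the predicted-minus-observed
histogram, on a standard curve the dilution fit, on the paired analysis the
per-fiber fold lines; `plot_perimeter_profile()` draws a fiber's profile with
its annotated domains.

A command-line wrapper (`inst/scripts/mitofoci`) exposes
`simulate` / `run` / `report` subcommands over the same functions; see
`vignettes/mitofoci-methods.Rmd` for the model, parameter and calibration
details.

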