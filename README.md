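# sodiumap

Quantitative sodium (²³Na) MRI mapping and glioma biomarker statistics.

Total tissue sodium concentration (TSC) rises progressively from normal
brain tissue through peritumoral edema and contrast-enhancing tumor to
central necrosis, and the median TSC of the whole tumor volume
discriminates glioblastoma from lower-grade glioma and reflects IDH
mutation status. sodiumap implements the full analysis chain needed to get
from sodium-weighted magnitude images to those biomarker statistics:

* **B1 mapping** by the double-angle method,
  α̂(x) = arccos(S₂ₐ / 2Sₐ), f(x) = α̂/α_nom, with reciprocity-based
  receive correction S_corr = Sₐ·sin α_nom / (f·sin(f·α_nom));
* **absolute quantification** via a two-point calibration line through
  external NaCl reference vials (0.3% / 0.6% w/v → 51.33 / 102.67 mM);
* **ROI statistics** with nawm slice-ROI merging, center-out overlap
  repair, nearest-neighbour mask resampling, whole-tumor fusion
  (gdce ∪ edema, minus necrosis and resection cavity), and normalization
  to nawm;
* **edema hotspot detection**: 26-connected components of edema voxels
  above the per-patient mean + 2 SD window, with a minimum size and a
  gdce-adjacency exclusion rule;
* the **statistical battery**: pairwise paired t-tests between tissue
  classes, Mann–Whitney U group comparisons, Holm–Bonferroni step-down
  correction over one family, ROC analysis with Youden cut-offs, DeLong
  AUC CIs, stratified-bootstrap sensitivity/specificity CIs,
  precision-recall curves, and volume–concentration Pearson correlation;
* a **synthetic phantom and cohort generator** (nested-ellipsoid brain
  phantom with reference vials, smooth B1 field, Rician noise; cohorts
  matched to published group medians/IQRs) so the entire pipeline is
  testable end to end without patient data.

Results are tibbles throughout; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

The default configuration simulates a 64³ phantom at (3 mm)³ with
compartment ground truths nawm 37.84, edema 54.69, gdce 61.72 and
necrosis 81.88 mM, a birdcage-like B1 bump, and Rician noise at nawm
SNR 20, then runs the full correction–calibration chain:

```r
library(sodiumap)
res <- run_pipeline(default_config())
res$region_stats
#>     region n_voxels volume_ml   mean    sd median
#> 1     nawm    37145  1002.915  38.08 1.585  38.07
#> 2    edema     2444    65.988  54.85 1.517  54.81
#> 3     gdce      509    13.743  61.76 1.562  61.74
#> 4 necrosis       78     2.106  81.79 1.653  81.66
#> 5  vial_lo      320     8.640  51.46 1.846  51.35
#> 6  vial_hi      320     8.640 102.62 1.714 102.57
```

The recovered compartment means sit within a fraction of a millimolar of
the ground truth despite the spatially varying transmit field, and the
successive increase nawm < edema < gdce < necrosis is preserved. The
calibration line and hotspot summary print their own QC:

```r
res$calibration
#> <na_calibration> mM = 1.153 * S + 0.1455
#>   vials: 44.41 a.u. -> 51.33 mM (n=72), 88.95 a.u. -> 102.7 mM (n=72)
res$hotspots
#> <na_hotspots> window [51.82, 57.88] mM; 43 component(s), 0 retained; patient negative
```

Cohort-level biomarker analysis on a synthetic 28-patient cohort matched
to the published grade groups (GBM n = 21, median 54.18 mM; non-GBM
n = 7, median 66.73 mM):

```r
gs <- glioma_group_specs()
co <- simulate_cohort(gs[gs$comparison == "grade", ], seed = 1)
roc <- roc_analysis(co$whole_tumor_median, co$group, "non_gbm", seed = 1)
roc
#> <na_roc> positive = 'non_gbm' (n=7 vs n=21)
#>   AUC 0.857 (95% CI 0.707-1.000), AUPRC 0.703
#>   Youden cut-off 65.12: sens 0.71 (0.29-1.00), spec 0.90 (0.76-1.00)
```

A single simulated cohort lands near the published discrimination (AUC
0.89, cut-off 60.39 mM); averaging over many cohorts recovers it closely
(see below). `holm_correct()` applied to the 11 raw p-values reported for
this analysis reproduces the published corrected values exactly.

See the methods vignette
(`vignettes/sodium-quantification-methods.Rmd`) for the model,
assumptions, and every numerical choice.

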