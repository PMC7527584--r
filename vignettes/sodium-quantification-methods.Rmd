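---
title: "Quantitative sodium MRI mapping and glioma biomarker statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative sodium MRI mapping and glioma biomarker statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodiumap)
```

## The problem

Total tissue sodium concentration (TSC) measured by sodium (^23^Na) MRI is
an emerging quantitative biomarker in neuro-oncology: sodium homeostasis is
disturbed early in tumor tissue, and TSC rises progressively from
normal-appearing white matter (nawm) through peritumoral edema and the
contrast-enhancing tumor rim to central necrosis. At ultra-high field (7 T),
TSC inside the whole tumor volume discriminates glioblastoma from
lower-grade glioma and carries information about IDH mutation status.

Turning a sodium-weighted magnitude image (arbitrary units) into an
absolute concentration map (mM) requires two corrections and one
calibration:

1. **Transmit-field (B1) estimation** — the flip angle actually achieved
   varies across the head. sodiumap uses the double-angle method: with
   acquisitions at nominal flips $\alpha$ and $2\alpha$ and full
   longitudinal relaxation,
   $\hat\alpha(x) = \arccos\!\left(\frac{S_{2\alpha}(x)}{2\,S_\alpha(x)}\right)$,
   and the relative field is $f(x) = \hat\alpha(x)/\alpha_{nom}$.
2. **Transmit/receive correction** — for a birdcage coil the principle of
   reciprocity equates receive sensitivity with the transmit field, so the
   corrected signal is
   $S_{corr} = S_\alpha \cdot \sin\alpha_{nom} \,/\, \big(f \sin(f\,\alpha_{nom})\big)$:
   one factor of $f$ removes receive weighting, the sine ratio removes the
   flip-angle weighting.
3. **Two-point vial calibration** — two external NaCl reference vials
   (0.3% and 0.6% w/v, i.e. 51.33 and 102.67 mM assuming complete
   dissociation at 58.44 g/mol) define the affine map from corrected
   signal to mM. With exactly two references the interpolating line is the
   unique fit; the intercept is kept to absorb offset-like bias.

Because no patient images accompany the study this package emulates, the
entire chain is exercised on a synthetic compartmental phantom and on
synthetic patient cohorts, both first-class, tested components.

## The signal model and its assumptions

`simulate_signal()` implements
$S(\alpha_{nom}) = \kappa\, C(x)\, f(x) \sin\!\big(f(x)\,\alpha_{nom}\big)$
with global gain $\kappa$ and concentration $C$. Assumptions:

* **Full relaxation.** TR = 160 ms is long against sodium T1 (~30–40 ms
  in tissue), so no T1 weighting is modelled; TE = 0.35 ms makes T2*
  decay negligible. Neither correction is applied in the quantification
  either, so the forward and inverse models are consistent.
* **Monoexponential tissue behaviour.** The biexponential T2* decay of
  sodium and any relaxation difference between agarose-free vials and
  tissue are ignored; vials are treated exactly like tissue. This is a
  deliberate simplification — the quantification chain inverts the model
  it simulates, which is what a round-trip validation needs, but absolute
  in-vivo accuracy in real data would also depend on these terms.
* **Rician noise.** Magnitude images of complex Gaussian data are Rician;
  noise is applied independently per voxel and per acquisition. The
  default level is set via `sigma_for_snr()` so that nawm SNR is 20, a
  typical value for (3 mm)^3 sodium imaging.

## The phantom and the cohort generator

`generate_phantom()` builds a brain ellipsoid of nawm containing strictly
nested tumor ellipsoids (necrosis ⊂ gdce ⊂ edema) plus two cylindrical
vials outside the brain, on a 64^3 grid of (3 mm)^3 voxels by default.
Compartment ground truths default to the reference values returned by
`sodium_reference_values()` (nawm 37.84, edema 54.69, gdce 61.72, necrosis
81.88 mM). The geometry guarantees the volume ordering edema > gdce >
necrosis and vials of several hundred voxels so vial means are stable; the
tumor centre is jittered by up to one voxel per seed so replicate phantoms
are not voxel-identical. What the phantom does **not** emulate: realistic
anatomy, partial-volume mixing at boundaries (truth is piecewise
constant), spatially correlated reconstruction noise, registration error.
Passing round-trip tests therefore demonstrates correctness of the
estimators under the stated model, not in-vivo accuracy.

The B1 field is a baseline-plus-Gaussian-bump profile (default range
roughly [0.9, 1.15], bounds [0.7, 1.25]) — the smooth centre-bright shape
typical of a birdcage coil at 7 T.

`simulate_cohort()` draws per-patient whole-tumor medians from normal
distributions matched to published group summaries: mean = group median,
sd = IQR width / 1.349, truncated at zero. Median/IQR are the only
summaries available for those groups, and a median/IQR-matched normal is
the minimal assumption; a log-normal alternative matched the same way is
available (`dist = "lognormal"`), and the data at n = 28 cannot
distinguish the two. Region medians are generated from the compartment
means/SDs with a shared patient-level random effect (`region_effect`,
default 0.5 of the variance) so that paired region tests see realistic
within-patient correlation; compartment missingness follows the study
rates (22/28 patients with a contrast-enhancing component, 9/28 with
necrosis, necrotic patients a subset of enhancing ones).

## Numerical choices

* **arccos domain.** The double-angle ratio is clamped to
  $[\varepsilon, 1-\varepsilon]$ ($\varepsilon = 10^{-6}$); voxels outside
  the domain or below the SNR floor are marked invalid and pass through
  correction unchanged (treated as $f = 1$) rather than becoming NaN, so
  ROI statistics never silently shrink. An actual flip reaching 180°
  invalidates the voxel (sine sign ambiguity).
* **B1 smoothing.** `fit_double_angle(smooth_mm =)` optionally applies a
  validity-weighted Gaussian filter. Default off. At nawm SNR 20 the raw
  voxelwise error is median |f − f_true| ≈ 0.02–0.03 (exactly what error
  propagation through arccos predicts); smoothing at 6 mm, well below the
  coil scale, brings it under 0.01 without measurable bias on noiseless
  data. The compartment means recovered by the pipeline average over
  thousands of voxels, so the default pipeline does not need smoothing.
* **Vial erosion.** Vial masks are eroded by one voxel (6-neighbourhood)
  before averaging, the standard guard against edge partial volume, and
  skipped automatically if erosion would leave fewer than 10 voxels.
* **Negative concentrations** (possible under noise) are floored at zero
  and counted (`floor_negative = FALSE` retains them).
* **Mask resampling** is nearest-neighbour, keeping labels categorical.
  Separate compartment masks are composed with centre-out precedence
  (necrosis over gdce over edema) and the number of reassigned voxels is
  reported; a nawm reference ROI overlapping tumor is rejected outright.
* **Hotspot detection.** The window is mean ± 2 SD over the patient's
  edema; voxels strictly above the upper frame (so a constant region
  yields nothing; an edema whose SD is at floating-point rounding level is
  treated as constant) are grouped with 26-connectivity; components under
  5 voxels are dropped, and a component whose fraction of voxels within
  one voxel of the enhancing region exceeds 0.25 is excluded. The
  adjacency rule is our deterministic operationalisation of the
  qualitative "not adjacent to the enhancing border" criterion — the
  threshold, connectivity and minimum size are all configurable. With
  independent voxel noise at SNR 20 and a ~2400-voxel edema, the default
  detector flags about 29% of noise-only patients (the rate is recorded
  as a regression fixture in the tests); independent noise is the worst
  case for spurious small clusters — reconstruction smoothing correlates
  real noise — and in practice the criterion is paired with qualitative
  review. Raising `min_size` to 10 brings the noise-only rate under 10%.
* **Youden cut-offs** are reported as midpoints between adjacent observed
  values (the convention of standard ROC tooling); AUC is computed by the
  rank form of the Mann–Whitney statistic and asserted against the
  trapezoid of the empirical curve, the DeLong method gives the AUC CI,
  and sensitivity/specificity CIs come from a 2000-replicate stratified
  bootstrap (percentile intervals, fixed seed). The precision-recall area
  uses the average-precision estimator
  $\sum_i (R_i - R_{i-1}) P_i$.
* **Mann–Whitney tests** use the exact null when the combined sample size
  is ≤ 20 and there are no ties, and the tie-corrected normal
  approximation otherwise — the cohort sizes here (28, 24, 14) straddle
  that switch.
* **Holm correction** treats all tests reported together as one family
  (`holm_correct()` wraps the step-down procedure; `family_size` allows a
  family larger than the vector supplied). Correcting every reported
  p-value to one global α of 0.05 in a single 11-test family reproduces
  the published corrected values exactly.
* **Determinism.** Every randomized operation takes an explicit integer
  seed; `run_pipeline()` writes a manifest with the config and MD5
  checksums of all outputs, and floats in CSV outputs are serialized at 6
  significant digits, making re-runs bit-identical.

## Problem sizes used in validation

The test suite validates estimator round trips on 32^3 phantoms (the
geometry scaled to half) and the headline recoveries on the default 64^3
phantom; cohort-level statistics are validated over 1000 simulated
cohorts for AUC/Youden recovery and 200–400 replicates for convergence
and exchangeability properties. These sizes give Monte-Carlo error
comfortably below the tolerances being asserted.

## Worked example

```{r pipeline, eval = FALSE}
res <- run_pipeline(default_config())
res$region_stats
res$hotspots

gs <- glioma_group_specs()
co <- simulate_cohort(gs[gs$comparison == "grade", ], seed = 1)
roc <- roc_analysis(co$whole_tumor_median, co$group, "non_gbm", seed = 1)
glance(roc)
autoplot(roc)
```

## Known limitations

* Piecewise-constant truth means no partial-volume structure; recovered
  compartment means are therefore slightly optimistic relative to real
  tissue with mixed boundary voxels.
* The cohort generator matches group location and spread but not any
  within-patient coupling between whole-tumor median and compartment
  medians beyond the shared random effect.
* Compressed-sensing reconstruction, registration, and manual
  segmentation — everything upstream of reconstructed, co-registered
  volumes — are out of scope; inputs are assumed already on a common
  grid up to voxel-size differences handled by nearest-neighbour
  resampling.
* Intracellular/extracellular sodium separation is not attempted; the
  maps are total sodium concentration.
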