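---
title: "Detecting anterior choroidal artery occlusion on CBV maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting anterior choroidal artery occlusion on CBV maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecbv)
```

## Scope and model

In the rat intraluminal MCAo model, the occluding filament sometimes also
blocks the anterior choroidal artery (AChA). The AChA's own supply is entirely
subcortical, but it anastomoses with MCA branches, so its occlusion removes a
collateral route into the MCA territory and is associated with much larger
infarcts — a plausible mechanism for the dichotomous infarct-volume
distributions this model is known for. `strokecbv` implements the
perfusion-CT procedure that makes the AChA call from cerebral blood volume
(CBV) maps, the histology volumetry it is compared against, and the cohort
statistics that link the two, plus a synthetic generator so that every stage
is exercised by tests with known ground truth.

## The classifier

The AChA call is a two-stage thresholding of a coronal CBV slice
(`classify_achao()`):

1. Voxels with CBV strictly above the large-vessel threshold (default
   10 ml/100 g) are *flagged* as vessels, not deleted: they drop out of every
   mean and count but the map stays grid-complete for display. The exclusion
   runs **first**, because vessel voxels would otherwise inflate the
   hemispheric mean used in stage 2.
2. The mean CBV of the contralateral hemisphere is computed over non-excluded
   voxels; ipsilateral AChA-territory voxels with CBV **greater than or equal
   to** that mean count as preserved signal. If at most `tolerance_voxels`
   (default 0, i.e. strict absence) such voxels exist, the AChA is called
   occluded.

The call uses the caudal slice (−2.4 mm bregma), the only level where the AChA
territory exists in the atlas; the rostral slice is carried for reporting, and
a pooled-slice contralateral mean is available (`pooled_contralateral = TRUE`)
for sensitivity analyses. The "no signal at all" reading of absence is the
strict default and the tolerance is exposed as a count because a voxel
tolerance is a judgment call with no canonical value; 0 is the conservative
choice and is what the zero-noise round-trip tests pin down. The classifier is
a pure function of (maps, atlas, parameters): blinding to outcome holds by
construction and is asserted by tests that permute the generator's truth flags
after maps exist.

A separate illustrative threshold, `predicted_infarct_mask()`, marks brain
voxels with CBV strictly **below** 2 ml/100 g as predicted infarct. The two
boundary conventions deliberately differ: preserved signal is inclusive (≥ the
contralateral mean), predicted infarct is exclusive (< 2), so a voxel exactly
at either boundary is treated as "not abnormal" in both directions.

## The atlas

No digital rat atlas ships with the package; territories are parametric
stand-ins on the imaging grid (default 128×128 voxels at the native in-plane
scale of 50/512 mm ≈ 0.098 mm, 2.4 mm slices at 0 and −2.4 mm bregma; a full
512×512 grid is one `grid_spec()` call away). Each hemisphere is a
half-ellipse; cortex is the outer elliptical shell (normalised radius
> 0.55); the MCA territory is a lateral sector spanning cortex and subcortex;
the AChA territory is a small ventro-medial subcortical blob on the caudal
slice only, kept disjoint from the MCA sector so the two residual-flow
signatures never overlap. Masks are built on one side and mirrored
column-for-column, making the left/right mirror property exact rather than
approximate; laterality is metadata (`laterality_convention`), never inferred
from pixel order, because radiological and neurological display conventions
disagree. The AChA blob's size and position are free parameters with no
published voxel extent; the defaults (~100 voxels at 128×128) were chosen once
as a plausibly small subcortical territory and are exposed in
`build_atlas(shape_params = ...)`.

## The synthetic cohort

`generate_cohort()` encodes the emulated study design: 28 Wistar rats
(300–500 g), occlusion durations permanent/1 h/2 h with group sizes 13/8/7 and
AChA co-occlusion in 7/2/1 animals. Stratum infarct volumes are drawn from
normal distributions truncated at zero — volumes are non-negative, and the
low-mean strata (15.55 mm³, SD 23.38) would otherwise go negative in a quarter
of draws; the truncation raises those strata's realised means, which the tests
acknowledge. The permanent strata use the published summaries
(144.5 ± 11.72 and 42.7 ± 27.62 mm³); per-stratum temporary-group summaries
were never published, so their means are back-calculated from the pooled and
permanent summaries ((18·24.6 − 6·42.7)/12 = 15.55 mm³ and
(10·129.6 − 7·144.5)/3 = 94.83 mm³), with the pooled SD of the matching
occlusion class, and the 1 h and 2 h strata are treated as identical because
the printed data cannot distinguish them. Cortical fractions of the total
volume come from the permanent-group compartment means (0.59 occluded, 0.33
patent), jittered per animal with SD 0.08 and truncated to [0, 1]. Body
weight is uniform and independent of volume, matching the null weight
correlation the analysis is expected to reproduce.

CBV fields (`generate_cbv_maps()`) are built from a baseline of 4 ml/100 g
(typical grey-matter CBV) with voxelwise Gaussian noise (SD 0.5 ml/100 g):
the ipsilateral MCA territory is scaled to a residual fraction 0.3, the
ipsilateral AChA territory to 0.1 when occluded or raised to 1.3× baseline
when patent (choroidal blood volume is conspicuously high on real maps), and
6 vessel voxels per hemisphere per slice are planted at 15 ml/100 g to
exercise the vessel exclusion. Values clamp at zero. At these defaults the
patent/occluded separation at the contralateral-mean threshold is many noise
SDs, so classification accuracy is limited by geometry, not noise — the tests
measure 100% recovery at both zero and default noise over 200 animals.

Histology traces (`generate_infarct_traces()`) place infarct voxels on 8
coronal sections 2 mm apart (positioned so the −0.3 and −2.3 mm probability-
map levels fall on sections), filling each compartment outward from the MCA
territory centroid until the voxel count matches the record's cortical and
subcortical volumes to within half a voxel-volume each. Edema is modelled as
uniform ipsilateral expansion with swelling fraction 0.10 — no swelling
magnitude was published; the value only needs to exercise the correction
formula `corrected = raw × contra/ipsi`, which exactly undoes a uniform
expansion. Note the planted masks match the *record* volumes as raw traced
volumes, so corrected volumes in a pipeline run are the record volumes scaled
by 1/1.1; every scale-free statistic (correlations, standardized β, p-values)
is unaffected, and the round-trip tests compare at the raw scale.

Determinism: every random draw runs in a substream seeded by a deterministic
integer hash of (seed, animal id, stage), so a cohort is reproducible
animal-by-animal — deleting a group does not shift any other animal's draws —
and a full `run_study()` writes bit-identical CSVs for a fixed (config, seed),
with doubles rounded to 6 significant digits at the write boundary.

## Statistics

The inference chain mirrors retrospective cohort practice:

* **Normality**: D'Agostino–Pearson omnibus K², implemented from the
  transformed-moment formulation (D'Agostino's skewness Z, Anscombe–Glynn
  kurtosis Z, K² ~ χ²₂) with population-moment (n-denominator) conventions;
  it requires n ≥ 8 and non-zero variance. Its type-I calibration at α = 0.05
  is property-tested by simulation.
* **Group comparisons** (`run_group_comparisons()`): AChAo vs patent within
  each duration group and pooled, in the fixed order 1 h, 2 h, permanent,
  pooled. A comparison whose smaller cell has fewer than 3 animals is
  summarised but *not analysed* — a deliberate small-cell rule rather than an
  underpowered test. The normality gate defaults to the **group** level: the
  omnibus test is undefined below n = 8, which every within-group cell here
  is, so per-cell gating would be vacuous at these sizes (a per-cell mode
  exists for larger cohorts). A failed or untestable gate flags the
  comparison (`normality_ok`) but the t statistic is still reported — a
  visible flag is more honest than a silent rank-test substitution, and no
  fallback test is part of the procedure. Student's pooled-variance t is the
  default, Welch optional. No multiple-testing correction is applied, and the
  report says so implicitly by listing every comparison.
* **Screening and regression**: candidate predictors (AChAo call, occlusion
  duration, weight) are screened by marginal Pearson correlation at p < 0.10;
  survivors enter an OLS fit on z-scored response and predictors (sample SD,
  n−1 denominator — stated because β values depend on it), giving
  standardized β, t-based p-values and adjusted r². Constant predictors (a
  cohort with no occluded animals) are dropped with a machine-readable
  warning instead of crashing the pipeline. Occlusion duration is coded in
  hours with permanent = 24 (the time to the histology endpoint); the
  original analysis never stated its coding, which is one reason the
  published β = 0.732/0.367, r = 0.58 and adjusted r² = 0.831 are not exactly
  reproducible from printed data (the other being that per-animal data were
  never deposited). The package therefore claims only the qualitative
  hierarchy — β(AChAo) > β(duration) > 0 — which the tests verify in ≥ 95% of
  200 seeded cohorts, alongside the quantitative checks that *are* derivable
  from printed summaries: the pooled point-biserial r ≈ 0.85 at large n and
  the permanent-group pooled t ≈ 8.91 (p < 0.0001).

## Numerical choices and degenerate inputs

Section-to-volume integration is the simple sum (area × spacing), not
trapezoidal — configurable ambition was traded for exact agreement with the
brute-force voxel-count oracle. Probability maps store the exact fraction k/n
(the testable object) next to the 24%-opacity compositing 1 − 0.76^k (the
cosmetic rendering, strictly increasing in k). Threshold boundaries are as
stated above; apportionment of infarct voxels across sections uses
largest-remainder rounding so totals are exact. Degenerate inputs fail loudly
with classed conditions: empty hemispheres or territories
(`strokecbv_geometry_error`), infeasible volumes, empty contralateral ROIs
after exclusion, zero-variance statistics inputs, rank-deficient designs.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the analysis assumes —
group margins, stratum moments, territory-localised hypoperfusion, planted
vessels, uniform edema — not real CT physics: no beam hardening, no partial
volume effects, no deconvolution residuals, no registration error, and
spatially uncorrelated noise. Classifier accuracies measured here are
therefore upper bounds for real data, where territory boundaries blur and the
contralateral mean carries structured noise. Likewise the regression-recovery
rates show the inference chain is wired correctly, not that the biological
effect sizes are as printed. Problem sizes used throughout (128×128 or 64×64
grids, 28-animal cohorts, 200-seed sweeps, 10⁵-draw correlation checks) were
chosen as the smallest sizes at which the checked quantities are stable.

## Limitations

Two coronal levels stand in for whole-brain coverage; the atlas is schematic;
the AChA territory size is a free parameter; permanent-occlusion coding as
24 h is a convention; and the normality gate reports rather than adjudicates.
All of these are exposed as configuration so a lab fitting this pipeline to
real maps can substitute measured geometry and their own conventions.
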