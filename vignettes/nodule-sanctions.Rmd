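---
title: "Simulating and measuring host sanctions in the pea-rhizobium symbiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring host sanctions in the pea-rhizobium symbiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulr)
```

## The scientific problem

Legumes trade carbon for fixed nitrogen with rhizobia housed in root nodules.
Because nodules can be founded by strains that fix nitrogen (Fix+) or cheat
(Fix−), hosts are under selection to *sanction*: to direct resources toward
nodules (or nodule sectors) occupied by cooperative strains.  Since nodule
tissue is built from plant carbon, a nodule's cross-sectional area is a proxy
for host investment.  Sanctions can act at two scales:

* **among nodules** — single-infection Fix+ nodules grow larger than Fix−
  nodules on the same root system;
* **within nodules** — in mixed-infection nodules founded by both strains, the
  Fix+ strain occupies a larger *partial nodule area* than the Fix− strain.

`nodulr` rebuilds the measurement chain for such experiments in a fully
simulated setting: it generates two-channel fluorescent root-mosaic images
with known ground truth, re-implements the automated image analysis that
detects and classifies nodules, computes per-plant sanctions metrics, and runs
clustered resampling inferences.  Every downstream stage is therefore testable
by parameter recovery, with no external data.

## The experimental design being emulated

The simulated experiment is a randomized complete block factorial: 3 pea
accessions (wild, domesticated, and a non-nodulating mutant) x 5 inocula x 3
aphid treatments (none, virus-free aphids, aphids carrying *Pea enation mosaic
virus*), replicated over 6 blocks — 270 plants.  The inocula use reciprocal
fluorophore labeling: 1-strain treatments mix red- and green-labeled copies of
the *same* strain, so any red/green difference in detected size or count is a
marker (detection) effect rather than biology; the two co-inoculation
treatments (`co_A`: red Fix+ / green Fix−; `co_B`: the reverse) swap the
labels so occupant effects can be separated from marker effects.
`marker_balance()` reports these diagnostics and emits the Fix+ marker color
as a model covariate.

## Sanctions metrics

For each co-inoculated plant, with `Z` the mean total area of
single-infection nodules by occupant (among-nodule mode) or the mean partial
area by strain across mixed-infection nodules (within-nodule mode):

$$\mathrm{strictness} = \ln\!\frac{Z_{\mathrm{Fix+}}}{Z_{\mathrm{Fix-}}}$$

Strictness is positive when the host favors the Fix+ strain; values at or
below zero mean no sanctioning (`is_sanctioning()` makes that call, with an
explicit `undefined` state when a plant lacks nodules in a class).  The log
ratio is antisymmetric under strain relabeling and invariant to rescaling all
areas — both properties are enforced by tests.  `Z` uses the arithmetic mean;
a median option exists for diagnostics but is never the default.  Partial-area
means over mixed nodules are unweighted by nodule size; plants with no nodule
in one class yield `NA` strictness and are excluded from strictness
regressions.

## The synthetic-data generator

`effect_config()` holds every generator setting.  Defaults encode the study
conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| `ratio_1strain` | 1.21 | Fix+/Fix− mean single-nodule area, 1-strain arms |
| `ratio_2strain` | 2.03 | same, co-inoculated arms |
| `fix_plus_2strain_boost` | 1.35 | Fix+ mean area, 2-strain vs 1-strain |
| `within_ratio_no_aphid` | 1.39 | Fix+/Fix− partial area in mixed nodules, no aphids |
| `within_ratio_aphid` | 1.0 | same under either aphid treatment |
| `p_mixed` | 0.15 | mixed-infection fraction of nodules (co-inoculated) |
| `p_nonfluorescent` | 0.04 | senescent, darkfield-only nodules |
| `p_touching` | 0.05 | probability a nodule is rendered edge-to-edge with a neighbor |
| `red_green_brightness_factor` | 2 | red-channel intensity relative to green |
| `cfu_r_target` | 0.37 | nodule-area vs logCFU correlation |
| `size_lognormal_sigma` | 0.45 | log-scale spread of nodule areas |
| `base_nodule_area` | 0.15 mm² | Fix− single nodule, 1-strain arm |

The Fix− cross-inoculum multiplier is derived as
`ratio_1strain * fix_plus_2strain_boost / ratio_2strain` (≈ 0.805, a ~20%
size penalty), keeping the four size parameters mutually consistent by
construction.  Choices the underlying experiment leaves open were fixed once,
on distributional grounds:

* **Nodule counts** are negative binomial around accession means (wild plants
  make more, smaller nodules; non-nodulating plants make none); counts in real
  root systems are overdispersed, so a Poisson would understate between-plant
  variance.
* **Nodule areas** are log-normal with multiplicative treatment effects —
  sizes are positive and right-skewed, and the effects being emulated are
  reported as percentages, which compose multiplicatively.
* **Within-nodule splits** are Beta-distributed with mean
  `r`/(1 + `r`) and concentration 20 (`within_split_concentration`); the Beta
  is the natural bounded-fraction family and the concentration sets a
  realistic nodule-to-nodule spread (SD ≈ 0.11) around the mean ratio.
* **Mixed-nodule rendering** draws spatially distinct angular sectors or
  intermingled per-pixel patches with probability 0.5 each, since both
  morphologies occur; per-channel pixel areas match the true partial areas up
  to rasterization/binomial error.
* **Non-fluorescent rate** defaults to 4% of nodules; the source quantity is a
  per-plant median over all nodulated plants, which the per-nodule probability
  approximates.
* **Geometry**: 1024x1024 8-bit frames at 0.01 mm/px, nodules placed along
  simulated root curves (quadratic Beziers) with a uniform fallback for dense
  populations.  All geometry is scale-parameterized; the frame size trades
  realism against desk-scale runtime.
* **logCFU** is linear in nodule area; when `cfu_noise_sd` is `NA` the noise
  is calibrated from the supplied areas so the population correlation equals
  `cfu_r_target`.
* **Virus titer** (arbitrary band-intensity units; only relative effects are
  meaningful) is drawn per inoculum (Fix+ < co-inoculated < Fix−), plus
  `titer_strictness_slope` times the plant's within-nodule strictness for
  co-inoculated plants under PEMV+ aphids.

Aphid exposure erases the *within*-nodule ratio (1.39 → 1.0) but not the
among-nodule effects, so both hypotheses about antagonist-compromised
sanctions can be simulated by moving either ratio independently.

## The detection pipeline

`detect_pipeline()` re-implements a particle-analysis macro over the
fluorescence layers:

1. **Thresholding** — per-channel absolute cutoffs (defaults 60/30 digital
   numbers for red/green), or `"auto"`: Otsu's criterion computed per channel
   after normalizing by the channel's mean brightness, which makes the
   automatic threshold robust to the 2-fold red/green imbalance.
2. **Segmentation** — foreground is the union of the two thresholded
   channels; features are 8-connected components (4-connected background for
   hole detection, the standard duality that avoids topological paradoxes).
   A brute-force flood-fill oracle cross-checks both on small images in the
   test suite.
3. **Hole removal** — enclosed background regions are filled and counted; the
   filter ledger counts them among the initially detected features, as
   particle-analysis tools do, so
   `n_initial = n_holes + n_below_min + n_above_max + n_retained` holds
   exactly on every run.
4. **Size filtering** — features outside [0.05, 12] mm² are dropped.  The
   bounds must be explicit numbers for reproducibility; both are overridable.
5. **Occupancy and classification** — per-feature percent of pixels above
   each channel threshold (channels assessed independently; a pixel may count
   for both); a nodule showing at least 10% of its area in *both* channels is
   `mixed_color`, one channel gives a single-color call, neither gives
   `nonfluorescent`.  The 10% minor-channel cutoff guards against
   bleed-through classifying every nodule as mixed.
6. **Strain assignment** — colors map to strains under the plant's labeling
   scheme; mixed-color nodules on co-inoculated plants split their area in
   proportion to the channel occupancies; non-fluorescent nodules are
   `unknown` and excluded from sanctions.

Touching nodules are *not* split by default: two adjacent single-color
nodules of different colors are deliberately detected as one mixed-color
feature, reproducing a documented artifact of edge-to-edge nodules in real
mosaics.  Because artifact pairs on co-inoculated plants inherit the 2-strain
size ratio, they bias the detected mixed-nodule fraction and the
within-nodule partial-area ratio upward by a few percentage points relative
to the generator's truth — visible in the recovery numbers and left in place
because the artifact is part of what is being emulated.

## Inference

The clustered comparisons are implemented as resampling procedures rather
than mixed-model likelihood-ratio tests: the scientific contrasts and their
clustering structure are preserved while keeping the machinery fully
self-contained.

* `cluster_permutation_contrast()` — the statistic is the difference in
  occupant-class means of *plant-level* means (each plant contributes once
  per class); the null re-shuffles occupant labels among nodules within each
  plant, preserving per-plant class counts and between-plant heterogeneity.
  Two-sided p-values use the add-one rule
  `(1 + #{|null| ≥ |obs|}) / (1 + n_perm)`, ties counted conservatively;
  an `exact = TRUE` mode enumerates all within-plant relabelings for small
  instances.  Type-I error is verified at 500 null replicates in the tests.
* `strictness_titer_association()` — pooled within-group slope of titer on
  strictness after centering both within marker-covariate groups; p-values
  permute strictness within groups.  Both variables are measured responses,
  so the slope is an association, not a causal effect.  Block structure is
  not stratified over; at ~20 informative plants, finer stratification would
  leave too few permutations per stratum.
* `pearson_cor()` and `holm_adjust()` wrap the standard product-moment test
  and step-down Holm correction behind validated interfaces.

Default settings: two-sided tests, `n_perm = 9999` in direct calls (999 in
`full_run()` for runtime), alpha 0.05.

## Numerical and degenerate-input choices

Undefined strictness is `NA` in memory and an empty CSV field on disk, never
a sentinel; constant inputs to correlations or associations raise errors
rather than returning `NaN`; degenerate thresholds (everything foreground)
are refused; ledger balances are asserted, not assumed.  All randomness flows
from explicit seeds; identical seed and configuration reproduce identical
tables and pixel-identical images (the TIFF writer cannot persist description
tags, so channel order and pixel scale live in a YAML sidecar next to each
image).

## What the tests do and do not show

The acceptance suite recovers the configured effects end to end with
problem sizes chosen for a single-CPU desk run: 60 mosaics (20-150 nodules
each) for the detection-validation correlations, 40 plants per inoculation
arm for each effect-size recovery, 500 nodules for the CFU correlation, and
500 null replicates at 999 permutations for the type-I calibration.  Passing
these tests shows the pipeline is internally consistent and unbiased (up to
the documented touching-nodule artifact) **on data the generator can
produce**.  Real mosaics differ in ways the generator does not emulate:
uneven illumination and autofluorescence, out-of-focus or partially buried
nodules, stitching seams, non-circular nodule outlines, and spatially
correlated root backgrounds.  Recovery here therefore bounds pipeline error
from below, not observer error on real images.

## Known limitations

* Cross-sectional area is a rough proxy for the three-dimensional volume a
  strain occupies; no 3-D reconstruction is attempted.
* Touching nodules are merged by default (see above); watershed splitting is
  available but off, to match the emulated analysis.
* The permutation analogs do not reproduce mixed-model chi-square statistics
  or degrees of freedom; they answer the same scientific questions with
  different machinery.
* PEMV titer is an arbitrary-unit band intensity; only relative effects and
  associations are meaningful.
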