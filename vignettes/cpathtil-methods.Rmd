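---
title: "Scoring tumour-infiltrating lymphocytes in the DCIS microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tumour-infiltrating lymphocytes in the DCIS microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biomarker

Ductal carcinoma in situ (DCIS) is stage-0 breast cancer confined within
the duct. The density of tumour-infiltrating lymphocytes (TILs) in the
stroma surrounding the ducts is a candidate prognostic marker for
ipsilateral breast events (IBE) — either in-situ recurrence (DCIS-IBE) or
invasive progression (I-IBE) — and a candidate predictor of radiotherapy
benefit. `cpathtil` implements a computational-pathology version of this
biomarker:

1. The **periductal microenvironment** of a patient's annotated DCIS
   regions is the set of pixels within a fixed radius (default 250 µm, with
   200 µm as the standard sensitivity setting) of the rasterised DCIS
   mask, excluding all annotated epithelium.
2. The **stroma** inside that ring is partitioned into square patches
   (default 100 µm), and each patch receives a TIL fraction: the
   lymphocyte-nucleus area divided by the patch's stromal area.
3. The **CPath TIL score** is ten times the stroma-area-weighted mean of
   the patch fractions. On this ×10 scale clinically reported cohort
   medians are of order 0.7.
4. Scores are **dichotomised** at the cohort median (score ≥ median →
   CPath TIL-high; score < median → CPath TIL-low), and the frozen
   threshold can be reapplied to new patients.
5. The resulting categories are evaluated with Kaplan–Meier estimates,
   cause-specific Cox models (including a radiotherapy × TIL interaction
   tested by likelihood ratio), Δχ² model comparison, and conditional
   logistic regression on age- and treatment-matched nested case–control
   sets.

## Imaging chain and its assumptions

Trial image archives are not distributable, and the original
biomarker used pretrained neural networks for nuclei segmentation and
patch TIL classification. `cpathtil` instead specifies a fully
deterministic classical chain, which makes every stage auditable and lets
a ground-truthed generator close the loop; published reproducibility
analyses of this biomarker family report high rank agreement (Spearman
ρ ≈ 0.95) when the segmentation algorithm is swapped, which motivates
treating the segmentation backend as replaceable.

* **Optical density.** `rgb_to_od()` maps 8-bit RGB to
  OD = −log10((I+1)/256), so absorbances add across stains
  (Beer–Lambert).
* **Stain deconvolution.** `deconvolve_stains()` projects each pixel's OD
  vector onto unit hematoxylin/eosin vectors in the Ruifrok–Johnston
  convention by least squares, clipping negative loadings at zero.
  Near-collinear stain matrices (condition number > 1e6) are rejected.
* **Nuclei.** `segment_nuclei()` applies an Otsu threshold to the
  hematoxylin channel, opens with a 1 µm disk, and splits touching blobs
  by a watershed on the Euclidean distance transform seeded at maxima at
  least 3 µm apart (the lymphocyte diameter floor). Components under
  10 µm² are dropped. Circularity (4πA/P²) uses a perimeter estimated
  from the city-block exposed-edge count scaled by π/4 — exact for
  digital disks, where boundary-pixel counting is badly biased on
  nuclei a few pixels across — and is clamped to [0, 1.05] to absorb
  discretisation.
* **Lymphocyte rule.** A nucleus is a lymphocyte iff area ∈ [15, 80] µm²,
  circularity ≥ 0.80, and mean hematoxylin OD ≥ 0.40 (all inclusive);
  small, round, hyperchromatic. All thresholds live in
  `lymphocyte_rule()` and are configurable.
* **Stroma.** Tissue is HSV saturation ≥ 0.05 and value ≤ 0.95 (robust to
  faint eosin); the DCIS mask and dilated non-lymphocyte nuclei inside
  the annotation are subtracted.

Geometry decisions worth stating: the ring uses the half-open rule
0 < d ≤ r measured by Euclidean distance transform from the rasterised
annotation (so DCIS pixels are never part of their own microenvironment);
rings of multiple ducts merge by union so overlapping stroma is counted
once; all annotated epithelium is excluded from every ring. The patch
grid is anchored at the image origin with half-open boxes, which makes
patch membership deterministic and order-independent; patches without
ring stroma are dropped; a lymphocyte belongs to the patch containing its
centroid. Patients with under 0.01 mm² of ring stroma are flagged
non-evaluable rather than scored.

Two genuinely open choices were fixed as follows. The patch size is not
specified in published descriptions ("small image patches"); the default
is 100 µm, large enough for stable fractions and comparable to common
TIL-map patching. The patch average could be unweighted or
pixel-weighted; the default weights patches by stromal area, because an
unweighted mean over-weights sliver patches at ring edges (an unweighted
option is retained). Likewise the patch "TIL percentage" of the original
CNN is operationalised as the lymphocyte area fraction of stroma, the
closest deterministic analogue; a count-per-mm² definition is available
via configuration.

## The synthetic histology generator

`generate_tile()` renders calibrated tiles from a `tile_spec()`: glass
(near-white), eosin-dominant stroma, duct epithelium with clustered
ellipsoidal nuclei (9–14 µm major axis, hematoxylin OD 0.35), and
lymphocytes as 6–9 µm hematoxylin-dominant disks (OD 0.85)
Poisson-scattered over stroma at a planted density. Rendering mixes OD
with the same published stain vectors the analyser assumes, adds Gaussian
OD noise (σ = 0.02), applies a 1 px blur, and converts to 8-bit RGB — so
deconvolution is exercised by construction and the planted truth
(masks, centroids, counts, densities, area fractions) is exact.

What the generator does *not* emulate: nuclear texture and chromatin,
stain variation across scanners, tissue folds, out-of-focus regions, and
spatially structured inflammation. Passing tests on synthetic tiles
therefore demonstrate that the geometry, calibration and statistics of
the pipeline are correct — not that the segmentation chain matches
pathologist-grade performance on real slides.

## The synthetic cohort generator

`simulate_cohort()` draws covariates (age ~ N(57.4, 6.0) years, tumour
size ~ N(15.6, 8.5) mm truncated positive, binary TIL / HER2 / treatment
indicators; ordinal grade and necrosis associated with TIL category) and
two latent exponential cause-specific event times with rates
λ_c·exp(xᵀβ_c), including a planted radiotherapy × TIL log-hazard
interaction; the earliest latent time before administrative censoring
(default 12.7 years) is observed with its cause. Default baseline
hazards (0.0115/yr in-situ, 0.0072/yr invasive) give roughly 20% events
by the censoring horizon, matching the scale of the motivating trial
cohort. An exponential baseline is sufficient because Cox estimation is
invariant to the baseline; the default interaction pattern plants the
effect on the in-situ cause and none on the invasive cause.

## Statistical toolkit

Standard machinery is delegated to `survival` and `stats`: Cox fits use
Efron ties and Wald intervals, with the model χ² from the likelihood
ratio against the null; Δχ² comparisons require nested covariate sets on
identical observations; the interaction p uses the LRT of the product
term (Wald optional), with subgroup HRs displayed from stratified fits.
Matching follows the nested case–control design: 1:2, identical
treatment allocation, age within ±7 years, control follow-up at least
the case's event time, seeded sampling without replacement among
eligibles (the design does not specify selection among eligibles, so it
is randomised reproducibly). Conditional logistic regression maximises
the exact per-set conditional likelihood. Rank tests enumerate exactly
for total n ≤ 10 and otherwise use large-sample approximations with
mid-rank tie corrections; the Mann–Whitney approximation omits the
continuity correction so that the two-group Kruskal–Wallis χ² p agrees
with it identically. Missing data are handled complete-case per model
with the model n recorded; all p values are two-sided at α = 0.05.

Competing first events are analysed as cause-specific hazards (the
competing type censored at its time): only first events are modelled,
and no subdistribution (Fine–Gray) model is attempted.

## Numerical conventions

Coordinates are 0-based and continuous: pixel (i, j) (1-based indices)
spans [j−1, j) × [i−1, i) with centre (j−0.5, i−0.5); polygons are (x, y)
in GeoJSON order. A pixel belongs to a polygon iff its centre is inside
under the even-odd rule; self-intersecting polygons are rejected.
Dichotomisation uses the midpoint median for even cohorts and the ≥ rule
at the threshold. Degenerate inputs fail loudly: empty DCIS masks
(patient non-evaluable), patches under 2 px, all-non-evaluable score
sets, concordant-only matched sets, constant covariates, and separated
Cox fits all raise descriptive errors.

## Problem sizes used in validation

The packaged tests and the acceptance script keep runs desk-sized: score
calibration uses 60 tiles of 600 px at 1 µm/px across planted densities
0–400/mm²; radius sensitivity uses 30 such tiles; Cox recovery uses 200
replicates of n = 1000; interaction error rates use 200 null replicates
(n = 1000) and 100 alternative replicates (n = 4000); the ring-geometry
oracle uses a 720² image. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances.

## Known limitations

* The classical lymphocyte classifier is tuned to the generator's
  morphology; on real H&E it would need threshold recalibration and
  likely colour normalisation (deliberately out of scope).
* Scores from whole slides must currently be computed tile-wise from
  annotated regions; pyramidal WSI formats are not parsed.
* The matched-set builder is greedy per case and does not optimise the
  global matching.
* Spatial TIL organisation (touching vs distant lymphocytes, subtypes)
  is not measured.
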