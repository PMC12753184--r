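# cpathtil

Computational-pathology scoring of tumour-infiltrating lymphocytes (TILs)
in the periductal microenvironment of ductal carcinoma in situ (DCIS),
with the survival-analysis toolkit needed to evaluate the resulting
biomarker in a clinical-trial cohort.

## Who this is for

Researchers studying immune infiltration in DCIS who want a fully
specified, deterministic alternative to CNN-based TIL pipelines: every
stage — stain deconvolution, nuclei segmentation, microenvironment
geometry, patch scoring, dichotomisation, and outcome modelling — is an
ordinary documented R function, and both an image generator and a cohort
simulator with exact ground truth are included so the whole chain can be
validated without access to trial data.

## The biomarker

For a patient with annotated DCIS regions on a calibrated H&E image:

* the **periductal microenvironment** is the stromal ring within radius
  *r* = 250 µm of the DCIS boundary (Euclidean distance transform of the
  rasterised annotation, all epithelium excluded, rings of multiple
  ducts merged by union);
* the ring stroma is partitioned into 100 µm patches; patch *i* gets a
  TIL fraction *p<sub>i</sub>* = lymphocyte-nucleus area / stromal area;
* the **CPath TIL score** is
  *S* = 10 · Σ *w<sub>i</sub> p<sub>i</sub>* / Σ *w<sub>i</sub>*, with
  *w<sub>i</sub>* the patch stromal area;
* patients are **CPath TIL-high** iff *S* ≥ the cohort median (the frozen
  threshold is reusable on new patients).

Prognosis and treatment interaction are assessed with Kaplan–Meier
estimates, cause-specific Cox models (Efron ties; model χ² by likelihood
ratio; radiotherapy × TIL product term tested by LRT), Δχ² comparison of
nested models, and conditional logistic regression on 1:2 age- and
treatment-matched nested case–control sets.

Lymphocytes are identified by a classical morphometric rule (area
15–80 µm², circularity ≥ 0.80, mean hematoxylin OD ≥ 0.40) after
Ruifrok–Johnston stain deconvolution, Otsu thresholding and
distance-transform watershed; see the methods vignette
(`vignettes/cpathtil-methods.Rmd`) for every assumption and default.

## Worked example

Score a synthetic tile with a known planted lymphocyte density, then
evaluate a simulated cohort:

```r
library(cpathtil)

spec <- fixture_tile_spec(600, 1, density = 150, seed = 42)  # 150 TILs/mm^2
tile <- generate_tile(spec)
score_tile(tile$image, spec$annotations, run_config(), patient_id = "demo")
#>   patient_id n_patches stroma_mm2 raw_density      score radius_um evaluable
#> 1       demo        34   0.274289 0.009679572 0.09679572       250      TRUE
```

The score 0.097 is the ×10-scaled stromal TIL area fraction in the
250 µm ring (34 patches, 0.27 mm² of stroma); the planted truth for this
tile is 0.082 on the same scale.

```r
sim <- simulate_cohort(cohort_sim_spec(2000, seed = 1))
cox_fit(sim$cohort, "IBE", c("category", "tamoxifen", "radiotherapy"))
#> Cox PH fit, outcome IBE: n=2000, events=336, model chi2=118.82 (df 3)
#>   categoryhigh                 HR 1.65 [95% CI 1.32-2.05]; p=7.143e-06
#>   tamoxifen                    HR 0.61 [95% CI 0.49-0.76]; p=1.007e-05
#>   radiotherapy                 HR 0.36 [95% CI 0.29-0.46]; p=5.924e-17

sets <- match_case_control(sim$cohort, ratio = 2, seed = 1)
conditional_logistic(sets, exposure = "category")
#> Matched OR 1.66 [95% CI 1.28-2.16]; p=0.0001395 (336 sets)
```

The TIL-high hazard ratio 1.65 reflects the simulator's planted
cause-specific effects (1.92 for in-situ and 2.42 for invasive
recurrence, diluted by the composite outcome and the planted
radiotherapy interaction); the matched odds ratio tells the same story
free of treatment confounding.

A thin command-line wrapper (`exec/cpathtil`) exposes the same
operations as subcommands: `simulate-images`, `simulate-cohort`,
`score`, `validate`, `sensitivity`.

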