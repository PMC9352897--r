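---
title: "CT body composition: tissue quantification and intermodal agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT body composition: tissue quantification and intermodal agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctbca)
```

## The problem

Routine staging CT already contains the information needed to monitor a
patient's body composition: adipose and muscle tissue have characteristic,
well-separated attenuation on the Hounsfield-unit (HU) scale. Given a CT
volume and a co-registered semantic segmentation of the torso into body
regions (subcutaneous tissue, muscle, abdominal cavity, thoracic cavity,
mediastinum, pericardium, bone), a voxel-level tissue classification yields
two simple ratio biomarkers — the Body Fat Ratio (BFR) and the Skeletal
Muscle Ratio (SMR) — that can be tracked longitudinally without the extra
DXA or BIA exams otherwise used for this purpose. The question such a
pipeline must answer before clinical use is a method-comparison question:
how well do CT-derived ratios agree with the established modalities, overall
and in the subgroups (BMI classes, sex) where systematic divergence is
expected?

`ctbca` implements both halves: the quantification pipeline, and the
agreement analysis (Pearson's r, Lin's concordance correlation coefficient,
Bland–Altman limits of agreement, normality screening), plus a synthetic
phantom and cohort generator that supplies inputs with known ground truth.

## Tissue classification model

A voxel's tissue class is a function of two things: its HU value and the
semantic region it lies in.

* **HU windows** (inclusive, in HU): adipose $[-190, -30]$, muscle
  $[-29, 150]$, air $[-1024, -800]$. These are the established soft-tissue
  thresholds; they are contiguous at integer HU. Simulated or interpolated
  volumes contain non-integer HU, for which the adipose/muscle boundary is
  split at the midpoint $-29.5$ — the least surprising float extension of
  thresholds stated on the integer grid. All windows are configurable
  (`hu_windows()`).
* **Region subclassification**: an adipose-window voxel becomes SAT in the
  subcutaneous region, VAT in the abdominal cavity, IMAT inside muscle, EAT
  inside the pericardium and PAT in the mediastinum outside the pericardium
  (the standard cardiac-fat anatomy: epicardial fat lies within the
  pericardial sac, paracardial fat outside it). A muscle-window voxel counts
  as muscle only in the muscle region. Bone is taken from the bone region
  label directly — there is no reliable single HU window spanning cortical
  and trabecular bone plus marrow, and the upstream segmentation already
  delineates it. Adipose-window voxels in the thoracic cavity or in bone
  (lung fat artefacts, marrow fat) belong to none of the five adipose
  compartments and are left unclassified rather than silently absorbed.
* **Air exclusion**: air-window voxels are removed from the denominator.
  The package defaults to excluding air in *every* region, not only the
  abdominal cavity: air is defined purely by HU, and leaving lung air in the
  denominator would make the ratios depend on how much lung the scan
  happens to cover. A config switch (`air_scope = "abdominal_cavity"`)
  restricts the exclusion for sensitivity analyses.

The biomarkers are then

$$\mathrm{BFR} = 100\,\frac{n_{SAT}+n_{VAT}+n_{IMAT}+n_{EAT}+n_{PAT}}{n_{body}},
\qquad
\mathrm{SMR} = 100\,\frac{n_{muscle}}{n_{body}},$$

with $n_{body}$ = non-background voxels minus excluded air. Both ratios are
invariant under uniform voxel-spacing rescaling; compartment volumes in
litres (count × voxel volume) are reported too, but they inherit the scan's
reconstruction spacing and are flagged as spacing-dependent.

## Agreement statistics

Method comparison uses paired per-subject readings, pairwise-complete per
comparison (a subject missing one modality still contributes to the other
comparisons — method-comparison studies routinely have unequal coverage
across modalities).

* **Pearson's r** with the two-sided t-based non-correlation test measures
  precision (tightness around *some* line). One terminological note: the
  statistic implemented is the product-moment correlation; "rank
  correlation" is occasionally used loosely for it in clinical reports, but
  no rank transform is involved here.
* **Lin's concordance correlation coefficient**
  $$\rho_C = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}$$
  with $n$-denominator moments, per the original 1989 definition (the $n$ vs
  $n-1$ choice matters at small $n$; the original is the citable one).
  $\rho_C$ penalises location and scale shifts, so $|\rho_C| \le |r|$ always,
  with equality exactly when means and variances agree — both facts are
  asserted as property tests. A confidence interval via the Fisher
  $z$-transform with Lin's asymptotic standard error is reported by default
  and can be switched off (`ccc_ci = FALSE`); it is an addition of good
  practice rather than a requirement of the analysis.
* **Bland–Altman**: differences are first-listed minus second-listed method
  (so a CT-vs-reference BFR comparison yields a positive mean difference
  when CT reads higher). Limits of agreement are $\bar d \pm 1.96\,s_d$ with
  the sample SD — the classical convention keeps 1.96 rather than a t
  quantile for the limits, while the CIs use t: the mean's CI via
  $s_d/\sqrt n$ and each limit's CI via the standard error
  $s_d\sqrt{3/n}$.
* **Shapiro–Wilk** (Royston's algorithm, via `stats::shapiro.test`) screens
  each modality × metric × BMI group for the normality the Pearson test
  assumes.

No multiple-testing correction is applied across the comparison grid; the
analysis is estimation-oriented (effect sizes with intervals), and this
choice is deliberate and documented rather than hidden.

Strata are BMI groups on the WHO cut points — half-open intervals
$[18.5, 25)$ healthy, $[25, 30)$ overweight, $\ge 30$ obese, with
underweight ($<18.5$) retained as a label for generality — or sex. A
stratum needs at least 3 complete pairs; smaller strata are skipped with a
warning rather than failing the whole report.

## What the synthetic data emulates

Clinical CT with paired DXA/BIA readings is not shippable; the package
instead generates inputs whose truth is known *by construction*.

**Phantoms** (`generate_phantom()`): a cylindrical torso whose body voxels
are partitioned into tissues at exactly the requested counts
(largest-remainder rounding), arranged as nested shells (subcutaneous fat
outside, then intermuscular fat and muscle, then mediastinal/pericardial
fat, bone, and an abdominal core with visceral fat, air pockets and
nondescript soft tissue). Each voxel's region label is the one its intended
tissue implies, and its HU is drawn uniformly strictly inside the tissue's
window, then perturbed by Gaussian noise *truncated to the window*
(default SD 3 HU, a plausible soft-tissue reconstruction noise). Truncation
is the design point: no noise level can push a voxel across a window
boundary, so quantification must recover the ground-truth counts with zero
error — the phantom is an exact oracle, not an approximate one. A
`voxel_list` layout allows hand-built single-voxel fixtures. What phantoms
do **not** emulate: anatomy, partial-volume mixing at tissue interfaces,
beam-hardening, or segmentation errors of the upstream network — passing
the phantom tests shows the counting and classification arithmetic is
right, not that any segmentation is.

**Cohorts** (`generate_cohort()`): each subject gets a BMI group
(multinomial by default; `stratified_exact` reproduces a fixed design such
as 22/35/17 of a 74-subject study), a BMI uniform within the group range
(obese capped at 40 kg/m² — some upper bound is needed to sample uniformly,
and class-III obesity is rare in the emulated population), sex,
anthropometrics, and latent "true" BFR/SMR values drawn from group-specific
Gaussians. The default group means ± SDs are those of a published
74-patient GEP-NET cohort's CT-derived measurements (BFR 32.43 ± 11.25,
40.36 ± 7.04, 49.79 ± 7.65 %; SMR 27.84 ± 4.90, 26.57 ± 4.19,
23.65 ± 5.17 %). Treating the published group mean ± SD as Gaussian
parameters is a modelling choice — per-subject distributions are not
published. Each modality then observes the latent value through

$$\text{reading} = \text{latent} + \beta_0 + \beta_1 g + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2),\ g \in \{0,1,2\},$$

clipped to $[0,100]$. The CT-derived method is the anchor (identity model):
the latent is defined on its scale. Default reference-modality parameters
are the reported mean differences and dispersions against CT-based
analysis: DXA BFR $\beta_0 = -5.29$, $\sigma = 0.8$; BIA BFR
$\beta_0 = -5.67$, $\sigma = 1.12$; BIA SMR $\beta_0 = +5.68$,
$\sigma = 0.85$; $\beta_1$ defaults to 0 because no per-group slope is
published, but the slope is the mechanism for studying the BMI-dependent
divergence the comparison literature reports. Default missingness mirrors
the emulated design (DXA 7/74, BIA 22/74 absent). Because readings are
clipped at 0 and 100, very wide latent distributions can truncate the error
model near the boundaries; the default parameters keep the mass far from
them.

## Numerical and design choices

* **Degenerate inputs** fail loudly with classed conditions: constant
  vectors for correlation, fewer than 3 complete pairs, an all-background
  volume, a legend missing a code that occurs in the data. Nothing is
  coerced to 0 or silently dropped except the documented pairwise-complete
  deletion.
* **Determinism**: generators take explicit seeds and restore the caller's
  RNG state; the whole simulate → quantify → compare chain writes
  byte-identical files on identical inputs, which the tests assert at the
  md5 level.
* **Exact partition**: target fractions are converted to voxel counts by
  largest-remainder rounding, so the counts always partition the body and
  sum mismatches cannot hide in rounding.
* **Coordinate convention**: CT and label volumes are combined
  voxel-for-voxel with no resampling; shape mismatch is an error, never an
  implicit interpolation. Axis order and spacing stay associated
  component-wise through file round-trips.
* **Problem sizes**: the validation suite uses phantoms up to 48³ voxels,
  100 random ≤16³ volumes against a brute-force per-voxel reference
  classifier, 10⁵-pair Bland–Altman calibration and 5000-subject recovery
  cohorts — sizes at which Monte-Carlo error is far below the effects being
  checked while the whole suite stays interactive.

## Known limitations

* The pipeline consumes an existing semantic segmentation; it neither
  produces one nor models its errors. Dice-level performance of any
  upstream network is out of scope.
* Volumes in litres depend on the reconstruction spacing (e.g. 5 mm
  whole-body protocols); only the ratios are spacing-invariant.
* The cohort simulator's additive-Gaussian error model cannot represent
  proportional bias (slope ≠ 1 in a regression sense) or
  heteroscedasticity within a BMI group; it is sufficient for validating
  the agreement statistics, not a generative model of real modality
  physics.
* Whether air exclusion should apply globally or only to abdominal air is
  ambiguous in the clinical literature this follows; the global default is
  the more consistent reading (see above), and the switch preserves the
  alternative.
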