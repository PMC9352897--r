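# ctbca — CT-based body composition analysis and intermodal agreement

`ctbca` quantifies body composition from a segmented CT volume and measures
how well the resulting biomarkers agree with reference modalities. It is
aimed at imaging researchers who already have a semantic body-region
segmentation (deep-learning or otherwise) of whole-body or torso CT and
want (a) reproducible tissue compartment quantification and (b) the
standard method-comparison statistics against DXA or BIA readings.

## What it computes

**Tissue classification.** Each voxel is classified from its Hounsfield
unit and its semantic region. Adipose tissue is HU ∈ [−190, −30], muscle
HU ∈ [−29, 150], and air HU ∈ [−1024, −800]. Adipose voxels are
subclassified by region into SAT (subcutaneous), VAT (abdominal cavity),
IMAT (within muscle), EAT (within the pericardium) and PAT (mediastinum
outside the pericardium); bone comes from the bone region label. Air-window
voxels are excluded from the body denominator.

**Biomarkers.** With n_body = non-background voxels minus excluded air,

    BFR = 100 · (n_SAT + n_VAT + n_IMAT + n_EAT + n_PAT) / n_body   [%]
    SMR = 100 · n_muscle / n_body                                   [%]

Both are invariant under uniform voxel-spacing rescaling; compartment
volumes in litres are reported alongside but are spacing-dependent.

**Agreement.** For each method pair and stratum (overall, BMI group, sex):
Pearson's r with the non-correlation test, Lin's concordance correlation
coefficient

    ρC = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)

(n-denominator moments; |ρC| ≤ |r| always), and Bland–Altman statistics
(mean difference, limits of agreement d̄ ± 1.96·s_d, confidence intervals),
plus a Shapiro–Wilk normality screen.

**Synthetic data.** `generate_phantom()` builds CT volumes whose tissue
composition is exact by construction (an oracle for the quantification),
and `generate_cohort()` simulates paired multi-modality measurement tables
with configurable per-modality bias, BMI-dependent bias, noise and
missingness.

## Worked example

```r
library(ctbca)

# a 32 x 32 x 16 phantom with known composition, then quantify it
ph     <- generate_phantom(phantom_spec(shape = c(32, 32, 16), seed = 7))
report <- quantify_tissues(classify_tissues(ph$ct, ph$regions))
print(report)
```

```
Body composition report
  body voxels (denominator): 11126
  BFR: 42.10 %   SMR: 31.58 %
  voxel spacing: 5 x 5 x 5 mm
       tissue voxels litres
   background   4672  0.584
          SAT   2342  0.293
          VAT   1405  0.176
         IMAT    469  0.059
          EAT    234  0.029
          PAT    234  0.029
       muscle   3514  0.439
         bone   1171  0.146
 excluded_air    586  0.073
 unclassified   1757  0.220
```

The BFR of 42.10 % is 100 × (2342+1405+469+234+234)/11126, with the 586
air-pocket voxels removed from the denominator — and equals
`ph$expected$bfr` exactly, because the phantom's composition is known by
construction.

```r
# a simulated 74-subject cohort (22/35/17 across BMI groups) and the
# CT-vs-DXA body-fat comparison, stratified by BMI group
tab <- generate_cohort(cohort_spec(seed = 7, allocation = "stratified_exact"))
cmp <- compare_methods(tab, metric = "bfr", pair = c("bca", "dxa"), stratify = "bmi")
print(cmp)
```

```
Method comparison: BFR, bca vs dxa (difference = bca - dxa)
  overall    n= 68  r=0.997 (p=1.9e-76)  ccc=0.886  mean diff=5.273  LoA=[3.743, 6.804]
  healthy    n= 21  r=0.997 (p=4.7e-22)  ccc=0.874  mean diff=5.299  LoA=[3.641, 6.957]
  overweight n= 33  r=0.996 (p=3.9e-34)  ccc=0.836  mean diff=5.257  LoA=[3.745, 6.768]
  obese      n= 14  r=0.996 (p=1e-13)  ccc=0.780  mean diff=5.274  LoA=[3.785, 6.764]
```

Readings here were simulated with a −5.29 percentage-point DXA bias and
0.8 pp noise, so the recovered mean difference ≈ 5.27 pp is the injected
truth; ccc < r because the concordance coefficient penalises the systematic
offset that leaves Pearson's r untouched. n varies per stratum because
subjects missing a DXA reading are dropped pairwise.

A thin command-line interface wraps the same functions:

```sh
BCA=$(Rscript -e 'cat(system.file("cli", "bca.R", package = "ctbca"))')
Rscript $BCA simulate phantom --seed 7 --out-ct vol.nii.gz --out-seg seg.nii.gz --out-truth truth.json
Rscript $BCA quantify --ct vol.nii.gz --seg seg.nii.gz --out report.json
Rscript $BCA simulate cohort --seed 7 --n 74 --out cohort.csv
Rscript $BCA compare --table cohort.csv --out study/
```

See `vignettes/body-composition.Rmd` for the model, its assumptions and the
design choices.

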