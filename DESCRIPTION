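Package: ctbca
Title: CT-Based Body Composition Analysis and Intermodal Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-level tissue quantification of segmented computed
    tomography volumes and method-comparison statistics for body
    composition analysis. Subclassifies a CT volume into adipose
    (subcutaneous, visceral, intermuscular, epicardial, paracardial),
    muscle and bone compartments by Hounsfield-unit thresholding within
    semantic body regions, computes the Body Fat Ratio and Skeletal
    Muscle Ratio biomarkers with an air-exclusion denominator, and
    quantifies agreement between imaging-derived and reference
    modalities (DXA, BIA) via Pearson correlation, Lin's concordance
    correlation coefficient and Bland-Altman limits of agreement,
    overall and stratified by BMI group or sex. Includes a synthetic CT
    phantom generator with known ground-truth composition and a paired
    multi-modality cohort simulator for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
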