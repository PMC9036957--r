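Package: frocdwi
Title: Fractional-Order-Calculus Diffusion MRI Modelling and Diagnostic
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and voxelwise fitting of the
    fractional-order-calculus (FROC) generalisation of the diffusion-weighted
    MRI signal together with the conventional mono-exponential apparent
    diffusion coefficient, volume-of-interest summarisation of the resulting
    parameter maps, and the diagnostic statistics used to evaluate such
    parameters as imaging biomarkers: Mann-Whitney group comparisons with
    Bonferroni correction, ROC analysis with Youden-index cutoffs and
    Hanley-McNeil confidence intervals, logistic combination of parameters,
    correlated-AUC comparison, and McNemar tests.  A synthetic cohort and
    phantom generator with Rician noise makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    minpack.lm,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
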