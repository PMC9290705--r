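Package: pbdlmrq
Title: Multiparametric Quantitative MRI Analysis of the Partial Bile Duct
    Ligation Mouse Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multiparametric quantitative
    MRI of cholestatic liver fibrosis in the partial bile duct ligation (PBDL)
    mouse model. Generates synthetic imaging cohorts with known tissue
    parameters and Metavir histology stages, fits voxel-wise T1 (variable flip
    angle), T2/T2* (log-linear multi-echo), ADC (two-point mono-exponential)
    and IVIM (segmented-then-full bi-exponential) parameter maps under Rician
    noise, summarizes regions of interest, and runs the group-comparison,
    Spearman-correlation, feature-selection and ROC statistics that evaluate
    MRI parameters as fibrosis and inflammation biomarkers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
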