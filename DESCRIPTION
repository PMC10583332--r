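Package: noddinorms
Title: Robust Normative Modelling of NODDI Microstructure in the AT(N)
    Framework
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Defines normal versus abnormal neurodegeneration from
    ROI-level NODDI metrics (neurite density and orientation dispersion)
    using age- and sex-adjusted robust normative z-scores with
    outlier-refined refitting, classifies CSF amyloid/tau (A/T) biomarker
    status from published cutoffs, and compares clinical and biomarker
    groups with Kruskal-Wallis tests, Benjamini-Hochberg FDR correction
    and Cliff's delta effect sizes.  Includes a Firth-penalized logistic
    regression model-comparison suite (ROC/AUC with DeLong confidence
    intervals, AIC, penalized likelihood ratios), voxel-level ROI
    extraction from co-registered tissue-fraction and metric volumes, a
    synthetic cohort generator and imaging phantoms for end-to-end
    testing, and a pipeline orchestrator with a thin command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
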