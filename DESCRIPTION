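Package: octplaq
Title: Quantitative Plaque Morphometry and Risk Modelling for Intravascular OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of intravascular optical
    coherence tomography (IVOCT) pullbacks in polar coordinates: synthetic
    pullback phantoms and cohort generators with known ground truth,
    dynamic-programming tracing of the fibrous-cap abluminal boundary,
    extraction of 17 lesion-level plaque features (lumen, calcium, and
    fibrous-cap geometry including fibrous-cap surface area and burden),
    Spearman-correlation collinearity pruning with hierarchical clustering,
    and a logistic-regression / ROC risk-modelling chain for binary lesion
    outcomes such as in-stent neoatherosclerosis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    graphics,
    grDevices,
    jsonlite,
    pROC,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
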