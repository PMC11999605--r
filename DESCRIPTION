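Package: eicoperm
Title: Permutation Analysis of Stimulated Whole-Blood Eicosanoid Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted eicosanoid lipidomics from
    whole-blood stimulation assays. Handles left-censored concentrations
    (zero, half-LOD and reversed Kaplan-Meier substitution), baseline
    subtraction and white-blood-cell normalization, per-metabolite
    Wilcoxon rank-sum tests calibrated by joint label permutation,
    resampling-based step-down minP and Benjamini-Hochberg multiplicity
    adjustment, and functional-class-scoring pathway inference with the
    Tippett (minimum p-value) combining function. Includes a synthetic
    cohort generator with planted group effects for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
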