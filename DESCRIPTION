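Package: recurmap
Title: Spatial Patterns of Glioblastoma Progression Relative to
    Radiotherapy Target Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs analysis clinical and planning target volumes
    (CTV/PTV) from a post-operative resection-cavity mask (convex hull plus
    a concentric millimetre margin), classifies contrast-enhancing tumor
    voxels at radiographic progression into six regions relative to those
    volumes (including a perfusion-derived inclusion zone and the CTV-PTV
    transition zone), computes distance-band burdens from the CTV margin,
    and runs the cohort-level statistical battery (normality-gated
    two-group tests, chi-squared contingency comparisons, Kaplan-Meier
    progression-free survival summaries). Ships a synthetic phantom and
    cohort generator with exact brute-force ground truth so the geometry
    and statistics are testable without patient imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    survival,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
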