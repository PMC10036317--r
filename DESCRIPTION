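Package: anthropix
Title: Mesh-Based Anthropometry and Comparative Error Statistics for
    Single-Image Height and Weight Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well height and weight can be estimated
    from a single photograph. Implements the mesh-based measurement chain
    used by 3D-model anthropometry (inter-pupillary-distance metric scaling,
    head-apex to foot-plane height, enclosed-volume weight at a fixed body
    density), a gender-specific population-average baseline estimator, and
    the comparative error statistics used to rank estimator groups: per-image
    individual and crowd median accuracies, percentile-bootstrap confidence
    intervals of medians, a Friedman omnibus test, and Bonferroni-corrected
    pairwise Wilcoxon signed-rank tests. A synthetic-data layer generates
    cohorts, study designs, landmark-annotated watertight body meshes, and
    simulated rating sessions with catch-trial quality filtering, so the full
    pipeline runs end-to-end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
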