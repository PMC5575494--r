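Package: uscontour
Title: Contour Agreement Analysis for 3D Ultrasound Organ Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify agreement between closed 3D organ contours
    (triangle meshes in mm), as used to evaluate semiautomated uterine
    segmentation on 3D transabdominal ultrasound against expert manual
    delineation. Implements four geometric agreement metrics (centroid
    distance, Dice similarity coefficient, mean surface-to-surface
    distance, and the uniform 95% coverage margin), per-vertex
    interobserver deviation maps, study-level bookkeeping (image-quality
    rating rules, pairwise comparison enumeration, segmentation-failure
    ledgers), Wilcoxon rank-sum group statistics with Bonferroni
    correction, and a fully seeded synthetic cohort generator producing
    uterus-like shapes, observer-perturbed manual contours and
    quality-dependent semiautomated contours with failures, so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
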