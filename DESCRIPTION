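Package: microglia3d
Title: 3D Morphometric Quantification of Retinal Microglia in Confocal Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies microglia in multi-channel 3D confocal stacks of
    IBA-1/CD68-labelled retina. Provides a three-class random-forest voxel
    classifier on a multi-scale filter bank, watershed-based instance
    segmentation with vasculature exclusion and size filtering, per-cell 3D and
    z-projected 2D morphometrics (volume, convex hull, solidity, convexity,
    circularity, axis ratio), CD68 colocalization per cell, count densities,
    and the group-comparison statistics layer (Shapiro-Wilk gated Student's t /
    Mann-Whitney U, two-way ANOVA with Bonferroni contrasts). Includes a
    synthetic confocal-stack simulator with ground-truth instance labels for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    car,
    emmeans,
    stats,
    tools,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
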