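Package: morphofdr
Title: Regional Brain Volumetry and Hierarchical FDR for Morphometric
    Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for deformation-based regional brain volumetry and
    tree-structured multiple testing. Computes regional volumes from
    voxel-wise local-volume-ratio maps weighted by probabilistic atlas
    maps, aggregates them through a hierarchical region tree, fits
    covariate-adjusted linear models for group differences and for
    associations with psychopathy (PCL-R) scores, and controls the false
    discovery rate over the region hierarchy using Simes family p-values,
    within-family Benjamini-Hochberg testing and level-wise threshold
    reduction.  A synthetic-cohort simulator with plantable effects
    supports power and error-rate studies of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
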