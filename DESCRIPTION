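Package: junctionr
Title: Quantifying Membrane Localization, Cell-Cell Adhesion and Protein
    Interaction in Cancer Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for quantifying cell-cell junction
    biology in breast cancer cell models. Implements the internuclear
    fluorescence-profile pipeline (profile extraction, length normalization
    to 100 arbitrary units, profile-map building, Poisson maximum a
    posteriori denoising, Bayesian geometric compensation of profile
    columns, and the maximum-mean-ratio statistic) for scoring membrane
    versus cytoplasmic protein localization; detachment-work analysis of
    atomic force microscopy force-distance curves; proximity ligation assay
    dot counting with blobs-per-cell normalization; immunohistochemistry
    extension scoring with contingency-table statistics; and seeded
    synthetic-data generators with recorded ground truth for every input
    the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff
Config/testthat/edition: 3
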