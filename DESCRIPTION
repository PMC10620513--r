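Package: trapmap
Title: Whole-Brain cFos-TRAP Cell Mapping, Quantification and Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for quantifying fluorescently labeled
    cFos-TRAPed cells across the whole mouse brain from coronal section
    images. Detects labeled cells (median filtering, rolling-ball
    background subtraction, thresholding, connected-component size
    filtering, centroid extraction), assigns them to hierarchical atlas
    regions via registered label maps, computes region-level activity
    ratios, runs two-way factorial ANOVA with fold changes across a
    sleep-deprivation 2x2 design, and estimates inter-regional
    functional connectivity from cross-animal Pearson correlation
    structure binned to parent regions, with Kolmogorov-Smirnov
    comparisons between groupings. A synthetic-data module generates toy
    atlases, registered label maps, fluorescence sections with
    ground-truth cells, and animal-by-region count tables with
    controllable effects and correlation structure, so every stage is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
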