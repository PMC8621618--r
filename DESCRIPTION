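Package: gliaclone
Title: Clonal Analysis of Multicolor Lineage-Traced Cortical Glia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clonal analysis of combinatorial multicolor
    (StarTrack-style) lineage tracing data in the mouse cortex. Converts
    per-cell cytoplasmic and nuclear fluorescence intensities for six
    fluorescent proteins into 12-digit color barcodes, groups labeled cells
    into clones using barcode identity, an intensity-consistency rule and a
    barcode-rarity filter, and computes per-clone statistics (clone size,
    rostro-caudal dispersion across serial sections, uniform versus mixed
    glial composition, laminar spread) together with the nonparametric
    group comparisons used in this field. Includes a synthetic-cohort
    generator emulating stochastic piggyBac reporter integration and glial
    clonal expansion, and a forward imaging model (render, detect,
    quantify) so the whole pipeline is testable end to end without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    nortest,
    jsonlite,
    tiff,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
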