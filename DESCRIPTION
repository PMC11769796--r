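Package: domescope
Title: Quantitative Dome Formation and Epithelial Organization Analysis
    for Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional organization of intestinal
    epithelial co-cultures (e.g. Caco-2/HT29-MTX-E12 on Transwell inserts)
    from two-channel confocal z-stacks. Provides per-optical-section
    adaptive segmentation, cell-coverage and contiguous-object profiles,
    connected-component shape scoring (area, eccentricity), height-map
    surface reconstruction with geometric dome detection and per-angle-view
    visibility counts, exact Mann-Whitney per-section condition comparisons,
    and closed-form barrier-physiology calculators (orbital shear stress,
    blank-corrected TEER, apparent permeability, flux AUC). A synthetic
    phantom generator produces domed-monolayer stacks with exact ground
    truth so that every stage of the pipeline is testable without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    pracma,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
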