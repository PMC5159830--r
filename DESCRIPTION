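Package: gridPheno
Title: Grid-Mapped Single-Cell Functional Phenotyping of Perifused Cells
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for functional phenotyping of heterogeneous cell mixtures
    imaged live on a gridded perifusion coverslip. The package simulates or
    ingests per-cell fluorescence time series (NAD(P)H autofluorescence or
    Fura calcium ratios) acquired under stepped-glucose perifusion protocols,
    calibrates each cell against its KCN and FCCP plateaus, scores responses
    with a drift-robust minimum-change statistic, maps post-fixation
    immunostain identities back to live-imaging ROIs through the fiducial
    grid, and reports per-type frequency distributions together with
    false-positive and false-negative rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, CellBiology, TimeCourse, Classification, Visualization
RoxygenNote: 7.3.3
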