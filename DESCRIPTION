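Package: woundquant
Title: Quantification of Single-Cell Wound Repair from Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify single-cell wound repair in time-lapse
    fluorescence microscopy of the Drosophila syncytial embryo model: wound
    segmentation and area tracing, actomyosin ring edge detection with Feret
    diameters, expansion/contraction statistics, kymographs and averaged line
    profiles with confidence intervals, plus post-wounding expression
    statistics (array spot filtering, FDR/fold-change differential-expression
    calls, TAD enrichment by Fisher's exact test, gene-size bootstrap, and
    delta-delta-Cq knockdown efficiency). A synthetic-data module generates
    wound movies and expression studies with complete ground truth so every
    stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
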