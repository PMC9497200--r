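Package: ctcscope
Title: Enumeration and Morphological Characterization of Circulating Tumor
    Cells and Tumor-Derived Extracellular Vesicles in Fluorescence
    Cartridge Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-cytometry pipeline for CellSearch-style cartridges:
    segmentation of four-channel (DAPI, PE/CK, APC/CD45, FITC)
    fluorescence frames, per-object morphometry, linear threshold gating
    into circulating tumor cell (CTC) and tumor-derived extracellular
    vesicle (tdEV) classes, rule-based assignment of six morphological
    CTC subclasses, and the accompanying nonparametric cohort statistics
    (Mann-Whitney U with mean ranks, Spearman rank correlation, Pearson
    chi-square on 2x2 tables, paired t). Includes a synthetic-cartridge
    generator with planted ground truth and a zero-inflated log-normal
    cohort simulator for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Software, Visualization
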