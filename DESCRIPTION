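Package: mcscquant
Title: Quantification of UVB-Induced Melanocyte Stem Cell Epidermal
    Migration from Two-Channel Skin Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify melanocyte stem cell (McSC) epidermal
    migration from two-channel whole-mount skin fluorescence images:
    hair-follicle detection from red-channel autofluorescence,
    estimation and removal of red-to-green spectral bleed-through,
    Laplacian-of-Gaussian detection of nuclear H2B-GFP point signals,
    per-mouse migration-rate aggregation (McSCs per hair follicle),
    section-based staining quantification (positive-area over
    DAPI-area ratios, cell counts, object-based colocalization), and
    the group statistics used for such designs (Welch t, paired t,
    Mann-Whitney). A synthetic two-channel skin-image generator with
    full ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
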