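Package: mpquant
Title: Quantification of Protein Micropatterns, Receptor Relocalization
    and Gliding-Assay Motility from Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-micropattern statistics (background-corrected selectivity,
    homogeneity and amount of protein patterned), normalized cross-adsorption
    matrices for sequential multiplexed micropatterns, nonspecific substrate
    binding, receptor-relocalization enrichment indices with bleed-through
    and temporal corrections, cell-on-micropattern adhesion metrics, and
    kymograph-based gliding-assay motility analysis. Includes a synthetic
    TIRF-like image generator (Poisson shot noise plus Gaussian read noise)
    producing pattern images, multiplexed series, gliding movies and cell
    adhesion fields with closed-form ground truth for validation of every
    metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
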