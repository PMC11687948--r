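Package: taxapix
Title: Interpretable Phenotype Classification from Microbiome Abundance Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms taxa-by-sample microbiome abundance tables into
    fixed-layout single-channel images by embedding taxa in two dimensions
    under functional-annotation-driven similarity, classifies sample
    phenotypes with a residual convolutional network carrying per-block
    spatial attention, and back-projects class saliency (Grad-CAM) through
    the pixel layout into per-taxon importance with downstream metabolite
    and functional-trait summaries. Ships a sparse compositional microbiome
    count simulator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microbiome, Classification, Software, FeatureExtraction
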