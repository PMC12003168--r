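Package: gliaquant
Title: Quantification Pipelines for Plaque-Associated Microglia, Myelin
    Morphometry and Single-Nucleus Compositional Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the bespoke quantification steps used
    in studies of microglial responses to amyloid pathology: a fluorescence
    image-analysis pipeline (Fourier size filtering, Gaussian denoising,
    rolling-ball background subtraction, Otsu thresholding, watershed nuclei
    segmentation, plaque segmentation and plaque-proximity marker
    quantification), electron-microscopy g-ratio morphometry from annotated
    axon area tables, grade-based microglial phagocytosis scoring, and
    single-nucleus compositional statistics (quality-control filters,
    doublet-cluster removal, cell-type proportion ANOVA with Holm-Bonferroni
    adjustment, a k-nearest-neighbour Kullback-Leibler neighbourhood
    variability statistic with shuffled controls, and differential-expression
    signature overlap). A ground-truthed synthetic-scene generator emulates
    every input data type so the full pipeline is testable without microscopy
    or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
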