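Package: itrait
Title: Image-Based Trait Extraction and Genetic Mapping for Plant Drought Phenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting image-based phenotypic traits (i-traits) from
    multi-optical plant scans (side-view RGB stacks, 250-band hyperspectral cubes,
    X-ray computed-tomography sinograms) and carrying them through a drought-
    phenomics genetics pipeline: four-step drought-trait selection (3-sigma outlier
    removal, WW/DS t-test, repeated multilayer-perceptron importance ranking,
    broad-sense heritability filtering), Q+K mixed-linear-model association with
    P3D variance components, iterative QTL merging, candidate-gene assignment,
    local/distant and static/dynamic eQTL classification, genomic selection with
    RR-BLUP and Bayes A, stepwise i-trait marker selection, and remote-sensing
    spectral indexes. A synthetic-data module generates image phantoms with known
    geometry and spectra plus genotype, phenotype and expression panels with a
    planted genetic architecture, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    lme4,
    nnet,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    tiff,
    png
Config/testthat/edition: 3
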