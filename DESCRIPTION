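Package: sgribo
Title: Stress-Granule Image Quantification and Ribo-Seq Translational
    Regulation Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-cell quantification of stress-granule foci from
    multi-channel fluorescence microscopy (Otsu nuclear segmentation,
    propagation-based single-cell segmentation, top-hat speckle
    enhancement, eccentricity filtering) and classification of
    translational regulation from paired RNA-seq/Ribo-seq counts
    (median-of-ratios normalization, negative-binomial Wald tests with a
    local dispersion trend, translation-efficiency interaction tests,
    buffering/abundance/TE gene classes), with preranked gene-set
    enrichment, hypergeometric over-representation against a TPM-defined
    background, melt-curve Tm estimation, and a synthetic-data generator
    providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    EBImage,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
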