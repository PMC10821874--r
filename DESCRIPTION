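Package: palatrix
Title: Paired Single-Cell Multiome Analysis of Branching Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for paired scRNA/scATAC multiome data of a
    branching developmental system: joint-modality quality control, LSI and PCA
    embeddings, background-matched peak-gene linkage tests, PWM scanning and
    chromVAR-style motif deviations, dual-modality marker transcription factors,
    optimal-transport trajectory coupling across sampling stages with Markov
    absorption fate probabilities, diffusion pseudotime, driver genes and
    stage-resolved motif enrichment, motif-prior gene-regulatory-network
    inference with in silico transcription-factor knockouts and perturbation
    scores, plus the validation statistics used to check such analyses. Ships a
    synthetic multiome generator with planted regulatory ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
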