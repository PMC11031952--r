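Package: gatmotif
Title: Graph-Attention Discovery of Transcription-Factor Binding Motifs in
    ATAC-Seq Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts transcription-factor binding sites (TFBSs) in fixed-length
    ATAC-seq-derived sequences and extracts multiple variable-length motifs from
    the trained model. Sequences and their constituent k-mers form a
    heterogeneous graph with similarity, coexisting and inclusive edges; a
    two-layer graph attention network learns k-mer and sequence embeddings and a
    fully connected layer classifies sequences as bound or unbound. Inclusive
    attention coefficients, denoised against shuffled-negative background, seed
    a merging procedure driven by k-mer coexisting probabilities that
    reconstructs binding-site instances of multiple lengths and summarises them
    as position probability matrices. Includes FASTA/BED input, a synthetic
    planted-motif benchmark generator, evaluation metrics and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
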