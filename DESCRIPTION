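Package: seq2track
Title: Sequence-to-Coverage Track Models with Pretraining and Transfer at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains a simplified Enformer-style neural network that
    predicts binned genomic coverage tracks (ATAC-seq, ChIP-seq, DNase-seq)
    from one-hot encoded DNA sequence, entirely on CPU at desk scale. Provides
    the full experimental machinery around the model: Poisson negative
    log-likelihood training with AdamW and a linear warmup/decay schedule,
    architecture ablations (removing the final pointwise convolution and/or a
    linear layer from the attention blocks, reducing attention depth),
    checkpointing with head replacement and trunk freezing for cross-species
    transfer, homology-aware train/validation/test splits, and a track-count
    generalization/specialization sweep. A synthetic regulatory-grammar
    generator plants motifs (including long-range motif pairs) that drive
    Poisson-distributed coverage, so every experiment runs in minutes on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
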