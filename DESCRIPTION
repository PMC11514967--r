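Package: motifcontrast
Title: Discriminative Sequence Analysis of Differential Transcription Factor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Explains binding differences between two ChIP-seq experiments
    (two cell types, two treatments, or two paralogous transcription factors)
    from sequence alone. Peaks unique to each experiment are anchored on the
    most likely binding site, and three classes of sequence features are
    extracted and weighted in a single L1-penalised logistic model: a
    discriminative core-motif PWM learned by logistic regression on aligned
    sites, (k-mer, region) nucleotidic-environment variables discovered over a
    lattice of contiguous bins, and (co-factor PWM, region) variables scored
    with a max-lattice. Ablation-based importance, per-class PPMs, Gini motif
    simplicity, Jaccard peak distance and a synthetic two-class sequence
    generator for validation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    Biostrings,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
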