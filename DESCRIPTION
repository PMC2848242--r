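Package: lsgpipe
Title: Regulatory Function Inference for Lineage-Specific Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for inferring putative functions of uncharacterized
    lineage-specific genes from microarray co-expression and promoter
    sequence analysis. Provides seed-based co-expression clustering with
    Pearson correlation thresholds, strand-aware proximal promoter
    extraction from a soft-masked genome, Match-style position weight
    matrix scanning with core and matrix similarity scores,
    over-representation analysis of single and composite (ordered and
    unordered pair/triplet) transcription factor binding sites by Fisher's
    exact test with Benjamini-Hochberg false discovery rate control,
    discriminative Gibbs-sampling motif discovery against a background
    promoter set, and weighted gene co-expression network analysis (power
    adjacency, topological overlap, module detection, hub genes). A seeded
    synthetic-data generator produces expression matrices, promoters, PWM
    libraries and annotations with known planted truth so every stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
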