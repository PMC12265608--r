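Package: txbench
Title: Biologically-Aware Benchmarking of Transcript Sequence Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking mature-mRNA property predictors under
    biologically-informed evaluation protocols. Provides homology-, chromosome-
    and k-mer-cluster-based train/test splitting with leakage diagnostics,
    Huffman-grammar compressibility analysis of genomic region corpora with
    cross-compression matrices, a linear-probing protocol over frozen sequence
    embeddings with cross-dataset Z-score aggregation and significance testing,
    compositional-generalization splits over upstream-AUG and Kozak-context
    features, desk-scale reference implementations of masked-language-model,
    decoupled-contrastive and scalarized joint training objectives, and
    synthetic transcript generators that emulate the statistical structure each
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
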