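Package: rotshift
Title: Decay-Stage Transcriptomics of Brown- and White-Rot Wood-Decay Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparative decay-stage transcriptomics of
    wood-decay fungi grown along spatial decay gradients. Normalizes
    gene-level read counts to RPKM, calls differentially expressed genes
    between wafer sections with a negative-binomial exact test under a
    common conditional-maximum-likelihood dispersion, classifies temporal
    expression trends into eight decay-stage subgroups pooled as early- or
    late-upregulated sets, intersects stage sets across species through
    reciprocal-best-hit ortholog groups (Venn partition, Spearman
    correlation, hierarchical clustering of early-to-late expression
    ratios), and computes functional-investment statistics for
    lignocellulose-oxidizing (LOX) and glycoside hydrolase (GH) gene
    classes: per-family early/late DEG counts and shift tests,
    hypergeometric term enrichment, GH:LOX transcription ratios, PCA of
    family expression, and Z-score scaling. A synthetic-data module
    simulates the multi-species wafer-section study design with known
    ground truth so the whole pipeline can be exercised and calibrated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
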