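Package: estDGE
Title: Digital Gene Expression Analysis of Multi-Library EST Collections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of digital gene expression measured by
    counting expressed sequence tags (ESTs) across multiple non-normalized
    cDNA libraries. Provides a SummarizedExperiment-based container for
    transcriptional-unit (TU) by library count matrices; per-library
    redundancy, analytic rarefaction and Simpson reciprocal diversity;
    an omnibus log-likelihood R statistic for differential expression with
    a Poisson-randomization calibration of the significance cutoff;
    two-way hierarchical clustering of frequency profiles with Java
    TreeView export and correspondence analysis of libraries and TUs;
    annotation overlays (InterPro-based PDF/POF classification, GO-term
    over-representation, phyletic-class profiles, ortholog overlap); codon
    usage analysis (RSCU, CAI against a highly expressed reference set,
    GC3, correspondence analysis of codons); and a synthetic EST-library
    generator with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS,
    seqinr,
    jsonlite
Config/testthat/edition: 3
biocViews: GeneExpression, Transcriptomics, Sequencing, Clustering
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
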