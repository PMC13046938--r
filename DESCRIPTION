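Package: deltabind
Title: Cell Type-Specific Differential Transcription Factor Binding at Risk Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how disease-associated regulatory variants alter
    transcription factor binding in specific cell types. Builds log-odds
    position weight matrices with exact score p-values computed by dynamic
    programming, scans risk-allele and non-risk-allele versions of candidate
    cis-regulatory elements, and classifies motifs as consistently disrupted
    or enhanced from per-element differential binding scores. Upstream, motifs
    are selected per cell type by hypergeometric enrichment in marker peaks,
    a bias-matched chromatin-accessibility deviation statistic, and a TF gene
    expression filter; downstream, implicated variants are mapped to candidate
    target genes and tested for pseudobulk differential expression between
    risk-allele carriers and non-carriers with a negative-binomial model.
    Includes a seeded synthetic-data generator emitting every input format
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
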