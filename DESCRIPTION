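Package: thymoselect
Title: TCR Repertoire Diversity, CDR3 Motif Scoring and Promiscuous
    Gene Expression Analysis for Thymic Selection Studies
Version: 0.1.0
Authors@R:
    person("thymoselect", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how the thymic epithelium shapes the T cell
    receptor (TCR) alpha-chain repertoire and the breadth of promiscuous
    gene expression.  Ingests MIGEC-style clonotype tables, applies
    functional and read-depth filters, and pools per-mouse clonotype sets
    into subset-by-genotype TCR catalogues.  Scores CDR3 amino-acid
    sequences for self-reactivity-associated features (position-6/7
    doublets; central cysteine under an apex-out alignment) with exact and
    t-test group comparisons.  Reimplements coverage-based rarefaction and
    extrapolation of clonotype richness (Hill number q = 0) in the
    Chao-Jost framework with bootstrap confidence intervals, relative
    diversity at a fixed coverage, and Morisita-Horn repertoire overlap.
    Estimates tissue-restricted-antigen expression breadth from sparse
    single-cell count matrices by fragment downsampling and cell
    resampling, and computes H3K27me3 ChIP/input metaprofiles in fixed
    bins around transcription start sites.  A synthetic-data module
    generates every input family with planted, recoverable parameters so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
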