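Package: lfcmm
Title: Similarity-Aware Mixed Linear Models for Transcript Log2 Fold Changes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits mixed linear models to per-transcript log2 fold changes in
    which biological similarity enters as the covariance matrix of a single
    random effect. Similarity between transcripts is measured by the overlap
    of their exon sets within a gene, and similarity between Gene Ontology
    terms or Reactome pathways by the Jaccard coefficient of their gene sets.
    Variance components are estimated by an expectation-maximization REML
    algorithm, effect solutions are obtained from Henderson's mixed model
    equations, and standardized solutions are tested against the standard
    normal distribution. Includes readers for GTF annotation, term-mapping
    tables and OBO ontologies, a synthetic-data generator with ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
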