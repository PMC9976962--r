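Package: methcompile
Title: Cross-Study Analysis of Compiled Blood DNA Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-study, cross-platform analysis of compiled blood
    DNA methylation (DNAm) array data: Beta/M-value conversion, sample and
    probe quality-control filters, reference-based blood cell-type
    deconvolution, linear removal of study-identifier batch effects, ANOVA
    fraction-of-explained-variance decomposition (including a study-bias
    adjustment simulation and hashed-profile PCA), deterministic feature
    hashing of probe-level profiles, an approximate nearest-neighbour sample
    search index with an exact oracle, simulation-based EWAS power analysis,
    and replication of sex-associated differentially methylated probes with
    concordance-at-the-top summaries. A synthetic-compilation generator with
    full ground truth supports end-to-end testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
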