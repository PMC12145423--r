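Package: globpat
Title: Global Patterns of Epigenetic Variation Across Individuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns recurring ("global") patterns of histone-modification
    variation across individuals with a stacked hidden Markov model over
    binarized ChIP-seq tracks, annotates a genome with them at 200 bp
    resolution, and associates the learned emission parameters with
    genotypes (gQTLs), gene expression, co-expression module eigengenes,
    protein abundance and case/control phenotype status. Includes quantile
    normalization, per-bin quasi-Poisson covariate correction, Poisson
    background binarization, greedy state matching for robustness
    diagnostics, base-level overlap enrichment against interval
    annotations, permutation-based family-wise error control, and a
    synthetic-data generator with ground truth for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
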