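Package: drivermod
Title: Driver Pattern Identification from Integrated Expression, Copy Number
    and Mutation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies candidate driver genes (modulators) and the gene
    modules they regulate from matched tumor gene expression, copy-number and
    somatic mutation profiles of drug-resistant and drug-sensitive samples.
    Implements Earth Mover's Distance differential screening with permutation
    q-values, a gene-length mutation-bias resampling filter, weighted
    co-expression modules via the topological overlap matrix, a
    mutual-exclusivity mutation network for candidate modulator selection,
    module-network learning with normal-gamma scored regression trees fitted
    by a classification EM algorithm, and dosage-sensitivity classification
    of modulators from local polynomial fits. A synthetic multi-omics
    generator with planted regulatory ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    jsonlite,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
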