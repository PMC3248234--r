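Package: gdaa
Title: Gene Differential Association Analysis via Permutation N-Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies genes whose correlation structure with all other
    genes differs between two biological conditions (differentially
    associated genes). For each gene, Fisher-transformed Pearson
    correlation vectors are computed within disjoint subject subgroups,
    the two conditions are compared with an energy-distance N-statistic
    using the Euclidean kernel, and significance is assessed against a
    permutation null distribution with an extended Bonferroni (per-family
    error rate) adjustment. Includes a deterministic two-tier parallel
    executor (worker processes over permutations, gene-block lanes within
    workers) whose output is invariant to the parallel configuration, a
    seeded synthetic-data generator with planted differential-association
    blocks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    parallel,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    SummarizedExperiment
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, Network, Software
RoxygenNote: 7.3.3
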