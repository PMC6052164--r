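Package: nncluster
Title: Nuclear Norm Clustering by Simulated Annealing
Version: 0.1.0
Authors@R:
    person("NNC", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Partitions samples into K clusters by minimizing the nuclear
    norm (sum of singular values) of the pooled within-cluster residual
    matrix, optimized with simulated annealing over label assignments.
    Includes external evaluation by macro-averaged F-score with optimal
    one-to-one cluster-to-class matching, seeded synthetic data generators
    (Gaussian blobs with optional feature correlation and outliers, and a
    toy case/control genotype panel with allelic chi-square SNP ranking),
    and a command-line interface for clustering, generation, evaluation
    and comparison against classic clustering methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
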