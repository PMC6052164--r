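#!/usr/bin/env Rscript
# Optional, not CI-gated: report (don't assert) NNC's macro-F on a real
# benchmark table. Uses the iris measurements shipped with base R; pass
# --input/--labels-col to score any other labeled CSV. Annealing is
# stochastic and the original normalization choice is unknown, so numbers
# are indicative, not a replication.

suppressPackageStartupMessages({
  library(optparse)
  library(nncluster)
})

opts <- parse_args(
  OptionParser(option_list = list(
    make_option("--input", type = "character", default = NULL),
    make_option("--labels-col", type = "character", dest = "labels_col",
                default = NULL),
    make_option("--k", type = "integer", default = NULL),
    make_option("--iters", type = "integer", default = 200000L),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--normalize", type = "character", default = "zscore")
  ))
)

if (is.null(opts$input)) {
  raw <- as.matrix(datasets::iris[, 1:4])
  truth <- as.integer(datasets::iris$Species) - 1L
  K <- 3L
  name <- "iris"
} else {
  dat <- read_data_matrix(opts$input, labels_col = opts$labels_col)
  raw <- dat$values
  truth <- dat$labels
  K <- opts$k
  name <- basename(opts$input)
}

M <- normalize_matrix(raw, method = opts$normalize)
for (report in c("final", "best")) {
  fit <- run_nnc(M, K = K, iterations = opts$iters, seed = opts$seed,
                 report = report)
  f <- macro_f_score(truth, fit$assignment, K = K)
  cat(sprintf("%s | N = %d, seed = %d, normalize = %s, report = %s: NN = %.4f, macro F = %.4f\n",
              name, opts$iters, opts$seed, opts$normalize, report,
              nnc_objective(M, fit$assignment, K), f$macro_f))
}
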