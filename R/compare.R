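#' Compare NNC with classic clustering methods on one labeled dataset
#'
#' Runs nuclear norm clustering and any requested comparators on the same
#' (already normalized) data matrix and scores each against the ground truth
#' with the same macro-F matching convention. Comparators are invoked from
#' their established implementations (`stats` and the `cluster` package),
#' never re-implemented; a comparator whose implementation is unavailable is
#' skipped with a warning.
#'
#' Supported methods: `nnc`, `kmeans`, `pam`, `hclust` (Euclidean,
#' complete linkage), `clara`, `agnes`, `diana`.
#'
#' @param M numeric n x p data matrix (normalized).
#' @param truth length-n ground-truth class labels.
#' @param K number of clusters.
#' @param methods character vector of method names (see above).
#' @param iterations annealing budget for the `nnc` row.
#' @param seed seed for `nnc` and `kmeans`.
#' @param report,matching passed to [run_nnc()] and [macro_f_score()].
#' @return data.frame with one row per method run: `method`, `macro_f`,
#'   `seed`, `iterations` (NA for non-NNC methods).
#' @export
nnc_compare <- function(M, truth, K,
                        methods = c("kmeans", "pam", "hclust", "clara",
                                    "agnes", "diana", "nnc"),
                        iterations = 20000L, seed = 1L,
                        report = "final", matching = "optimal") {
  M <- check_data_matrix(M)
  stopifnot(length(truth) == nrow(M))
  needs_cluster <- c("pam", "clara", "agnes", "diana")
  have_cluster <- requireNamespace("cluster", quietly = TRUE)
  rows <- list()
  for (m in methods) {
    pred <- switch(
      m,
      nnc = run_nnc(M, K = K, iterations = iterations, seed = seed,
                    report = report)$assignment,
      kmeans = with_seed_(seed,
                          kmeans(M, centers = K, nstart = 10L)$cluster - 1L),
      hclust = cutree(hclust(dist(M)), k = K) - 1L,
      pam = if (have_cluster) cluster::pam(M, k = K)$clustering - 1L,
      clara = if (have_cluster) cluster::clara(M, k = K)$clustering - 1L,
      agnes = if (have_cluster)
        cutree(stats::as.hclust(cluster::agnes(M)), k = K) - 1L,
      diana = if (have_cluster)
        cutree(stats::as.hclust(cluster::diana(M)), k = K) - 1L,
      {
        warning(sprintf("comparator '%s' is unavailable; skipped", m),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(pred)) {
      if (m %in% needs_cluster) {
        warning(sprintf("comparator '%s' needs the 'cluster' package; skipped",
                        m), call. = FALSE)
      }
      next
    }
    f <- macro_f_score(truth, pred, matching = matching, K = K)
    rows[[m]] <- data.frame(
      method = m,
      macro_f = f$macro_f,
      seed = if (m %in% c("nnc", "kmeans")) seed else NA_integer_,
      iterations = if (m == "nnc") as.integer(iterations) else NA_integer_
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
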