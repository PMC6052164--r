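#' Contingency table of true classes against predicted clusters
#'
#' `counts[c, k]` is the number of samples with true class c assigned to
#' cluster k. Class labels may be arbitrary (factor, character, integer);
#' cluster labels are the assignment's integers. `K` may declare more
#' clusters than appear in `pred` (empty columns are kept).
#'
#' @param truth length-n vector of ground-truth class labels.
#' @param pred length-n integer assignment (labels in `0..K-1`).
#' @param K optional declared cluster count; default is `max(pred) + 1`.
#' @return list with `counts` (C x K integer matrix), `class_labels`,
#'   `cluster_labels`.
#' @export
contingency_table <- function(truth, pred, K = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  if (length(truth) < 1L) {
    stop("need at least one sample", call. = FALSE)
  }
  pred <- as.integer(pred)
  if (is.null(K)) K <- max(pred) + 1L
  pred <- check_assignment(pred, length(truth), K)
  tf <- factor(truth)
  pf <- factor(pred, levels = 0:(K - 1L))
  counts <- unclass(table(tf, pf))
  dimnames(counts) <- NULL
  list(counts = counts,
       class_labels = levels(tf),
       cluster_labels = 0:(K - 1L))
}

#' Per-pair F1 matrix of a contingency table
#'
#' Entry `[c, k]` treats cluster k as the predicted positive set for class c:
#' precision is `counts[c,k]` over the cluster-k column sum, recall is
#' `counts[c,k]` over the class-c row sum, and F1 = 2PR/(P+R), defined as 0
#' whenever P + R = 0 (including empty cluster columns).
#'
#' @param counts C x K non-negative integer matrix (see
#'   [contingency_table()]).
#' @return C x K numeric matrix with entries in `[0, 1]`.
#' @export
pair_f_matrix <- function(counts) {
  col_tot <- colSums(counts)
  row_tot <- rowSums(counts)
  P <- sweep(counts, 2L, pmax(col_tot, 1L), "/")
  R <- sweep(counts, 1L, pmax(row_tot, 1L), "/")
  F <- matrix(0, nrow(counts), ncol(counts))
  nz <- (P + R) > 0
  F[nz] <- 2 * P[nz] * R[nz] / (P[nz] + R[nz])
  F
}

# Exact optimal one-to-one matching maximizing the summed per-class F,
# by dynamic programming over subsets of clusters: dp[c][mask] = best sum for
# the first c classes using exactly the clusters in mask (a class may also be
# left unmatched, scoring 0). O(C * 2^K); ties broken toward lower cluster
# index, then "unmatched", for reproducibility.
match_one_to_one_ <- function(F) {
  C <- nrow(F)
  K <- ncol(F)
  if (K > 20L) {
    stop("optimal one-to-one matching supports at most 20 clusters",
         call. = FALSE)
  }
  n_mask <- bitwShiftL(1L, K)
  prev <- rep(-Inf, n_mask)
  prev[1L] <- 0
  choice <- matrix(NA_integer_, nrow = C, ncol = n_mask)
  for (ci in seq_len(C)) {
    cur <- rep(-Inf, n_mask)
    for (mask in 0:(n_mask - 1L)) {
      # class ci unmatched
      best <- prev[mask + 1L]
      best_k <- 0L # 0 encodes "unmatched"
      if (mask > 0L) {
        for (k in seq_len(K)) {
          bit <- bitwShiftL(1L, k - 1L)
          if (bitwAnd(mask, bit) != 0L) {
            cand <- prev[bitwXor(mask, bit) + 1L] + F[ci, k]
            if (cand > best + 1e-12) {
              best <- cand
              best_k <- k
            }
          }
        }
      }
      cur[mask + 1L] <- best
      choice[ci, mask + 1L] <- best_k
    }
    prev <- cur
  }
  mask <- which.max(prev) - 1L
  mapping <- rep(NA_integer_, C)
  for (ci in rev(seq_len(C))) {
    k <- choice[ci, mask + 1L]
    if (k > 0L) {
      mapping[ci] <- k
      mask <- bitwXor(mask, bitwShiftL(1L, k - 1L))
    }
  }
  mapping
}

#' Macro-averaged F-score of a clustering against ground truth
#'
#' External evaluation used throughout the package's benchmarks. Builds the
#' class-by-cluster contingency table, scores every (class, cluster) pair by
#' F1, matches clusters to classes, and averages the per-class F values
#' without class-size weighting (hence "macro").
#'
#' With `matching = "optimal"` (default) the one-to-one class-cluster
#' matching maximizing the summed per-class F is found exactly; classes left
#' unmatched (necessarily so when K < C) score 0, extra clusters are ignored.
#' This convention penalizes cluster collapse: an all-in-one-cluster
#' prediction cannot score near 1. `"best-match"` lets every class
#' independently take its best-F cluster (an upper bound on the optimal
#' matching's score), for sensitivity checks.
#'
#' @inheritParams contingency_table
#' @param matching `"optimal"` or `"best-match"`.
#' @return object of class `"f_score_report"`: list with `per_class_f`
#'   (named by class), `macro_f`, `mapping` (class -> cluster label, NA when
#'   unmatched; one-to-one under `"optimal"`), `matching`, and `table` (the
#'   contingency list).
#' @examples
#' macro_f_score(c(0, 0, 1, 1), c(1, 1, 0, 0))$macro_f # 1
#' macro_f_score(c(0, 0, 1, 1), c(0, 0, 0, 0), K = 2)$macro_f # 1/3
#' @export
macro_f_score <- function(truth, pred, matching = c("optimal", "best-match"),
                          K = NULL) {
  matching <- match.arg(matching)
  tab <- contingency_table(truth, pred, K = K)
  F <- pair_f_matrix(tab$counts)
  C <- nrow(F)
  if (matching == "optimal") {
    m <- match_one_to_one_(F)
    per_class <- ifelse(is.na(m), 0, F[cbind(seq_len(C), ifelse(is.na(m), 1L, m))])
    mapping <- tab$cluster_labels[m]
  } else {
    k_best <- apply(F, 1L, which.max)
    per_class <- F[cbind(seq_len(C), k_best)]
    mapping <- tab$cluster_labels[k_best]
  }
  names(per_class) <- tab$class_labels
  names(mapping) <- tab$class_labels
  res <- list(per_class_f = per_class,
              macro_f = mean(per_class),
              mapping = mapping,
              matching = matching,
              table = tab)
  class(res) <- "f_score_report"
  res
}

#' @export
print.f_score_report <- function(x, ...) {
  cat(sprintf("Macro-averaged F-score (%s matching): %.4f\n",
              x$matching, x$macro_f))
  for (i in seq_along(x$per_class_f)) {
    cat(sprintf("  class %s -> cluster %s: F = %.4f\n",
                names(x$per_class_f)[i],
                ifelse(is.na(x$mapping[i]), "(unmatched)", x$mapping[i]),
                x$per_class_f[i]))
  }
  invisible(x)
}
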