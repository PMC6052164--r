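#' Per-cluster means of a data matrix under an assignment
#'
#' Computes the K x p matrix of cluster centers (arithmetic row means) and the
#' cluster sizes. Empty clusters are legal: they get count 0 and an all-zero
#' placeholder center, which no row ever references.
#'
#' @param M numeric n x p data matrix.
#' @param A integer assignment vector of length n with labels in `0..K-1`.
#' @param K number of clusters.
#' @return list with `centers` (K x p matrix) and `counts` (length-K integer).
#' @examples
#' cluster_means(rbind(c(0, 0), c(2, 2)), c(0, 0), K = 1)
#' @export
cluster_means <- function(M, A, K) {
  M <- check_data_matrix(M)
  A <- check_assignment(A, nrow(M), K)
  p <- ncol(M)
  counts <- tabulate(A + 1L, nbins = K)
  centers <- matrix(0, nrow = K, ncol = p)
  sums <- rowsum(M, group = A)
  present <- as.integer(rownames(sums)) + 1L
  centers[present, ] <- sums / counts[present]
  list(centers = centers, counts = counts)
}

#' Pooled within-cluster residual matrix
#'
#' Row i of the result is `M[i, ] - C[A[i], ]`, where C holds the cluster
#' means: every sample minus the center of its assigned cluster, stacked into
#' one n x p matrix. Within each non-empty cluster the residual rows sum to
#' the zero vector.
#'
#' @inheritParams cluster_means
#' @return numeric n x p residual matrix.
#' @export
pooled_residual <- function(M, A, K) {
  M <- check_data_matrix(M)
  A <- check_assignment(A, nrow(M), K)
  cm <- cluster_means(M, A, K)
  M - cm$centers[A + 1L, , drop = FALSE]
}

#' Nuclear norm (trace norm) of a matrix
#'
#' The sum of the singular values of X, equivalently the sum of the square
#' roots of the eigenvalues of X'X. It is the L1 norm of the singular-value
#' spectrum: compared with the squared (Frobenius) error it is less sensitive
#' to outlying rows, and it penalizes residuals spread across many directions,
#' encouraging low-rank within-cluster structure.
#'
#' @param X numeric matrix with finite entries.
#' @return non-negative scalar.
#' @examples
#' nuclear_norm(diag(c(3, 4))) # 7
#' @export
nuclear_norm <- function(X) {
  X <- check_data_matrix(X)
  sum(svd(X, nu = 0L, nv = 0L)$d)
}

#' Singular-value spectrum of a matrix
#'
#' Convenience accessor returning the non-increasing vector of singular
#' values; its sum is [nuclear_norm()].
#'
#' @inheritParams nuclear_norm
#' @return numeric vector of length `min(nrow(X), ncol(X))`, non-increasing,
#'   all entries non-negative.
#' @export
singular_spectrum <- function(X) {
  X <- check_data_matrix(X)
  svd(X, nu = 0L, nv = 0L)$d
}

#' Nuclear-norm clustering objective NN(A)
#'
#' The quantity minimized by [run_nnc()]: the nuclear norm of the pooled
#' within-cluster residual of M under assignment A. Zero exactly when every
#' cluster's rows are identical.
#'
#' @inheritParams cluster_means
#' @return non-negative scalar.
#' @examples
#' nnc_objective(rbind(c(1, 0), c(-1, 0)), c(0, 0), K = 1) # sqrt(2)
#' @export
nnc_objective <- function(M, A, K) {
  nuclear_norm(pooled_residual(M, A, K))
}

# Fast unchecked objective for the annealer's inner loop: M validated once
# upstream, A already a legal integer vector.
objective_unchecked_ <- function(M, A, K) {
  counts <- tabulate(A + 1L, nbins = K)
  centers <- matrix(0, nrow = K, ncol = ncol(M))
  sums <- rowsum(M, group = A)
  present <- as.integer(rownames(sums)) + 1L
  centers[present, ] <- sums / counts[present]
  sum(svd(M - centers[A + 1L, , drop = FALSE], nu = 0L, nv = 0L)$d)
}
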