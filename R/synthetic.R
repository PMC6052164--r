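#' Labeled Gaussian blob generator
#'
#' Draws K clusters of multivariate-normal points, the standard synthetic
#' regime for exercising a clusterer: cluster k contributes
#' `n_per_cluster[k]` rows with covariance
#' `noise_sd^2 * ((1 - correlation) * I + correlation * J)` (equicorrelated
#' features). When `centers` is not given, centers are auto-spaced along the
#' first coordinate at intervals of `separation * noise_sd`, so `separation`
#' is the between-center distance in units of the per-feature noise sd:
#' large values (e.g. 10) give linearly separable clusters, small values
#' (e.g. 2) give overlapping ones.
#'
#' @param n_per_cluster integer vector of K cluster sizes.
#' @param p feature count.
#' @param centers optional K x p matrix of cluster centers; overrides
#'   `separation`.
#' @param separation center spacing in units of `noise_sd` (default 10).
#' @param noise_sd per-feature noise standard deviation (default 1).
#' @param correlation common pairwise feature correlation rho, `0 <= rho < 1`.
#' @param seed optional integer seed (caller's RNG state restored).
#' @return list with `values` (n x p matrix, columns `f1..fp`), `labels`
#'   (length-n 0-based integer truth), `centers`, `K`.
#' @examples
#' b <- gaussian_blobs(c(50, 50, 50), p = 4, separation = 10, seed = 1)
#' table(b$labels)
#' @export
gaussian_blobs <- function(n_per_cluster, p, centers = NULL, separation = 10,
                           noise_sd = 1, correlation = 0, seed = NULL) {
  K <- length(n_per_cluster)
  stopifnot(K >= 1L, all(n_per_cluster >= 1L), p >= 1L, noise_sd > 0)
  if (correlation < 0 || correlation >= 1) {
    stop("correlation must be in [0, 1)", call. = FALSE)
  }
  if (is.null(centers)) {
    centers <- matrix(0, nrow = K, ncol = p)
    centers[, 1L] <- (seq_len(K) - 1L) * separation * noise_sd
  } else {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == K, ncol(centers) == p)
  }
  n <- sum(n_per_cluster)
  labels <- rep(seq_len(K) - 1L, times = n_per_cluster)
  sigma <- noise_sd^2 * ((1 - correlation) * diag(p) +
                           correlation * matrix(1, p, p))
  L <- chol(sigma)
  values <- with_seed_(seed, {
    Z <- matrix(rnorm(n * p), nrow = n, ncol = p)
    Z %*% L + centers[labels + 1L, , drop = FALSE]
  })
  colnames(values) <- paste0("f", seq_len(p))
  list(values = values, labels = labels, centers = centers, K = K)
}

#' Inject heavy outliers into a data matrix
#'
#' Displaces `floor(fraction * n)` randomly chosen rows by a uniformly random
#' direction of length `magnitude * sd(M)` (overall entry-wise sd of the
#' data), leaving every other row bit-identical. Rows are displaced in place,
#' not appended, so any accompanying truth labels stay aligned.
#'
#' @param M numeric n x p matrix.
#' @param fraction fraction of rows to displace, in `[0, 0.5]`.
#' @param magnitude displacement length in units of the data sd.
#' @param seed optional integer seed.
#' @return list with `values` (modified matrix) and `outliers` (sorted
#'   1-based indices of displaced rows).
#' @export
inject_outliers <- function(M, fraction, magnitude, seed = NULL) {
  M <- check_data_matrix(M)
  stopifnot(fraction >= 0, fraction <= 0.5, magnitude >= 0)
  n <- nrow(M)
  p <- ncol(M)
  n_out <- floor(fraction * n)
  if (n_out == 0L) {
    return(list(values = M, outliers = integer(0)))
  }
  scale <- magnitude * sd(as.vector(M))
  with_seed_(seed, {
    idx <- sort(sample.int(n, size = n_out))
    for (i in idx) {
      dir <- rnorm(p)
      M[i, ] <- M[i, ] + dir / sqrt(sum(dir^2)) * scale
    }
    list(values = M, outliers = idx)
  })
}
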