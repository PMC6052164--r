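# Independent oracles used by the property and acceptance tests. These stay
# deliberately naive: eigen decomposition instead of SVD, exhaustive
# enumeration instead of dynamic programming / annealing.

# Nuclear norm via the eigenvalues of X'X (independent eigen path).
# Eigenvalues below the numerical-rank threshold dim * eps * lambda_max are
# zero up to round-off; without clamping them, sqrt() inflates that noise
# from eps * ||X||^2 to sqrt(eps) * ||X||, which would swamp the 1e-8
# comparison for no reason related to either code path.
nn_eigen_oracle <- function(X) {
  ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  ev[ev < length(ev) * .Machine$double.eps * max(ev, 0)] <- 0
  sum(sqrt(pmax(ev, 0)))
}

# Macro-F by exhaustive enumeration of every partial one-to-one matching of
# classes to clusters (each class may also stay unmatched, scoring 0).
brute_macro_f <- function(truth, pred, K = NULL) {
  tab <- contingency_table(truth, pred, K = K)
  F <- pair_f_matrix(tab$counts)
  C <- nrow(F)
  K <- ncol(F)
  best <- -Inf
  rec <- function(ci, used, acc) {
    if (ci > C) {
      best <<- max(best, acc)
      return(invisible())
    }
    rec(ci + 1L, used, acc) # class ci unmatched
    for (k in seq_len(K)) {
      if (!used[k]) {
        used[k] <- TRUE
        rec(ci + 1L, used, acc + F[ci, k])
        used[k] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, K), 0)
  best / C
}

# Global minimum of the NNC objective by enumerating all K^n assignments.
brute_min_nn <- function(M, K) {
  n <- nrow(M)
  grid <- as.matrix(expand.grid(rep(list(0:(K - 1L)), n)))
  min(apply(grid, 1L, function(a) nnc_objective(M, a, K)))
}

# Random orthogonal matrix via QR of a Gaussian matrix.
random_orthogonal <- function(p) {
  qr.Q(qr(matrix(rnorm(p * p), p, p)))
}
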