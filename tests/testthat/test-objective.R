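test_that("cluster_means computes per-cluster means and sizes", {
  cm <- cluster_means(rbind(c(0, 0), c(2, 2)), c(0, 0), K = 1)
  expect_equal(cm$centers, rbind(c(1, 1)))
  expect_equal(cm$counts, 2L)

  cm <- cluster_means(rbind(c(1, 0), c(3, 0), c(5, 10)), c(0, 0, 1), K = 2)
  expect_equal(cm$centers, rbind(c(2, 0), c(5, 10)))
  expect_equal(cm$counts, c(2L, 1L))

  # empty cluster: count 0 and an all-zero placeholder center
  cm <- cluster_means(rbind(c(1, 1)), 0L, K = 2)
  expect_equal(cm$counts, c(1L, 0L))
  expect_equal(cm$centers[2, ], c(0, 0))
})

test_that("pooled_residual subtracts each row's cluster center", {
  expect_equal(pooled_residual(rbind(c(1, 0), c(-1, 0)), c(0, 0), K = 1),
               rbind(c(1, 0), c(-1, 0)))
  expect_equal(pooled_residual(rbind(c(1, 0), c(3, 0), c(5, 10)),
                               c(0, 0, 1), K = 2),
               rbind(c(-1, 0), c(1, 0), c(0, 0)))
  # identical rows within each cluster -> zero residual
  M <- rbind(c(1, 2), c(1, 2), c(9, 9))
  expect_equal(pooled_residual(M, c(0, 0, 1), K = 2), matrix(0, 3, 2))
})

test_that("within-cluster residual rows sum to zero", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    p <- sample(1:6, 1)
    K <- sample(1:3, 1)
    M <- matrix(rnorm(n * p), n, p)
    A <- sample.int(K, n, replace = TRUE) - 1L
    R <- pooled_residual(M, A, K)
    for (k in unique(A)) {
      expect_equal(colSums(R[A == k, , drop = FALSE]), rep(0, p),
                   tolerance = 1e-10)
    }
  }
})

test_that("nuclear_norm matches known values and rejects bad input", {
  expect_equal(nuclear_norm(matrix(0, 3, 3)), 0)
  expect_equal(nuclear_norm(diag(c(3, 4))), 7)
  expect_equal(nuclear_norm(matrix(1, 2, 2)), 2)
  expect_error(nuclear_norm(matrix(c(1, Inf, 0, 1), 2, 2)), "non-finite")
})

test_that("nuclear_norm agrees with the independent eigen oracle", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(1:12, 1)
    p <- sample(1:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    expect_equal(nuclear_norm(X), nn_eigen_oracle(X), tolerance = 1e-8)
  }
})

test_that("nuclear_norm is unitarily invariant and absolutely homogeneous", {
  set.seed(31)
  for (rep in 1:20) {
    p <- sample(2:8, 1)
    X <- matrix(rnorm(6 * p), 6, p)
    Q <- random_orthogonal(p)
    expect_equal(nuclear_norm(X %*% Q), nuclear_norm(X), tolerance = 1e-8)
    c0 <- rnorm(1, sd = 3)
    expect_equal(nuclear_norm(c0 * X), abs(c0) * nuclear_norm(X),
                 tolerance = 1e-8)
  }
})

test_that("singular_spectrum is non-negative, sorted, and sums to the norm", {
  set.seed(5)
  X <- matrix(rnorm(40), 8, 5)
  s <- singular_spectrum(X)
  expect_length(s, 5)
  expect_true(all(s >= 0))
  expect_true(all(diff(s) <= 0))
  expect_equal(sum(s), nuclear_norm(X))
})

test_that("objective known values: zero law and K = 1", {
  # clusters of identical rows score exactly 0
  M <- rbind(c(1, 2), c(1, 2), c(5, 5), c(5, 5))
  expect_equal(nnc_objective(M, c(0, 0, 1, 1), K = 2), 0)
  expect_equal(nnc_objective(rbind(c(1, 0), c(-1, 0)), c(0, 0), K = 1),
               sqrt(2), tolerance = 1e-12)
  # K = 1 equals the nuclear norm of the column-centered matrix
  set.seed(41)
  M <- matrix(rnorm(50), 10, 5)
  centered <- sweep(M, 2, colMeans(M))
  expect_equal(nnc_objective(M, rep(0, 10), K = 1), nuclear_norm(centered))
})

test_that("objective is invariant to label and row permutations", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    p <- sample(2:5, 1)
    K <- 3
    M <- matrix(rnorm(n * p), n, p)
    A <- sample.int(K, n, replace = TRUE) - 1L
    base <- nnc_objective(M, A, K)
    expect_gte(base, 0)
    # permute cluster labels
    perm <- sample(0:(K - 1))
    expect_equal(nnc_objective(M, perm[A + 1], K), base, tolerance = 1e-10)
    # permute rows of M and entries of A identically
    ord <- sample(n)
    expect_equal(nnc_objective(M[ord, , drop = FALSE], A[ord], K), base,
                 tolerance = 1e-10)
  }
})

test_that("objective is zero exactly when the residual vanishes", {
  set.seed(47)
  for (rep in 1:20) {
    M <- matrix(rnorm(24), 8, 3)
    A <- sample(0:1, 8, replace = TRUE)
    R <- pooled_residual(M, A, 2)
    obj <- nnc_objective(M, A, 2)
    if (max(abs(R)) < 1e-10) {
      expect_lt(obj, 1e-10)
    } else {
      expect_gt(obj, 1e-10)
    }
  }
})

test_that("assignment validation rejects malformed label vectors", {
  M <- matrix(rnorm(6), 3, 2)
  expect_error(nnc_objective(M, c(0, 1), K = 2), "length")
  expect_error(nnc_objective(M, c(0, 1, 2), K = 2), "labels")
  expect_error(nnc_objective(M, c(0, -1, 1), K = 2), "labels")
})
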