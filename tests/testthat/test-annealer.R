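test_that("initialize_assignment draws uniform labels reproducibly", {
  expect_equal(initialize_assignment(5, 1, seed = 1), rep(0L, 5))
  expect_identical(initialize_assignment(50, 3, seed = 9),
                   initialize_assignment(50, 3, seed = 9))
  # frequencies within 4 binomial sd of n/K
  a <- initialize_assignment(10000, 4, seed = 2)
  expect_true(all(a %in% 0:3))
  freq <- tabulate(a + 1, nbins = 4)
  bound <- 4 * sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(freq - 2500) <= bound))
  expect_warning(initialize_assignment(2, 5, seed = 1), "empty")
})

test_that("propose_move changes at most one label, uniformly over samples", {
  A <- rep(0L, 6)
  set.seed(3)
  pm <- propose_move(A, K = 1)
  expect_identical(pm$assignment, A) # K = 1 is always a no-op
  set.seed(4)
  counts <- integer(10)
  A <- sample(0:2, 10, replace = TRUE)
  for (i in 1:10000) {
    pm <- propose_move(A, K = 3)
    expect_lte(sum(pm$assignment != A), 1)
    counts[pm$index] <- counts[pm$index] + 1L
  }
  bound <- 4 * sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(counts - 1000) <= bound))
})

test_that("temperature follows N/(divisor*(iter+1)) and decreases strictly", {
  expect_equal(temperature(0, 20000), 200)
  expect_equal(temperature(19999, 20000), 0.01)
  tt <- temperature(0:999, 1000)
  expect_true(all(diff(tt) < 0))
  expect_equal(temperature(0, 1000, divisor = 10), 100)
})

test_that("accept_move: improvements and ties always, large uphill never", {
  set.seed(8)
  for (i in 1:50) {
    nn <- runif(1, 0, 100)
    temp <- runif(1, 1e-3, 10)
    expect_true(accept_move(nn, nn - runif(1, 0, 5), temp))
    expect_true(accept_move(nn, nn, temp))
  }
  # moderate uphill at high temperature is accepted at about exp(-d/T)
  set.seed(9)
  acc <- mean(replicate(4000, accept_move(0, 1, 2)))
  expect_equal(acc, exp(-0.5), tolerance = 0.05)
})

test_that("run_nnc is deterministic and internally consistent", {
  b <- gaussian_blobs(c(10, 10), p = 3, separation = 8, seed = 5)
  r1 <- run_nnc(b$values, K = 2, iterations = 300, seed = 7,
                trajectory = TRUE)
  r2 <- run_nnc(b$values, K = 2, iterations = 300, seed = 7,
                trajectory = TRUE)
  expect_identical(r1, r2)
  # trajectory invariants
  tr <- r1$trajectory
  expect_equal(nrow(tr), 300)
  expect_true(all(diff(tr$nn_best) <= 0))
  expect_true(all(tr$nn >= 0))
  expect_true(all(diff(tr$temp) < 0))
  expect_lte(r1$best_nn, min(tr$nn))
  expect_lte(r1$best_nn, r1$final_nn)
  # reported objectives match a from-scratch recomputation
  expect_equal(r1$final_nn, nnc_objective(b$values, r1$final_assignment, 2))
  expect_equal(r1$best_nn, nnc_objective(b$values, r1$best_assignment, 2))
})

test_that("run_nnc report modes and K = 1 behave as documented", {
  b <- gaussian_blobs(c(8, 8), p = 2, separation = 6, seed = 6)
  rb <- run_nnc(b$values, K = 2, iterations = 400, seed = 1, report = "best")
  expect_identical(rb$assignment, rb$best_assignment)
  rf <- run_nnc(b$values, K = 2, iterations = 400, seed = 1, report = "final")
  expect_identical(rf$assignment, rf$final_assignment)
  # same seed => same search path regardless of report mode
  expect_equal(rb$best_nn, rf$best_nn)

  M <- matrix(rnorm(30), 10, 3)
  r1 <- run_nnc(M, K = 1, iterations = 5, seed = 1)
  expect_equal(r1$assignment, rep(0L, 10))
  expect_equal(r1$final_nn, nuclear_norm(sweep(M, 2, colMeans(M))))
})

test_that("run_nnc does not perturb the caller's RNG stream", {
  b <- gaussian_blobs(c(5, 5), p = 2, seed = 1)
  set.seed(123)
  x1 <- rnorm(3)
  set.seed(123)
  invisible(run_nnc(b$values, K = 2, iterations = 20, seed = 42))
  x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("run_nnc rejects degenerate input", {
  expect_error(run_nnc(matrix(numeric(0), 0, 2), K = 1), "at least one")
  expect_error(run_nnc(rbind(c(1, 2)), K = 1, iterations = 0), "iterations")
})
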