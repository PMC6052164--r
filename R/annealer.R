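#' Random initial assignment
#'
#' Draws each of the n labels independently and uniformly from `0..K-1`.
#'
#' @param n sample count.
#' @param K cluster count. `K > n` is permitted (some clusters are then
#'   necessarily empty) but warned about.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return integer vector of length n with labels in `0..K-1`.
#' @export
initialize_assignment <- function(n, K, seed = NULL) {
  stopifnot(n >= 1L, K >= 1L)
  if (K > n) {
    warning("K > n: some clusters will necessarily be empty", call. = FALSE)
  }
  with_seed_(seed, sample.int(K, size = n, replace = TRUE) - 1L)
}

#' Single-sample relabel proposal
#'
#' Picks one sample uniformly at random and redraws its label uniformly from
#' `0..K-1`. The new label may equal the old one (a no-op proposal); the
#' proposal kernel is deliberately inclusive, so the Hamming distance between
#' A and the proposal is at most 1.
#'
#' @param A current integer assignment (labels in `0..K-1`).
#' @param K cluster count.
#' @return list with `assignment` (the proposal) and `index` (1-based index
#'   of the redrawn sample).
#' @export
propose_move <- function(A, K) {
  n <- length(A)
  i <- sample.int(n, size = 1L)
  A2 <- A
  A2[i] <- sample.int(K, size = 1L) - 1L
  list(assignment = A2, index = i)
}

#' Annealing temperature schedule
#'
#' `T(iter) = N / (divisor * (iter + 1))` with 0-based `iter`, so the run
#' starts at `T = N / divisor` and ends at `T = 1 / divisor`. Strictly
#' decreasing in `iter`.
#'
#' @param iter 0-based iteration index, `0 <= iter < N`.
#' @param N total iteration budget.
#' @param divisor schedule divisor, default 100.
#' @return positive temperature.
#' @examples
#' temperature(0, 20000) # 200
#' temperature(19999, 20000) # 0.01
#' @export
temperature <- function(iter, N, divisor = 100) {
  stopifnot(all(iter >= 0), all(iter < N), divisor > 0)
  N / (divisor * (iter + 1.0))
}

#' Metropolis acceptance rule
#'
#' Accepts the proposal iff `Uniform(0,1) < exp((nn - nn_prime) / temp)`.
#' Improvements and equal-cost moves have exponent >= 0, hence exp >= 1, and
#' are accepted without consuming a uniform draw (identical behavior, no
#' overflow). For worsening moves the exponent is negative, so `exp()` cannot
#' overflow; at very negative exponents it underflows to 0 and the move is
#' effectively never accepted.
#'
#' @param nn current objective value.
#' @param nn_prime proposed objective value.
#' @param temp positive temperature.
#' @return logical: accept the proposal?
#' @export
accept_move <- function(nn, nn_prime, temp) {
  stopifnot(temp > 0, is.finite(nn), is.finite(nn_prime))
  expo <- (nn - nn_prime) / temp
  if (expo >= 0) {
    return(TRUE)
  }
  runif(1L) < exp(expo)
}

#' Nuclear Norm Clustering by simulated annealing
#'
#' Minimizes [nnc_objective()] over label assignments. Starting from a
#' uniform random assignment, each iteration proposes relabeling one random
#' sample to a random cluster, evaluates the full residual SVD of the
#' proposal, and accepts by the Metropolis rule under the cooling schedule
#' `T = N / (divisor * (iter + 1))`. Runs exactly `iterations` iterations.
#'
#' One seeded RNG stream drives initialization, proposals and acceptance
#' draws in that fixed order, so a run is exactly replayable from
#' `(M, config, seed)`. The cost per iteration is one SVD of the n x p
#' residual, i.e. O(n * p * min(n, p)); the whole run is
#' O(n * p * min(n, p) * iterations).
#'
#' @param M numeric n x p data matrix (normalize first; see
#'   [normalize_matrix()]).
#' @param K desired number of clusters.
#' @param iterations annealing budget N; default 20000 is usually enough,
#'   200000 for harder problems.
#' @param seed optional integer seed (caller's RNG state is restored).
#' @param report `"final"` returns the assignment held after the last
#'   iteration (the literal algorithm); `"best"` returns the lowest-objective
#'   assignment seen during the run. Both are always recorded in the result.
#' @param schedule_divisor divisor in the temperature schedule (default 100).
#' @param trajectory if TRUE, record per-iteration `(iter, temp, nn, nn_best,
#'   accepted)` in the result.
#' @return object of class `"nnc_result"`: a list with `assignment` (per
#'   `report`), `final_assignment`, `best_assignment`, `final_nn`, `best_nn`,
#'   `trajectory` (data.frame or NULL), and the config echo (`K`,
#'   `iterations`, `seed`, `report`, `schedule_divisor`, `n`, `p`).
#' @examples
#' b <- gaussian_blobs(c(20, 20), p = 2, separation = 10, seed = 1)
#' fit <- run_nnc(normalize_matrix(b$values), K = 2, iterations = 500, seed = 1)
#' macro_f_score(b$labels, fit$assignment)$macro_f
#' @export
run_nnc <- function(M, K, iterations = 20000L, seed = NULL,
                    report = c("final", "best"), schedule_divisor = 100,
                    trajectory = FALSE) {
  report <- match.arg(report)
  M <- check_data_matrix(M)
  stopifnot(K >= 1L, iterations >= 1L, schedule_divisor > 0)
  n <- nrow(M)
  if (n < K) {
    warning("K > n: some clusters will necessarily be empty", call. = FALSE)
  }
  N <- as.integer(iterations)

  with_seed_(seed, {
    A <- sample.int(K, size = n, replace = TRUE) - 1L
    nn <- objective_unchecked_(M, A, K)
    best_nn <- nn
    best_A <- A

    traj <- if (trajectory) {
      list(iter = integer(N), temp = numeric(N), nn = numeric(N),
           nn_best = numeric(N), accepted = logical(N))
    }

    for (it in seq_len(N) - 1L) {
      i <- sample.int(n, size = 1L)
      new_label <- sample.int(K, size = 1L) - 1L
      A2 <- A
      A2[i] <- new_label
      nn_prime <- objective_unchecked_(M, A2, K)
      temp <- N / (schedule_divisor * (it + 1.0))
      expo <- (nn - nn_prime) / temp
      acc <- if (expo >= 0) TRUE else runif(1L) < exp(expo)
      if (acc) {
        A <- A2
        nn <- nn_prime
        if (nn < best_nn) {
          best_nn <- nn
          best_A <- A
        }
      }
      if (trajectory) {
        traj$iter[it + 1L] <- it
        traj$temp[it + 1L] <- temp
        traj$nn[it + 1L] <- nn
        traj$nn_best[it + 1L] <- best_nn
        traj$accepted[it + 1L] <- acc
      }
    }

    res <- list(
      assignment = if (report == "best") best_A else A,
      final_assignment = A,
      best_assignment = best_A,
      final_nn = nn,
      best_nn = best_nn,
      trajectory = if (trajectory) as.data.frame(traj),
      K = as.integer(K),
      iterations = N,
      seed = seed,
      report = report,
      schedule_divisor = schedule_divisor,
      n = n,
      p = ncol(M)
    )
    class(res) <- "nnc_result"
    res
  })
}

#' @export
print.nnc_result <- function(x, ...) {
  cat("Nuclear Norm Clustering result\n")
  cat(sprintf("  n = %d samples, p = %d features, K = %d clusters\n",
              x$n, x$p, x$K))
  cat(sprintf("  iterations = %d, seed = %s, report = %s\n",
              x$iterations, if (is.null(x$seed)) "NULL" else x$seed,
              x$report))
  cat(sprintf("  final NN = %.6f, best NN = %.6f\n", x$final_nn, x$best_nn))
  cat(sprintf("  cluster sizes (reported assignment): %s\n",
              paste(tabulate(x$assignment + 1L, nbins = x$K),
                    collapse = ", ")))
  invisible(x)
}
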