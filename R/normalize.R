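#' Normalize a raw data matrix column-wise
#'
#' Prepares a raw feature matrix for clustering. `zscore` (the default used
#' throughout the package) centers each column to mean 0 and scales it to
#' sample standard deviation 1, so that all features enter the residual SVD
#' on a common scale. `minmax` maps each column to `[0, 1]`. `none` passes the
#' matrix through unchanged.
#'
#' A constant column cannot be scaled; under `zscore` or `minmax` it is mapped
#' to all zeros with a warning rather than producing division by zero.
#'
#' @param raw numeric matrix or data frame, samples in rows, features in
#'   columns; no missing or non-finite values.
#' @param method one of `"zscore"`, `"minmax"`, `"none"`.
#' @return numeric matrix of the same dimensions, with column names retained.
#' @examples
#' normalize_matrix(cbind(a = c(1, 2, 3), b = c(10, 20, 30)))
#' @export
normalize_matrix <- function(raw, method = c("zscore", "minmax", "none")) {
  method <- match.arg(method)
  M <- check_data_matrix(raw)
  if (method == "none") {
    return(M)
  }
  constant <- apply(M, 2L, function(x) max(x) == min(x))
  if (any(constant)) {
    warning(sprintf("%d constant column(s) mapped to zeros under %s: %s",
                    sum(constant), method,
                    paste(which(constant), collapse = ", ")),
            call. = FALSE)
  }
  out <- if (method == "zscore") {
    mu <- colMeans(M)
    s <- apply(M, 2L, sd)
    s[constant] <- 1
    sweep(sweep(M, 2L, mu, "-"), 2L, s, "/")
  } else {
    lo <- apply(M, 2L, min)
    span <- apply(M, 2L, max) - lo
    span[constant] <- 1
    sweep(sweep(M, 2L, lo, "-"), 2L, span, "/")
  }
  out[, constant] <- 0
  out
}
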