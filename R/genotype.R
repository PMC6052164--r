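#' Toy case/control biallelic genotype panel
#'
#' Emulates the shape of a small GWAS panel: n = cases + controls samples by
#' m SNPs, genotypes coded as minor-allele counts in `{0, 1, 2}` drawn as
#' Binomial(2, f) under Hardy-Weinberg. Each SNP's control-group minor allele
#' frequency f is drawn uniformly from `maf_range`; at the `n_causal` causal
#' SNPs the case group uses frequency `f + delta`, a direct allele-frequency
#' shift between cases and controls. All draws are seed-deterministic.
#'
#' @param n_cases,n_controls group sizes (default 500 each).
#' @param m_snps number of SNPs (default 500).
#' @param n_causal number of causal SNPs (default 0, a null panel).
#' @param delta case-control allele-frequency shift at causal SNPs; every
#'   resulting frequency must stay inside (0, 1).
#' @param maf_range length-2 range for control minor allele frequencies.
#' @param seed optional integer seed.
#' @return object of class `"genotype_panel"`: list with `genotypes`
#'   (n x m integer matrix, columns `snp1..snpm`), `phenotype` (length-n,
#'   1 = case, 0 = control), `causal_snps` (1-based indices), `maf`
#'   (control frequencies), `delta`.
#' @examples
#' panel <- genotype_panel(n_cases = 50, n_controls = 50, m_snps = 20,
#'                         n_causal = 2, delta = 0.3, seed = 1)
#' table(panel$genotypes[, panel$causal_snps[1]], panel$phenotype)
#' @export
genotype_panel <- function(n_cases = 500L, n_controls = 500L, m_snps = 500L,
                           n_causal = 0L, delta = 0, maf_range = c(0.05, 0.5),
                           seed = NULL) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, m_snps >= 1L,
            n_causal >= 0L, n_causal <= m_snps)
  if (maf_range[1L] <= 0 || maf_range[2L] >= 1 ||
      maf_range[1L] > maf_range[2L]) {
    stop("maf_range must satisfy 0 < lo <= hi < 1", call. = FALSE)
  }
  if (maf_range[1L] + delta <= 0 || maf_range[2L] + delta >= 1) {
    stop("delta pushes case allele frequencies outside (0, 1)", call. = FALSE)
  }
  n <- n_cases + n_controls
  with_seed_(seed, {
    maf <- runif(m_snps, maf_range[1L], maf_range[2L])
    causal <- if (n_causal > 0L) sort(sample.int(m_snps, n_causal)) else integer(0)
    f_case <- maf
    f_case[causal] <- maf[causal] + delta
    G <- matrix(0L, nrow = n, ncol = m_snps,
                dimnames = list(NULL, paste0("snp", seq_len(m_snps))))
    case_rows <- seq_len(n_cases)
    ctrl_rows <- n_cases + seq_len(n_controls)
    for (j in seq_len(m_snps)) {
      G[case_rows, j] <- rbinom(n_cases, 2L, f_case[j])
      G[ctrl_rows, j] <- rbinom(n_controls, 2L, maf[j])
    }
    res <- list(genotypes = G,
                phenotype = c(rep(1L, n_cases), rep(0L, n_controls)),
                causal_snps = causal,
                maf = maf,
                delta = delta)
    class(res) <- "genotype_panel"
    res
  })
}

#' Rank SNPs by allelic chi-square association
#'
#' For each SNP, builds the 2 x 2 allele-count table (minor vs major allele
#' counts in cases vs controls; each sample contributes two alleles, so a
#' group's minor-allele count is `2 * #hom + #het`) and computes the 1-df
#' Pearson chi-square statistic without continuity correction. SNPs are
#' ranked by ascending p-value, ties broken by SNP index; a monomorphic SNP
#' (one allele absent from the pooled sample) gets p = 1 by convention and
#' ranks last.
#'
#' @param panel a `"genotype_panel"`, or any list with `genotypes`
#'   (n x m matrix of 0/1/2) and `phenotype` (length-n, 1 = case,
#'   0 = control, both groups non-empty).
#' @param top_m optionally keep only the `top_m` best-ranked SNPs.
#' @return data.frame ordered by rank with columns `snp` (1-based index),
#'   `chisq`, `p_value`.
#' @examples
#' panel <- genotype_panel(n_cases = 100, n_controls = 100, m_snps = 50,
#'                         n_causal = 5, delta = 0.3, seed = 1)
#' head(rank_snps_allelic(panel), 5)
#' @export
rank_snps_allelic <- function(panel, top_m = NULL) {
  G <- panel$genotypes
  pheno <- panel$phenotype
  stopifnot(nrow(G) == length(pheno))
  cases <- pheno == 1L
  n_case <- sum(cases)
  n_ctrl <- sum(!cases)
  if (n_case == 0L || n_ctrl == 0L) {
    stop("both phenotype groups must be non-empty", call. = FALSE)
  }
  a <- colSums(G[cases, , drop = FALSE])        # minor alleles, cases
  b <- 2 * n_case - a                           # major alleles, cases
  cc <- colSums(G[!cases, , drop = FALSE])      # minor alleles, controls
  d <- 2 * n_ctrl - cc                          # major alleles, controls
  N <- 2 * (n_case + n_ctrl)
  col1 <- a + cc
  col2 <- b + d
  mono <- col1 == 0 | col2 == 0
  denom <- (a + b) * (cc + d) * col1 * col2
  chisq <- ifelse(mono, 0, N * (a * d - b * cc)^2 / pmax(denom, 1))
  p <- pchisq(chisq, df = 1L, lower.tail = FALSE)
  p[mono] <- 1
  # monomorphic SNPs rank after any polymorphic SNP that happens to hit p = 1
  ord <- order(p, mono, seq_along(p))
  out <- data.frame(snp = ord, chisq = chisq[ord], p_value = p[ord],
                    row.names = NULL)
  if (!is.null(top_m)) out <- head(out, top_m)
  out
}
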