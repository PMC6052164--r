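---
title: "Nuclear norm clustering: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear norm clustering: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`nncluster` partitions the n rows of a numeric matrix M into K clusters by
minimizing

$$\mathrm{NN}(A) \;=\; \Big\lVert M - C_{A}\Big\rVert_{*}
 \;=\; \sum_j \sigma_j\!\big(M - C_A\big),$$

where $A \in \{0,\dots,K-1\}^n$ is the label vector, $C_A$ stacks each row's
cluster mean, and $\lVert\cdot\rVert_*$ is the nuclear norm, the sum of
singular values of the pooled within-cluster residual. Two properties
motivate the objective over the within-cluster sum of squares:

* **Robustness.** The nuclear norm is an L1 norm on the singular-value
  spectrum. A single displaced row inflates the squared error quadratically
  but enters the spectrum roughly linearly, so heavy outliers distort the
  optimum less.
* **Correlation handling.** The SVD internally orthogonalizes the features;
  residual energy shared among correlated features is counted once per
  direction rather than once per feature, down-weighting redundant columns.

The objective is invariant to permutations of the cluster labels and
equivariant under simultaneous row permutations of M and A; it is zero
exactly when every cluster consists of identical rows. Empty clusters are
legal states: a cluster no row references contributes nothing to the
residual (its placeholder center is never subtracted from anything), so
annealing moves may empty and refill clusters freely.

## Optimization

Minimization is a plain single-site simulated annealing over assignments:

1. draw the initial A uniformly at random;
2. for iterations $iter = 0, \dots, N-1$: relabel one uniformly chosen
   sample to a uniformly chosen cluster (possibly its current one), evaluate
   the proposal's objective by a **full SVD recomputation**, and accept iff
   $U(0,1) < \exp\big((\mathrm{NN}-\mathrm{NN}')/T\big)$ with
   $T = N / (100\,(iter+1))$.

Deliberate consequences of taking the update rules literally:

* Improving **and equal-cost** proposals are always accepted
  ($\exp(0) = 1$ beats any uniform draw), so the chain drifts across
  objective plateaus. Acceptance is decided without consuming a uniform draw
  when the exponent is $\ge 0$; for negative exponents `exp()` cannot
  overflow and underflows harmlessly to 0. This is an exact implementation
  of the printed rule with no floating-point hazard.
* The same N appears as iteration budget and in the temperature numerator,
  so the schedule always runs from $T = N/100$ down to $T = 1/100$
  regardless of problem size. The divisor (default 100) is exposed as
  `schedule_divisor` but changing it departs from the reference schedule.
* No incremental SVD shortcuts: each of the N evaluations decomposes the
  full n × p residual, making the run cost
  $O(n\,p\,\min(n,p)\,N)$. At the package's scales (hundreds of samples,
  tens of features) a 20000-iteration run takes a couple of seconds in
  plain R, so no compiled code is used.

**Reported assignment.** The literal algorithm returns the assignment held
after the last iteration (`report = "final"`). Because equal-or-better moves
are always accepted, the final state can have drifted off the best state
visited; `report = "best"` returns the lowest-objective assignment seen.
Both are always recorded in the result, `"final"` is the default for
fidelity, `"best"` is what we recommend and use in the recovery tests.

**Reproducibility.** One seeded RNG stream drives initialization, proposals
and acceptance draws in that fixed order; `run_nnc` restores the caller's
RNG state. Identical (data, config, seed) gives bit-identical results, which
the determinism tests check down to the output bytes.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `K` | user input | desired cluster count; the method never selects it |
| `iterations` (N) | 20000 | annealing budget; 20000 is usually enough, 200000 for hard or larger problems |
| `schedule_divisor` | 100 | temperature scale of the schedule; fixed by the reference algorithm |
| `report` | `"final"` | `"final"` = literal algorithm, `"best"` = best-seen (recommended) |
| `normalize` | `"zscore"` | per-column standardization before clustering (see below) |
| `matching` | `"optimal"` | cluster-to-class matching convention for macro-F |

## Normalization

The reference algorithm operates on a "normalized" matrix without defining
the normalization. The package defaults to per-column z-scores, the
conventional choice that makes heterogeneous features commensurate inside
one SVD; `minmax` and `none` are selectable. Constant columns cannot be
scaled and are mapped to all-zeros with a warning. Two caveats discovered
while validating:

* Because the temperature range $[1/100,\,N/100]$ is fixed, the *scale* of
  the data determines how cold the chain effectively runs. On z-scored data
  whose objective is ~40 with per-move deltas of ~0.05, the chain stays
  relatively hot for most of the budget and recovery suffers; on the same
  data at its raw scale the deltas are an order of magnitude larger and
  recovery is immediate. Accordingly, the synthetic-recovery tests run on
  the generator's raw output — its features are constructed on a common
  unit (noise sd 1), so standardization would only shrink the
  between-cluster signal. For real tables with heterogeneous units z-score
  remains the sensible default.
* Normalization is a pre-processing step: the objective, the annealer and
  the evaluation never renormalize internally.

## Evaluation: macro-averaged F

`macro_f_score` builds the C × K class-by-cluster contingency table, scores
every (class, cluster) pair by F1 (precision from the cluster column, recall
from the class row, $F = 0$ when $P + R = 0$), and averages per-class F
**unweighted**. Two matching conventions are exposed:

* `"optimal"` (default): the one-to-one class↔cluster matching maximizing
  the summed per-class F, found exactly by dynamic programming over cluster
  subsets ($O(C\,2^K)$, capped at K ≤ 20; ties broken toward the lower
  cluster index). Unmatched classes (forced when K < C) score 0; surplus
  clusters are ignored. This convention penalizes cluster collapse — an
  all-in-one-cluster prediction of a two-class truth scores 1/3, not ~0.8 —
  and is the one used throughout the tests.
* `"best-match"`: each class independently takes its best-F cluster; always
  ≥ the optimal-matching score. Provided for sensitivity analysis because
  the exact convention used in the original benchmarks is not recoverable.

The exhaustive-enumeration oracle in the test suite confirms the DP on all
random instances with C, K ≤ 4.

## The synthetic world

The generators state the world the claims are tested in; their defaults are
fixed and are not tuned against test outcomes.

* `gaussian_blobs`: K equicorrelated Gaussian clusters
  ($\Sigma = \sigma^2[(1-\rho)I + \rho J]$), centers auto-spaced along the
  first coordinate at `separation` × noise-sd intervals. `separation = 10`
  (the recovery setting) gives linearly separable clusters — the regime
  where the nuclear-norm objective is known to do best; `separation ≈ 2`
  gives overlap. Blobs emulate separability and feature correlation; they do
  **not** emulate non-convex shapes, unequal covariances, or categorical
  features, so a green recovery test establishes correct optimization on
  separable Gaussian structure, not state-of-the-art accuracy on arbitrary
  data.
* `inject_outliers` displaces `floor(fraction·n)` existing rows by a random
  direction of length `magnitude` × overall data sd, keeping truth labels
  aligned (rows are moved, never appended).
* `genotype_panel` draws Binomial(2, f) genotypes under Hardy–Weinberg with
  control-group MAF uniform on `maf_range` (default 0.05–0.5) and a direct
  case/control frequency shift `delta` at the causal SNPs; 500/500
  cases/controls and 500 SNPs mirror the scale of the GWAS protocol the
  package emulates. It does not model linkage disequilibrium, population
  structure, genotyping error or missingness.
* `rank_snps_allelic` uses the 1-df Pearson chi-square on the 2 × 2 allele
  count table **without** continuity correction (the emulated protocol names
  no variant; the uncorrected statistic is the textbook allelic test).
  Monomorphic SNPs get p = 1 by convention and rank after any polymorphic
  SNP that ties at p = 1; remaining ties break by SNP index.

## Numerical choices

* Singular values come from LAPACK via base `svd()`; they are stored
  non-increasing (the sum is order-invariant; ordering is for reproducible
  reporting).
* The independent test oracle computes
  $\sum\sqrt{\lambda_j(X^\top X)}$ via a symmetric eigen decomposition.
  Eigenvalues below the numerical-rank threshold
  $\dim \cdot \varepsilon \cdot \lambda_{\max}$ are clamped to zero before
  the square root: round-off noise of size $\varepsilon\lVert X\rVert^2$
  would otherwise be inflated to $\sqrt{\varepsilon}\,\lVert X\rVert$ and
  dominate a 1e−8 comparison. The clamp corrects the oracle's conditioning,
  not the implementation under test.
* Zero-objective checks use an absolute 1e−10 tolerance; equality checks of
  two SVD paths use 1e−8 relative.
* `temperature` uses 0-based iterations so the first iteration evaluates at
  exactly $N/100$.

## Known limitations

* Cost grows linearly in N with a full SVD per iteration; beyond a few
  thousand samples runs become slow, and the method is aimed at medium-size
  tables.
* Annealing is stochastic: different seeds may return different partitions,
  and on z-scored data the fixed schedule may need N = 200000 to converge.
* K is an input; no model-selection heuristic is provided.
* No missing-value handling, sparse inputs or out-of-core data; inputs must
  be fully numeric after the id/label columns are removed.
* Real-data scores reported by `scripts/uci_check.R` (e.g. macro F printed
  for the iris table) are indicative only: annealing is stochastic and the
  original normalization is unknown, so they are reported, never asserted.
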