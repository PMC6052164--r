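# nncluster

Nuclear norm clustering for numeric sample-by-feature tables, aimed at
biostatistics and epidemiology workflows (e.g. clustering case/control
subjects on a panel of top-associated SNPs) where classic squared-error
clustering is thrown off by outliers and correlated features.

## The method

Given a data matrix **M** (n samples × p features) and a desired cluster
count K, a label vector A ∈ {0,…,K−1}ⁿ induces the *pooled within-cluster
residual* matrix R with rows

R<sub>i·</sub> = M<sub>i·</sub> − C<sub>A[i]·</sub>,

where C<sub>k·</sub> is the mean of the rows assigned to cluster k. The
clustering objective is the **nuclear norm** (trace norm) of that residual,

NN(A) = ‖R‖<sub>*</sub> = Σ<sub>j</sub> σ<sub>j</sub>(R),

the sum of the singular values of R. Relative to the within-cluster *squared*
error minimized by k-means, the nuclear norm is an L1 measure on the
singular-value spectrum: it down-weights large outlying residuals and
penalizes residual energy spread across correlated directions, encouraging
compact, low-rank within-cluster structure.

NN(A) is minimized over label assignments by **simulated annealing**: each
iteration relabels one random sample to a random cluster, recomputes the
residual SVD, and accepts the proposal iff
`Uniform(0,1) < exp((NN − NN′)/T)` under the cooling schedule
`T = N / (100 · (iter + 1))` for an iteration budget N (default 20000; use
200000 for hard problems). Every evaluation is a full SVD, so a run costs
O(n · p · min(n, p) · N).

External evaluation uses the **macro-averaged F-score**: clusters are
matched one-to-one to true classes so as to maximize the summed per-class F1
(exact bitmask dynamic programming), and the per-class F1 values are
averaged unweighted. Cluster collapse therefore cannot score well.

## Worked example

```r
library(nncluster)

blobs <- gaussian_blobs(c(50, 50, 50), p = 4, separation = 10, seed = 1)
fit <- run_nnc(blobs$values, K = 3, iterations = 20000, seed = 1,
               report = "best")
print(fit)
#> Nuclear Norm Clustering result
#>   n = 150 samples, p = 4 features, K = 3 clusters
#>   iterations = 20000, seed = 1, report = best
#>   final NN = 48.828178, best NN = 48.828178
#>   cluster sizes (reported assignment): 50, 50, 50

macro_f_score(blobs$labels, fit$assignment)
#> Macro-averaged F-score (optimal matching): 1.0000
#>   class 0 -> cluster 0: F = 1.0000
#>   class 1 -> cluster 2: F = 1.0000
#>   class 2 -> cluster 1: F = 1.0000
```

`best NN = 48.83` is the smallest residual nuclear norm seen during the run;
here the annealer recovers the generating partition exactly (macro F = 1),
as it should on blobs separated by 10 noise standard deviations.

The GWAS-style helper generates a toy case/control genotype panel and ranks
SNPs by the 1-df allelic chi-square test:

```r
panel <- genotype_panel(n_cases = 500, n_controls = 500, m_snps = 500,
                        n_causal = 10, delta = 0.25, seed = 1)
top <- rank_snps_allelic(panel, top_m = 50)
head(top, 3)
#>   snp    chisq      p_value
#> 1 465 158.1937 2.807527e-36
#> 2  51 136.6478 1.439890e-31
#> 3  89 135.8068 2.199204e-31
sum(panel$causal_snps %in% top$snp)
#> [1] 10
```

All 10 planted causal SNPs land inside the top 50, mirroring the
select-top-50-SNPs-then-cluster protocol the package emulates at toy scale.

## Command line

A thin wrapper lives at `inst/cli/nnc.R` (after installation:
`system.file("cli", "nnc.R", package = "nncluster")`):

```sh
Rscript nnc.R generate --kind blobs --n-per-cluster 50,50,50 --p 4 --seed 1 --out blobs
Rscript nnc.R cluster --input blobs_data.csv --labels-col label --k 3 \
    --iters 20000 --seed 1 --normalize none --report best --out run
Rscript nnc.R compare --input blobs_data.csv --labels-col label --k 3 --out cmp
```

`cluster` writes `run_assignment.csv` (sample id, 0-based cluster),
`run_summary.json` (config, seed, input MD5, final/best NN, macro F when
labels are given) and optionally a per-iteration trajectory CSV; `generate`
writes a manifest JSON that replays byte-identically via `--manifest`.

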