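# sigsimplex

Tools for analysing expression matrices measured over several phenotypic
sample groups — proteomics or transcriptomics data where the interesting
genes are *signature genes*: uniquely expressed (SG) or uniquely silent
(DSG) in one group. Such genes carry the most uneven missingness (random
losses where they are expressed, detection-limit censoring where they are
silent), are missed by one-versus-rest tests, and are mis-coloured by
classical z-score heatmaps. The package provides, for each of these
problems:

* **Group-wise, mechanism-aware pre-imputation.** In log space, with
  $\epsilon$ the minimum observed value (the working detection limit) and
  $\bar{x}_k(i), \sigma_k(i)$ the observed mean/SD of gene $i$ in group
  $k$, each missing cell is imputed by

  $$\tilde{x}_k(i) = \alpha_k(i)\,\tfrac{\epsilon}{2} + [1-\alpha_k(i)]\,\bar{x}_k(i),
    \qquad \alpha_k(i) = \Phi\!\big(\tfrac{\epsilon - \bar{x}_k(i)}{\sigma_k(i)}\big),$$

  a convex blend of the censoring imputand and the group mean weighted by
  the estimated probability that the cell fell below the detection limit.
  Seven classical peer imputers (half-min, mean, sample-wise kNN, PPCA,
  NIPALS, SVDimpute, SVT) are included for like-for-like comparison.

* **Cosine one-sample signature tests.** Each gene's cross-group mean
  vector $x(i)$ is scored against the ideal SG reference $\hat e_k$ (a
  simplex vertex) and the ideal DSG reference $\hat e_k \oplus \vec 1$
  (the opposite facet centre) by the magnitude-invariant statistic
  $t = \cos(x(i), \mathrm{ref})\in[0,1]$, with empirical-null p-values and
  BH q-values; one-versus-rest Welch t and fold-change baselines included.

* **A unified heatmap.** Simplex normalization
  $\hat x(i) = x(i)/\sum_k \bar x_k(i)$ followed by origin-preserving,
  scale-only log-space standardization, with genes and samples ordered by
  cosine score — zero expression maps to the same display value for every
  gene.

* **Ground-truth-embedded simulators and metrics**: a Dirichlet /
  truncated-Gaussian scatter-simplex generator, a mixed MNAR/MAR masking
  protocol with recorded truth, RMSE/NRMSE over the masked cells, partial
  ROC/AUC at an FPR cutoff, and benchmark harnesses for both tasks.

## Worked example

Simulate a 3-group benchmark, mask half of the cells with mixed
mechanisms, pre-impute, and rank downregulated signature genes:

```r
library(sigsimplex)

sim <- simulate_simplex(K = 3, seed = 1)   # 2610 genes x 30 samples
xl  <- to_log_space(sim$x)
msk <- simulate_missingness(xl, overall_rate = 0.5, mar_proportion = 0.4,
                            seed = 2)
msk$masked
#> <expr_mat> 2610 genes x 30 samples, log space, 37845 missing (48.3%)

res <- impute_mgpi(msk$masked, sim$design)
glance(res)
#> # A tibble: 1 × 5
#>   method n_genes n_samples n_imputed   epsilon
#>   <chr>    <int>     <int>     <int>     <dbl>
#> 1 mgpi      2610        30     37845 0.0000436

round(rmse(res, msk$omega), 3)                      # masked-cell error
#> [1] 0.506
round(rmse(impute_mean(msk$masked), msk$omega), 3)  # mean-imputation baseline
#> [1] 1.433

scores <- empirical_null_pvalues(
  score_signatures(from_log_space(res$completed), sim$design, kind = "dsg"))
dplyr::arrange(scores, p_value, dplyr::desc(statistic))
#> # A tibble: 2,610 × 7
#>   gene_id   kind  best_group statistic tie    p_value q_value
#>   <chr>     <chr> <chr>          <dbl> <lgl>    <dbl>   <dbl>
#> 1 gene_2547 dsg   G2             1.000 FALSE 0.000766       1
#> 2 gene_1916 dsg   G1             1.000 FALSE 0.00115        1
#> 3 gene_2113 dsg   G2             1.000 FALSE 0.00153        1
#> ...
```

The pre-imputation error (0.506 log2 units over 37,845 masked cells) is
about a third of the mean-imputation baseline, and the top-ranked genes
are all true simulated DSGs (statistic ≈ 1 means the group-mean pattern
sits at a simplex facet centre; the rank-based empirical-null q-values are
deliberately conservative — detection quality is evaluated by partial AUC,
see below). `order_by_cosine()` + `autoplot()` then draw the unified
heatmap of the top signatures, and `run_imputation_benchmark()` /
`run_detection_benchmark()` reproduce the full comparisons.

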