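# midpclust

Variable clustering by mutual information and Dirichlet process mixtures,
with a group elastic-net predictive stage.

## The problem

High-dimensional biomedical feature sets — e.g. model parameters
extracted from vectorcardiogram (VCG) recordings — contain blocks of
mutually redundant variables whose relationships are **nonlinear**: a
weight parameter and its absolute value, or a chaotic signal and its
lagged copies, are nearly deterministic functions of each other yet can
be exactly uncorrelated. Pearson-correlation-based clustering misses
these blocks; penalized regression that ignores them is unstable.

`midpclust` clusters the *columns* (variables) of a numeric data matrix
by nonlinear interdependence and uses the clusters to structure a
predictive model:

1. plug-in histogram mutual information for every pair of variables,
   `MI = Σ p(k,l) log[p(k,l)/(p(k)p(l))]` on a `B × B` equal-width grid
   (`B = ⌊√(N_s/5)⌋` by default);
2. reciprocal-MI dissimilarity `δ_ij = 1/MI_ij`, capped at the
   reciprocal of the estimator's bias floor `(B−1)²/(2N_s)`;
3. classical metric scaling of `B = −½ H Δ⁽²⁾ H` (top positive
   eigenpairs, `Y = V_d Λ_d^½`);
4. a Dirichlet-process Gaussian mixture over the embedded variables,
   fitted by collapsed Gibbs sampling (CRP representation, conjugate
   Normal–Inverse-Wishart base measure) — the number of clusters is
   inferred, not fixed;
5. optionally, Gram–Schmidt orthonormalization within each cluster and a
   group elastic-net logistic regression
   `−ℓ(β) + γ Σ_k √p_k ‖β_k‖₂ + λ‖β‖₁` with seeded cross-validated
   tuning.

Pearson + group-average hierarchical clustering is included as the
baseline, and generators for the standard benchmarks (four nonlinear
clusters built from Gaussians, a logistic map and a Lorenz-coupled AR(2)
process; a two-cluster motivating example; a grouped redundant-feature
surrogate with a binary outcome) are first-class, tested code.

## Worked example

```r
library(midpclust)

sim <- simulate_table1(1000, seed = 1)   # 20 variables, 4 true clusters of 5
res <- run_pipeline(sim$data, seed = 1)
res
#> MI-DP pipeline on 20 variables
#>   MAP partition: K = 4 (sizes: 5, 5, 5, 5 )
adjusted_rand_index(res$partition$labels, sim$true_labels$labels)
#> [1] 1
round(res$embedding$Y[c(1, 6, 11, 16), ], 2)
#>        y1    y2
#> v1  -5.38 -4.01
#> v6   5.60 -0.32
#> v11  1.18 -2.80
#> v16 -2.02  6.80
```

The MAP partition has exactly four occupied clusters and matches the
generating groups perfectly (adjusted Rand index 1): each parent variable
and its nonlinear transforms/lagged copies are grouped together even
though most of those relationships are invisible to linear correlation.
The four rows shown are the 2-D embedding coordinates of the four
cluster parents — well separated, one per group. With a binary response,
`run_pipeline(data, response = z, ...)` continues through
orthonormalization, cross-validated group elastic-net fitting, and a
classification report (accuracy/sensitivity/specificity in percent).

A thin command-line front end ships in `inst/cli/midp.R`
(`simulate` and `run` subcommands over the same functions).

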