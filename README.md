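# fdmoments

Moment-based estimation of the number of false discoveries in two-group
differential-expression testing when the tests are strongly dependent.

## The problem

A microarray (or similar large-scale) experiment records expression of
*G* genes on *M* arrays split between two treatment groups. Every gene is
tested against the null hypothesis of no differential expression via a
pooled two-sample *t* statistic, mapped to a z value
*z* = Φ⁻¹(*T*<sub>M−2</sub>(*t*)) so that nulls are unit normal. Genes with
*z* ≤ δ (default δ = −2.5) are "discovered"; with essentially all genes
null, the tail count

&nbsp;&nbsp;𝔉 = #{*z*<sub>g</sub> ≤ δ}

counts false discoveries. Under independence E𝔉 = *G*·Φ(δ), but intergene
correlation inflates Var(𝔉) enormously, making that mean useless as an
estimate for any particular data set. The observable count in the
zero-symmetric **center area** C = #{|*z*<sub>g</sub>| ≤ *c*} (default
*c* = 1), which is strongly *negatively* correlated with 𝔉, can rescue the
estimate: this package estimates the joint distribution p(𝔉, C) and
reports the conditional p(𝔉 | C) at the observed center count.

## The method

1. **Correlation reduction.** Residuals (per-gene within-group means
   removed, columns standardized) yield (G choose 2) pairwise correlations
   ρ̄. Their Fisher transforms τ̄ = atanh ρ̄ are fitted with a zero-mean
   normal whose variance, minus the sampling variance of τ̄, estimates the
   spread of the true correlations. Mapping back through tanh and the
   Beta-family variance identity σ² = 1/(2α + 1) gives a single **omnibus
   parameter α** with density q<sub>ρ</sub>(ξ) ∝ (1 − ξ²)<sup>α</sup> on
   [−1, 1]; an inverse-Wishart construction extends it to a density
   q<sub>R</sub> of 3×3 correlation submatrices with matching marginals.
2. **Moment propagation.** Means, covariances and third central moments of
   z-histogram counts are mixture integrals of bivariate/trivariate normal
   probabilities over q<sub>ρ</sub> and q<sub>R</sub>; region sums give the
   nine moments of (𝔉, C) (second order is deterministic quadrature, third
   order uses quasi-Monte-Carlo draws of correlation matrices).
3. **Maximum entropy.** The maxent distribution on a mesh over
   {f ≥ 0, c ≥ 0, f + c ≤ G} matching those moments (degree-2 or degree-3
   monomial constraints in normalized coordinates, convex dual solved by
   damped Newton) yields p̂(𝔉, C); slicing at the observed C gives
   p̂(𝔉 | C), whose mean is the point estimate.

A Gamma-Gamma/Gaussian-copula simulator generates correlated all-null
expression matrices (x<sub>gm</sub> ~ Γ(κ, θ<sub>g</sub>),
θ<sub>g</sub> ~ Γ(κ₀, θ₀), dependence imposed by mapping correlated
normals through the Gamma quantile function) for end-to-end validation.

## Worked example

Simulate a correlated all-null panel (500 genes, 8 arrays, 4 + 4 design),
log it, and run the full pipeline:

```r
library(fdmoments)
cfg   <- gamma_gamma_config(preset = "gamma1", G = 500, M = 8)
R     <- dense_correlation(500, seed = 3)
panel <- simulate_null_matrix(cfg, R = R, seed = 5)
panel$values <- log(panel$values); panel$log_transformed <- TRUE
estimate_false_discoveries(panel, order = 3, n_mc = 4000, seed = 9,
                           n_F = 60, n_C = 200)
#> false-discovery estimate (order 3)
#>   alpha          5.6716
#>   observed counts: tail 1, center 277
#>   corr(F, C)     -0.734
#>   E[F | C]       8.0762  (naive mean 3.105)
#>   50% interval   [5.961, 10.73]
```

The estimated α ≈ 5.7 summarizes a heavy spread of pairwise correlations;
the implied corr(𝔉, C) ≈ −0.73 is what lets the observed center count
(277, far below its null mean of ≈ 341) inform the tail. The conditional
estimate replaces the constant naive mean 3.1, which never responds to the
data at hand. Across replicates the conditional estimates track the
realized tail counts:

```r
bm <- run_benchmark(cfg, n_reps = 10, orders = c(2, 3), seed = 7,
                    n_mc = 2000, n_F = 60, n_C = 200)
bm$table[1:3, c("rep", "realized", "C_obs", "alpha", "order2", "order3")]
#>   rep realized C_obs    alpha    order2     order3
#> 1   1       15   234 4.198809 11.915494 14.4948447
#> 2   2        1   434 3.085489  1.019710  0.1336213
#> 3   3        2   262 6.894953  9.864949 11.0660122
```

(The naive mean is 3.1 in every row.) At the acceptance-test scale
(40 replicates) the third-moment estimator's mean absolute error is
smaller than the second-moment one's, which is in turn far below the
naive estimator's.

A thin command-line front end lives at `inst/cli/fdmoments.R`
(`alpha`, `moments`, `estimate`, `control`, `simulate`, `benchmark`
subcommands; JSON reports, TSV tables).

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the
correlation coefficient between 𝔉 and C implied by the second-moment
aggregation at the two published analysis configurations
(G = 3226, α = 17.77 and G = 7680, α = 3.51; c = 1, δ = −2.5, Δ = 0.1):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
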