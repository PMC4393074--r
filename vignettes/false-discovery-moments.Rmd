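---
title: "Estimating false-discovery counts under intergene correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating false-discovery counts under intergene correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdmoments)
```

## The model

`fdmoments` addresses a multiple-testing situation with three defining
features: thousands of marginally correct null hypotheses, strong and
unknown dependence among the test statistics, and very few samples. The
canonical instance is two-group differential expression: *G* genes on
*M* microarrays, a pooled two-sample *t* per gene, and the probit map
`z = qnorm(pt(t, M - 2))` making every null score a unit normal variate.
The scores are treated as jointly Gaussian to third order, with
`cor(z_g, z_g')` approximated by the correlation of the corresponding
residual expression rows (exact for the two-sample *t* under independent
arrays).

Two counts summarize the z histogram: the rejection-tail count
`F = #{z <= delta}` — under the all-null convention, the number of false
discoveries — and the center-area count `C = #{|z| <= c}`. The center
area is presumed to contain essentially no non-null scores, so `C` is
observable. Correlation makes `Var(F)` explode while leaving
`E F = G * pnorm(delta)` unchanged, so the useful object is not the mean
but the conditional distribution `p(F | C)`: `F` and `C` are strongly
negatively correlated (a histogram squeezed into the center starves the
tails and vice versa), so the observed `C` carries real information about
the unobserved `F`.

The package estimates the first three joint moments of `(F, C)` from a
one-parameter summary of the correlation structure, fits the
maximum-entropy joint distribution matching them, and conditions on the
observed `C`.

## The correlation density and the omnibus parameter

All dependence enters through the empirical distribution of the
`choose(G, 2)` pairwise correlations of the standardized residual matrix.
Sampling noise at small *M* would swamp a direct histogram, so the
pipeline works on the Fisher scale:

1. `tau = atanh(rho_bar)` for every gene pair (optionally a seeded uniform
   subsample of pairs, default budget 5e5; unbiased for variances);
2. a zero-mean normal is fitted to the `tau` values by the method of
   moments (`sigma2_raw = mean(tau^2)`; the mean is reported as a
   diagnostic only — column standardization pins the average correlation
   near zero, which justifies the symmetric fit);
3. the sampling variance of `tau` is subtracted:
   `sigma2_denoised = sigma2_raw - v_eps`;
4. `sigma2_rho = E[tanh(xi)^2]` under `N(0, sigma2_denoised)` undoes the
   Fisher map by quadrature;
5. `alpha = (1 - sigma2_rho) / (2 * sigma2_rho)` inverts the symmetric
   Beta-family variance identity `sigma2 = 1/(2 alpha + 1)`.

The result is the density `q_rho(xi) ∝ (1 - xi^2)^alpha` on [−1, 1]. An
inverse-Wishart argument (identity scale, degrees of freedom
`nu - G = 2 alpha + 1`) extends it to the density `q_R` of 3×3 correlation
submatrices whose scalar marginals are exactly `q_rho`; `sample_qR()`
draws from it by a Bartlett construction, and the closed-form density
`q_R_logpdf()` is available with a cached importance-sampled
normalization.

### The sampling-variance constant

The source formulas print the Fisher sampling variance as `1/(G - 3)`,
which is dimensionally wrong (it involves the gene count, not the number
of observations per correlation; with thousands of genes the correction
would vanish and the deconvolution would be pointless). Classical theory
for a partial correlation controlling `q` covariates gives
`1/(n - 3 - q)`; removing group means is `q = K - 1` covariates, so with
`df_res = M - K` the default is

`v_eps = 1/(df_res - 2) = 1/(M - K - 2)`.

A null simulation of the exact pipeline (iid normal rows, M = 16, K = 2)
reproduces this constant (empirical 0.0827 vs 1/12 = 0.0833, while the
alternatives 1/13 and 1/14 are visibly too small). The constant remains
user-settable (`sampling_var`) because small-sample conventions differ.

### The exponent convention

The printed chain of formulas is internally off by one in the Beta
parameterization: the density is printed as `(1 - xi^2)^alpha`, but the
variance map `sigma2 = 1/(2 alpha + 1)` belongs to the kernel
`(1 - xi^2)^(alpha - 1)`. The package default (`convention = "printed"`)
uses the formulas exactly as printed — density exponent `alpha`, variance
map as above — because that combination reproduces the published
downstream values: at the BRCA-scale configuration (G = 3226,
alpha = 17.77) it yields corr(F, C) = −0.88 against the published −0.89,
and at the HIV-scale configuration (G = 7680, alpha = 3.51) −0.73 against
−0.75; the self-consistent variant (`convention = "consistent"`, exponent
`alpha - 1`) gives −0.88 but only −0.68 for the second configuration and
is therefore not the default. The discrepancy is O(1/alpha) and only
matters for small alpha. Internal recovery tests run under
`"consistent"`, where generation and estimation agree exactly; under
`"printed"` the published map carries an inherent ≈ +1 bias in alpha that
is a property of the printed formulas, not of the pipeline.

## Moment propagation

For bin counts `Y_b` of the z histogram, means are
`G * Delta * dnorm(z_b)`; covariances and third moments replace sums over
gene pairs/triplets by mixture integrals `Q_rho` and `Q_R` of bivariate
and trivariate normal densities over the correlation densities. One sign
matters: the printed covariance formula subtracts the same-bin Kronecker
term, which would make variances negative in the independence limit;
re-deriving from the count expansion shows the same-gene term is added,
and the implementation (`+ delta_bb' * mu_b - mu_b * mu_b'`) reduces
exactly to multinomial covariance/third-moment formulas at
`alpha = Inf`, verified against exhaustive enumeration at G ≤ 6.
Likewise the printed region sums for `sigma2_F` and the (F, C) covariance
contain obvious typos (wrong region, squared factors); the implementation
follows the definitions.

Two evaluation paths exist and are tested against each other:

* **region path** (default): the tail and center are intervals, so all
  moments are bivariate/trivariate normal box probabilities under the
  correlation mixture — no histogram truncation or midpoint error. Second
  moments use Gauss–Legendre quadrature (the substitution `xi = sin θ`
  removes the endpoint singularity); third moments average conditional
  2-D quadratures over a shared sample of correlation matrices.
* **bins path**: the literal midpoint-rule sums over the truncated grid
  (z in [−6, 6], sub-range mass added analytically to the tail mean),
  kept for testing; it agrees with the region path to the expected
  O(Delta²) ≈ 0.3–2% depending on the component.

Third moments are the expensive part. Plain Monte Carlo over `q_R` needs
very large samples because the aggregated third moments arise from a
~10-fold cancellation of `O(G^3)` terms; the default therefore drives the
Bartlett construction with a Cranley–Patterson-shifted Halton sequence
(`sample_qR(method = "halton")`), giving near-`1/n` convergence. With the
default `n_mc = 2e4` the BRCA-scale third-moment set is stable to well
under a percent; the scaled-down benchmark uses `n_mc = 2000`.

The lemma-based aggregation was validated end to end against brute force:
at G = 30 with a fixed dense correlation matrix, all nine moments of
(F, C) from 2e5 simulated z vectors agree with the aggregation run on the
exact plug-in pair/triplet distributions of that matrix within three
Monte-Carlo standard errors (`rho_sample` / `R_sample` arguments expose
the plug-in route).

## The maximum-entropy fit

`p_hat(F, C)` is the maximum-entropy distribution on an equispaced mesh
over the feasible triangle `{f >= 0, c >= 0, f + c <= G}` matching the
estimated moments. Internals (the reference appendix is not public):

* sufficient statistics are the monomials of total degree ≤ order (5 for
  order 2, 9 for order 3) in normalized coordinates
  (`(f - mu_F)/sd_F`, `(c - mu_C)/sd_C`), additionally standardized
  against the uniform mesh measure for conditioning;
* the convex dual (log-partition minus target inner product) is minimized
  by Newton iterations with Levenberg–Marquardt damping, initialized from
  the analytic Gaussian solution; convergence demands constraint
  violations below 1e-8 (1e-6 when the dual has stagnated at
  floating-point resolution);
* the mesh default is 100 × 500 (F × C) covering mean ± 6 sd per axis,
  clipped to the triangle. When third moments are present each axis is
  extended by `2 |skewness|` sd on the side the skew points to —
  cubic-constrained fits put mass far beyond the Gaussian range, and the
  tight box otherwise renders strongly skewed moment sets (skewness ≈ 6
  arises at alpha ≈ 3) infeasible. Finer meshes (the reference used up to
  400 × 2000 for the more correlated data set) change the conditional
  mean by under 1%.

The solver was checked cell-by-cell (1e-6) against an independent primal
maximizer (softmax-parameterized entropy with an augmented Lagrangian on
the moment constraints) on a 12 × 12 mesh, and against the discretized
Gaussian in the uncorrelated order-2 case.

`conditional()` slices the joint at the mesh column nearest the observed
`C` (no interpolation — the mesh is fine enough that the choice moves the
estimate by well under the Monte-Carlo noise), renormalizes, and reports
the mean (the point estimate), median, and central 50%/75% intervals.
`control_discoveries()` scans tail thresholds and returns the least
extreme one whose conditional exceedance bound
`P(F >= gamma * G_star | C) <= lambda` holds.

## The simulator and what a green test establishes

`simulate_null_matrix()` reproduces the published simulation protocol:
expression `x_gm ~ Gamma(kappa, theta_g)` with
`theta_g ~ Gamma(kappa0, theta0)` (so mean `kappa * theta_g` and variance
`kappa * theta_g^2` — brighter genes are noisier), correlated via a
Gaussian copula `Zc = L Z` with `L` the lower Cholesky factor of
`R + diag_load * I` (the printed `L'Z` would not impose `R` on the rows;
the diagonal load, default 1e-3, guards rank deficiency since M << G, and
rows are rescaled so marginals stay exact). The three reference parameter
sets (1, 0.6, 500), (2, 0.39, 384), (3, 0.33, 300) share total marginal
variance ≈ 3.9e5 within 2% and span exponential to near-Gaussian
histograms.

One substitution: the published simulations imposed the correlation
matrix of the real BRCA data; that matrix is external data, so the
default here is a seeded dense factor-model correlation
(`dense_correlation()`, `cov2cor(BB' + D)`), and any user-supplied matrix
is accepted. Consequences: the generator reproduces dense, realistically
scaled dependence but not the specific eigenstructure of a real
microarray study, so benchmark results are qualitative (does
conditioning help, do third moments help) rather than figure-exact. The
desk-scale benchmark default is G = 500, M = 8, 40 replicates
(seconds per replicate); the published scale (G = 3226, 800 replicates)
is reachable by arguments.

## Numerical choices and degenerate inputs

* Bin edges anchor at zero so `c`, `delta` and the truncation bounds fall
  exactly on edges; scores bin half-open `[lo, hi)`, so a score exactly
  at `-c` counts center-side; observed counts use the raw scores with
  `<=`, not the truncated bins.
* Tail-side: left only (`z <= delta`), matching the reference analyses;
  negate scores for a right tail.
* Standardization uses the sample variance (denominator G − 1); either
  convention only rescales columns and leaves all correlations unchanged.
* Degenerate inputs error early and name the offender: missing cells,
  nonpositive values under log, single-array groups, constant columns,
  zero pooled variances, |rho| = 1 pairs (excluded with a warning),
  nonpositive denoised variance (with the advice to use more pairs or the
  independence limit `alpha = Inf`).
* All randomness is seed-parameterized; Halton draws use a seeded
  Cranley–Patterson shift so they are reproducible yet honestly
  randomized.

## Known limitations

* The all-null presumption makes the estimate of F conservative when a
  material non-null fraction leaks into the tail; no pi0 correction is
  implemented.
* A single omnibus alpha cannot represent multi-modal correlation
  structure (e.g. a few tight clusters in a sea of independence); the
  plug-in `rho_sample`/`R_sample` route exists for such cases.
* Third-order z-score Gaussianity is an assumption, not a theorem, for
  t-derived scores at small M.
* Moments above order 3 are out of scope; the exceedance-control scan
  refits the maxent distribution per candidate threshold and is
  correspondingly slow for fine threshold grids.
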