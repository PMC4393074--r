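# Shared fixtures and independent oracles, all built in code at test time.

# iid-normal expression panel
make_panel <- function(G = 50, M = 10, seed = 1, groups = NULL) {
  set.seed(seed)
  if (is.null(groups)) groups <- rep(c(1L, 2L), each = M / 2)
  expression_panel(matrix(rnorm(G * M), G, M), groups)
}

# G x G correlation matrix drawn from the inverse-Wishart construction with
# degrees of freedom nu (pairwise marginals follow the Beta-family density
# with kernel exponent (nu - G - 1) / 2)
iw_correlation <- function(G, nu, seed = 1) {
  set.seed(seed)
  A <- diag(sqrt(rchisq(G, nu - seq_len(G) + 1)))
  A[lower.tri(A)] <- rnorm(G * (G - 1) / 2)
  B <- backsolve(t(A), diag(G), upper.tri = TRUE)  # B = inv(A)', Sigma = BB'
  stats::cov2cor(B %*% t(B))
}

# panel whose rows are correlated unit normals with pairwise correlations
# drawn from q_rho(alpha_star) under the self-consistent convention
make_correlated_panel <- function(alpha_star, G = 500, M = 16, seed = 1) {
  R <- iw_correlation(G, G + 2 * alpha_star - 1, seed = seed)
  set.seed(seed + 1000L)
  Z <- t(chol(R)) %*% matrix(rnorm(G * M), G, M)
  expression_panel(Z, rep(c(1L, 2L), each = M / 2))
}

# Exhaustive multinomial moment oracle: G independent genes, each falling in
# category j with probability p[j] (categories = bins plus an implicit
# remainder).  Enumerates all length(p)^G outcomes and returns the exact
# mean vector, covariance matrix and third-central-moment tensor of the
# category counts.  Only usable for tiny G.
multinomial_enumeration_oracle <- function(G, p) {
  K <- length(p)
  stopifnot(K^G <= 2e5, abs(sum(p) - 1) < 1e-12)
  combos <- as.matrix(expand.grid(rep(list(seq_len(K)), G)))
  prob <- apply(combos, 1L, function(a) prod(p[a]))
  counts <- t(apply(combos, 1L, function(a) tabulate(a, nbins = K)))
  mu <- colSums(counts * prob)
  cc <- sweep(counts, 2L, mu)
  covm <- t(cc * prob) %*% cc
  third <- array(0, dim = c(K, K, K))
  for (i in seq_len(K)) for (j in seq_len(K)) for (k in seq_len(K))
    third[i, j, k] <- sum(prob * cc[, i] * cc[, j] * cc[, k])
  list(mu = mu, cov = covm, third = third)
}

# Generic primal maximum-entropy solver: maximize H(p) over the simplex
# subject to A'p = targ, via softmax parameterization and an augmented
# Lagrangian with BFGS inner iterations.  Independent of the package's dual
# Newton solver; used as its oracle.
softmax_entropy_oracle <- function(A, targ) {
  obj <- function(x, u, rho) {
    e <- exp(x - max(x)); p <- e / sum(e)
    viol <- drop(crossprod(A, p)) - targ
    sum(p * log(pmax(p, 1e-300))) + sum(u * viol) + 0.5 * rho * sum(viol^2)
  }
  grad <- function(x, u, rho) {
    e <- exp(x - max(x)); p <- e / sum(e)
    viol <- drop(crossprod(A, p)) - targ
    gp <- log(pmax(p, 1e-300)) + 1 + drop(A %*% (u + rho * viol))
    p * (gp - sum(p * gp))
  }
  x <- numeric(nrow(A)); u <- numeric(length(targ)); rho <- 10
  p <- NULL; viol <- Inf
  for (outer_it in 1:80) {
    o <- stats::optim(x, obj, grad, u = u, rho = rho, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
    x <- o$par
    e <- exp(x - max(x)); p <- e / sum(e)
    viol <- drop(crossprod(A, p)) - targ
    if (max(abs(viol)) < 1e-11) break
    u <- u + rho * viol
    rho <- min(rho * 2, 1e8)
  }
  list(p = p, viol = viol)
}

# empirical (F, C) moments of a sample with batch-based standard errors
fc_moment_stats <- function(Fv, Cv, n_batches = 20) {
  stat <- function(f, cc) c(mean(f), mean(cc), var(f), var(cc), cov(f, cc),
                            mean((f - mean(f))^3),
                            mean((f - mean(f))^2 * (cc - mean(cc))),
                            mean((f - mean(f)) * (cc - mean(cc))^2),
                            mean((cc - mean(cc))^3))
  n <- length(Fv)
  batches <- matrix(seq_len(n), ncol = n_batches)
  bs <- apply(batches, 2L, function(ix) stat(Fv[ix], Cv[ix]))
  list(est = stat(Fv, Cv), se = apply(bs, 1L, sd) / sqrt(n_batches))
}

# numerical cdf of the scalar correlation density (for KS tests)
qrho_cdf <- function(q, alpha, convention = "printed") {
  vapply(q, function(x)
    stats::integrate(q_rho_pdf, -1, x, alpha = alpha,
                     convention = convention, rel.tol = 1e-9)$value,
    numeric(1))
}
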