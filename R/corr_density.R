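# Estimation of the one-parameter empirical correlation density.
#
# The pairwise correlations of the standardized residual rows are Fisher
# transformed, their variance is denoised by subtracting the sampling
# variance, mapped back to the correlation scale, and summarized by the
# omnibus shape parameter alpha of the symmetric Beta-family density
# q_rho(xi) on [-1, 1].  The induced density of 3x3 correlation submatrices
# q_R follows from an inverse-Wishart construction whose marginalization
# property forces every scalar marginal back to q_rho.
#
# Two exponent conventions are supported.  The source formulas relate the
# density kernel, the variance map and the inverse-Wishart degrees of
# freedom in a way that is off by one in the Beta parameterization:
#   "printed"    q_rho ∝ (1-xi^2)^alpha,   alpha = (1-s2)/(2 s2)  (default)
#   "consistent" q_rho ∝ (1-xi^2)^(alpha-1), so Var(q_rho) = 1/(2 alpha + 1)
#                matches the alpha = (1-s2)/(2 s2) map exactly.
# The default reproduces the published downstream values; see the methods
# vignette for the numerical comparison.

.qrho_exponent <- function(alpha, convention = c("printed", "consistent")) {
  convention <- match.arg(convention)
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be finite and >= 0")
  a <- if (convention == "printed") alpha else alpha - 1
  if (a < -0.5 + 1e-12)
    stop("density exponent ", signif(a, 3), " is not integrable; ",
         "alpha too small for convention '", convention, "'")
  a
}

.qR_df <- function(alpha, convention = c("printed", "consistent")) {
  # 3x3 inverse-Wishart degrees of freedom whose correlation submatrix has
  # scalar marginals with kernel exponent .qrho_exponent(alpha).
  2 * .qrho_exponent(alpha, convention) + 4
}

#' Fisher transform and its inverse
#'
#' `fisher(rho) = atanh(rho)` approximately normalizes and variance-
#' stabilizes sample correlation coefficients; `fisher_inv` is `tanh`.
#'
#' @param rho Correlations, `|rho| < 1`.
#' @param tau Fisher-transformed values.
#' @return Numeric vector.
#' @export
fisher <- function(rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  atanh(rho)
}

#' @rdname fisher
#' @export
fisher_inv <- function(tau) tanh(tau)

#' Pairwise correlations of residual rows
#'
#' Computes sample correlation coefficients between gene (row) pairs of the
#' standardized residual matrix; when the full set of G-choose-2 pairs
#' exceeds `max_pairs`, a uniform seeded subsample of pairs is used
#' (variance estimates remain unbiased under uniform pair sampling).
#' Zero-variance rows and degenerate pairs with `|rho| >= 1` are dropped
#' with a warning.
#'
#' @param res A `residual_panel` (standardized; see [standardize_columns()]).
#' @param max_pairs Pair budget (default 5e5).
#' @param seed Optional seed for the pair subsample.
#' @return Object of class `correlation_sample`: `rho_bar`, `tau_bar`,
#'   `df_res` (residual degrees of freedom M - K), `n_pairs`.
#' @export
pairwise_correlations <- function(res, max_pairs = 5e5, seed = NULL) {
  if (inherits(res, "expression_panel")) res <- standardize_columns(res)
  stopifnot(inherits(res, "residual_panel"))
  if (res$effective_df < 5L)
    stop("residual degrees of freedom must be >= 5 for the Fisher-variance ",
         "correction (got ", res$effective_df, ")")
  X <- res$values
  keep <- apply(X, 1L, stats::sd) > 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance residual row(s) excluded")
    X <- X[keep, , drop = FALSE]
  }
  G <- nrow(X)
  n_all <- G * (G - 1) / 2
  if (n_all <= max_pairs) {
    R <- stats::cor(t(X))
    rho <- R[upper.tri(R)]
  } else {
    idx <- with_seed(seed, sample(n_all, max_pairs))
    # decode the linear index of the upper triangle (column-major)
    j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
    i <- idx - (j - 1) * (j - 2) / 2
    Xc <- X - rowMeans(X)
    Xc <- Xc / sqrt(rowSums(Xc^2))
    rho <- rowSums(Xc[i, , drop = FALSE] * Xc[j, , drop = FALSE])
  }
  bad <- abs(rho) >= 1 - 1e-12
  if (any(bad)) {
    warning(sum(bad), " degenerate pair(s) with |rho| ~ 1 excluded")
    rho <- rho[!bad]
  }
  structure(list(rho_bar = rho, tau_bar = atanh(rho),
                 df_res = res$effective_df, n_pairs = length(rho)),
            class = "correlation_sample")
}

#' Denoise the Fisher-scale variance
#'
#' The observed Fisher-transformed correlations are modeled as true values
#' plus sampling noise, `tau_bar = tau + eps`; a zero-mean normal is fitted
#' by the method of moments (variance = mean of squares; the mean is a
#' diagnostic, not subtracted) and the sampling variance of `eps` is
#' subtracted to recover the spread of the underlying correlations.
#'
#' @param sample A `correlation_sample`.
#' @param sampling_var Variance of the sampling noise on the Fisher scale.
#'   Default `1/(df_res - 2)` with `df_res = M - K` the residual degrees of
#'   freedom: this is the classical Fisher variance `1/(n - 3 - q)` of a
#'   partial correlation controlling the `q = K - 1` group covariates, and
#'   is what null simulations of the residual pipeline reproduce.  Pass a
#'   number to override (e.g. `1/(M - 3)`).
#' @return The denoised variance, with the raw variance, sampling variance
#'   and tau-mean diagnostic attached as attributes.
#' @export
denoise_tau_variance <- function(sample, sampling_var = NULL) {
  stopifnot(inherits(sample, "correlation_sample"))
  if (is.null(sampling_var)) sampling_var <- 1 / (sample$df_res - 2)
  raw <- mean(sample$tau_bar^2)
  out <- raw - sampling_var
  if (out <= 0)
    stop("denoised Fisher-scale variance is nonpositive (raw ",
         signif(raw, 4), " <= sampling ", signif(sampling_var, 4),
         "); no detectable correlation signal - use more pairs or the ",
         "independence limit alpha = Inf")
  structure(out, sigma2_tau_raw = raw, sampling_var = sampling_var,
            tau_mean = mean(sample$tau_bar))
}

#' Map a Fisher-scale variance to the correlation scale
#'
#' Pushes a zero-mean normal with variance `sigma2_tau` through `tanh`:
#' `sigma2_rho = E[tanh(xi)^2]`, computed by adaptive quadrature.  Always
#' strictly smaller than `sigma2_tau` since `|tanh(x)| < |x|`.
#'
#' @param sigma2_tau Positive variance on the Fisher scale.
#' @return Variance on the correlation scale.
#' @export
rho_scale_variance <- function(sigma2_tau) {
  stopifnot(sigma2_tau > 0)
  s <- sqrt(sigma2_tau)
  stats::integrate(function(x) tanh(x)^2 * dnorm(x, sd = s),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

#' Omnibus shape parameter from a correlation-scale variance
#'
#' Inverts the variance map `sigma2 = 1/(2 alpha + 1)` of the symmetric
#' Beta-family correlation density: `alpha = (1 - sigma2)/(2 sigma2)`.
#'
#' @param sigma2_rho Variance on the correlation scale, in (0, 1].
#' @return `alpha >= 0`.
#' @export
alpha_from_variance <- function(sigma2_rho) {
  if (sigma2_rho <= 0 || sigma2_rho > 1)
    stop("sigma2_rho must lie in (0, 1]")
  (1 - sigma2_rho) / (2 * sigma2_rho)
}

#' Estimate the omnibus correlation parameter alpha from a panel
#'
#' Full reduction: residualize, standardize columns, pairwise correlations,
#' Fisher transform, variance denoising, back-transform, and the alpha map.
#'
#' @param panel An [expression_panel()] or `residual_panel`.
#' @param max_pairs,seed Passed to [pairwise_correlations()].
#' @param sampling_var Passed to [denoise_tau_variance()].
#' @return Object of class `corr_density_model`: `alpha`, `sigma2_tau_raw`,
#'   `sigma2_tau_denoised`, `sigma2_rho`, `sampling_var`, `df_res`,
#'   `tau_mean`, `n_pairs`.
#' @export
estimate_alpha <- function(panel, max_pairs = 5e5, seed = NULL,
                           sampling_var = NULL) {
  samp <- pairwise_correlations(panel, max_pairs = max_pairs, seed = seed)
  s2tau <- denoise_tau_variance(samp, sampling_var = sampling_var)
  s2rho <- rho_scale_variance(as.numeric(s2tau))
  structure(list(alpha = alpha_from_variance(s2rho),
                 sigma2_tau_raw = attr(s2tau, "sigma2_tau_raw"),
                 sigma2_tau_denoised = as.numeric(s2tau),
                 sigma2_rho = s2rho,
                 sampling_var = attr(s2tau, "sampling_var"),
                 df_res = samp$df_res,
                 tau_mean = attr(s2tau, "tau_mean"),
                 n_pairs = samp$n_pairs),
            class = "corr_density_model")
}

#' @export
print.corr_density_model <- function(x, ...) {
  cat("correlation density model\n",
      "  alpha                 ", signif(x$alpha, 6), "\n",
      "  sigma2_tau (raw)      ", signif(x$sigma2_tau_raw, 6), "\n",
      "  sigma2_tau (denoised) ", signif(x$sigma2_tau_denoised, 6), "\n",
      "  sigma2_rho            ", signif(x$sigma2_rho, 6), "\n",
      "  pairs                 ", x$n_pairs, "\n", sep = "")
  invisible(x)
}

#' Scalar correlation density q_rho
#'
#' Normalized density of pairwise correlations on [-1, 1] with kernel
#' `(1 - xi^2)^a`; the exponent `a` follows the convention (see
#' Details in the package vignette).  `alpha = Inf` is the independence
#' limit (point mass at zero) and is rejected here.
#'
#' @param xi Evaluation points in [-1, 1].
#' @param alpha Omnibus shape parameter, >= 0.
#' @param convention `"printed"` (default) or `"consistent"`.
#' @return Density values.
#' @export
q_rho_pdf <- function(xi, alpha, convention = "printed") {
  if (any(abs(xi) > 1)) stop("|xi| must be <= 1")
  a <- .qrho_exponent(alpha, convention)
  lz <- .qrho_lognorm(a)
  out <- numeric(length(xi))
  inside <- abs(xi) < 1
  out[inside] <- exp(a * log1p(-xi[inside]^2) - lz)
  if (a < 0) out[!inside] <- Inf
  out
}

#' Unnormalized log density of a 3x3 correlation matrix
#'
#' Marginal density of a 3x3 correlation submatrix under the inverse-Wishart
#' construction tied to `alpha`; its scalar marginals coincide with
#' [q_rho_pdf()].  Parameterized by the three upper-triangle entries.
#' Returns `-Inf` outside the positive-definite region.
#'
#' @param r12,r13,r23 Off-diagonal entries (vectors of equal length).
#' @param alpha Omnibus shape parameter.
#' @param convention `"printed"` or `"consistent"`.
#' @return Unnormalized log density values.
#' @export
q_R_logpdf <- function(r12, r13, r23, alpha, convention = "printed") {
  a <- .qrho_exponent(alpha, convention)
  det3 <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  ok <- det3 > 0 & abs(r12) < 1 & abs(r13) < 1 & abs(r23) < 1
  out <- rep(-Inf, length(det3))
  out[ok] <- (2 * a + 2) * log(det3[ok]) -
    (a + 2) * (log1p(-r12[ok]^2) + log1p(-r13[ok]^2) + log1p(-r23[ok]^2))
  out
}

#' Normalization constant of the 3x3 correlation density
#'
#' Computes `log` of the integral of `exp(q_R_logpdf)` over the positive-
#' definite subset of the cube, by seeded importance sampling from the
#' product of scalar marginals.  Cached per (alpha, convention).
#'
#' @param alpha Omnibus shape parameter.
#' @param convention `"printed"` or `"consistent"`.
#' @param n Number of importance draws.
#' @param seed Seed for the (cached) draw.
#' @return Log normalization constant.
#' @export
normalize_qR <- function(alpha, convention = "printed", n = 2e5, seed = 101) {
  key <- paste0("qRnorm_", convention, "_", signif(alpha, 12))
  if (!is.null(.fdm_cache[[key]])) return(.fdm_cache[[key]])
  a <- .qrho_exponent(alpha, convention)
  draws <- with_seed(seed, {
    # product-of-marginals proposal via the Beta representation
    matrix(2 * rbeta(3 * n, a + 1, a + 1) - 1, ncol = 3)
  })
  lg <- rowSums(a * log1p(-draws^2) - .qrho_lognorm(a))
  lf <- q_R_logpdf(draws[, 1], draws[, 2], draws[, 3], alpha, convention)
  lw <- lf - lg                       # -Inf for non-PSD draws contributes 0
  m <- max(lw[is.finite(lw)])
  out <- m + log(sum(exp(lw[is.finite(lw)] - m)) / n)
  .fdm_cache[[key]] <- out
  out
}

#' Sample 3x3 correlation matrices from q_R
#'
#' Draws 3x3 inverse-Wishart matrices (identity scale, degrees of freedom
#' tied to alpha) by the Bartlett decomposition and rescales each to a
#' correlation matrix.  The scalar marginals of the off-diagonals then
#' follow [q_rho_pdf()].  `alpha = Inf` returns identity matrices.
#'
#' @param alpha Omnibus shape parameter (may be `Inf`).
#' @param n Number of draws.
#' @param seed Optional seed.
#' @param convention `"printed"` or `"consistent"`.
#' @param method `"mc"` for plain Monte Carlo, `"halton"` for a randomized
#'   (Cranley-Patterson shifted) Halton sequence driving the Bartlett
#'   construction; the latter converges much faster for smooth integrands
#'   and is what the moment aggregation uses.
#' @return `n x 3` matrix with columns `r12`, `r13`, `r23`.
#' @export
sample_qR <- function(alpha, n, seed = NULL, convention = "printed",
                      method = c("mc", "halton")) {
  method <- match.arg(method)
  if (is.infinite(alpha))
    return(matrix(0, n, 3, dimnames = list(NULL, c("r12", "r13", "r23"))))
  nu <- .qR_df(alpha, convention)
  with_seed(seed, {
    if (method == "halton") {
      U <- .halton_matrix(n, 6L)
      shift <- runif(6)
      U <- (U + matrix(shift, n, 6, byrow = TRUE)) %% 1
      U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
      a11 <- sqrt(qchisq(U[, 1], nu)); a22 <- sqrt(qchisq(U[, 2], nu - 1))
      a33 <- sqrt(qchisq(U[, 3], nu - 2))
      a21 <- qnorm(U[, 4]); a31 <- qnorm(U[, 5]); a32 <- qnorm(U[, 6])
    } else {
      a11 <- sqrt(rchisq(n, nu)); a22 <- sqrt(rchisq(n, nu - 1))
      a33 <- sqrt(rchisq(n, nu - 2))
      a21 <- rnorm(n); a31 <- rnorm(n); a32 <- rnorm(n)
    }
    # closed-form inverse of the lower-triangular Bartlett factor
    b11 <- 1 / a11; b22 <- 1 / a22; b33 <- 1 / a33
    b21 <- -a21 / (a11 * a22)
    b32 <- -a32 / (a22 * a33)
    b31 <- (a21 * a32 - a22 * a31) / (a11 * a22 * a33)
    # Sigma = B'B is the inverse-Wishart draw
    s11 <- b11^2 + b21^2 + b31^2
    s22 <- b22^2 + b32^2
    s33 <- b33^2
    s12 <- b21 * b22 + b31 * b32
    s13 <- b31 * b33
    s23 <- b32 * b33
    cbind(r12 = s12 / sqrt(s11 * s22),
          r13 = s13 / sqrt(s11 * s33),
          r23 = s23 / sqrt(s22 * s33))
  })
}
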