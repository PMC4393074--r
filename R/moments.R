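# Moments of the null z-histogram counts and their aggregation into the
# moment set of the tail count F and the center count C.
#
# Under the all-null model every z is a unit normal and any pair (triplet)
# of z scores is bivariate (trivariate) normal with correlation(s) drawn
# from the empirical correlation density.  Bin-count moments then reduce to
# mixture integrals Q_rho and Q_R of multivariate normal densities over the
# correlation density, and the (F, C) moments are region sums of bin
# moments.  The default "region" path evaluates the equivalent interval
# (box) probabilities directly, which is exact in the bin width; the "bins"
# path (midpoint rule on the histogram grid) is retained as a cross-check.

# mixture E_xi over the correlation density or an empirical sample
.qrho_mix <- function(alpha, convention, n_nodes, rho_sample = NULL) {
  if (!is.null(rho_sample))
    return(list(xi = rho_sample, w = rep(1 / length(rho_sample),
                                         length(rho_sample))))
  .qrho_nodes(.qrho_exponent(alpha, convention), n_nodes)
}

# pairwise mixture density values for vectors z1, z2 (elementwise pairs)
.Qrho_pairs <- function(z1, z2, xi, w) {
  out <- numeric(length(z1))
  for (k in seq_along(xi)) {
    r <- xi[k]; s2 <- 1 - r^2
    out <- out + w[k] * exp(-(z1^2 - 2 * r * z1 * z2 + z2^2) / (2 * s2)) /
      (2 * pi * sqrt(s2))
  }
  out
}

#' Mean of a histogram bin count
#'
#' Under the all-null model the expected count in bin `b` is
#' `G * delta_bin * dnorm(z_b)` with `z_b` the bin center (midpoint rule).
#'
#' @param G Number of genes.
#' @param spec A [histogram_spec()].
#' @param b Bin index (vector allowed); default all bins.
#' @return Expected counts.
#' @export
bin_mean <- function(G, spec, b = seq_along(spec$centers)) {
  G * spec$delta_bin * dnorm(spec$centers[b])
}

#' Pairwise mixture density Q_rho
#'
#' `Q_rho(z1, z2)` is the bivariate unit-normal density averaged over the
#' correlation density: `E_xi[ N2(z1, z2; rho = xi) ]`, evaluated by
#' Gauss-Legendre quadrature.  Symmetric in its arguments and under a joint
#' sign flip.  `alpha = Inf` gives the independence limit
#' `dnorm(z1) * dnorm(z2)`.
#'
#' @param z1,z2 Evaluation points (vectors of equal length are paired).
#' @param alpha Omnibus shape parameter (may be `Inf`).
#' @param convention Density exponent convention.
#' @param n_nodes Quadrature size.
#' @return Mixture density values.
#' @export
Q_rho <- function(z1, z2, alpha, convention = "printed", n_nodes = 120) {
  if (is.infinite(alpha)) return(dnorm(z1) * dnorm(z2))
  mix <- .qrho_mix(alpha, convention, n_nodes)
  .Qrho_pairs(z1, z2, mix$xi, mix$w)
}

#' Triplet mixture density Q_R
#'
#' `Q_R(z1, z2, z3)` is the trivariate unit-normal density averaged over the
#' density of 3x3 correlation matrices: `E_Xi[ N3(z; 0, Xi) ]`, estimated by
#' Monte Carlo over a shared seeded sample from [sample_qR()] (or a supplied
#' `R_sample`), symmetrized over the six argument permutations.
#' `alpha = Inf` gives `dnorm(z1) * dnorm(z2) * dnorm(z3)`.
#'
#' @param z1,z2,z3 Evaluation points (vectors of equal length are paired).
#' @param alpha Omnibus shape parameter (may be `Inf`).
#' @param n_mc Monte Carlo sample size when drawing internally.
#' @param seed Seed for the internal draw.
#' @param convention Density exponent convention.
#' @param R_sample Optional `n x 3` matrix of (r12, r13, r23) draws reused
#'   across evaluations.
#' @param symmetrize Average over argument permutations (default TRUE).
#' @return Mixture density values.
#' @export
Q_R <- function(z1, z2, z3, alpha = NULL, n_mc = 2e4, seed = 1,
                convention = "printed", R_sample = NULL, symmetrize = TRUE) {
  if (!is.null(alpha) && is.infinite(alpha))
    return(dnorm(z1) * dnorm(z2) * dnorm(z3))
  if (is.null(R_sample))
    R_sample <- sample_qR(alpha, n_mc, seed = seed, convention = convention)
  r12 <- R_sample[, 1]; r13 <- R_sample[, 2]; r23 <- R_sample[, 3]
  det3 <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  det3 <- pmax(det3, 1e-300)
  A11 <- (1 - r23^2) / det3; A22 <- (1 - r13^2) / det3
  A33 <- (1 - r12^2) / det3
  A12 <- (r13 * r23 - r12) / det3
  A13 <- (r12 * r23 - r13) / det3
  A23 <- (r12 * r13 - r23) / det3
  cst <- 1 / ((2 * pi)^1.5 * sqrt(det3))
  perms <- if (symmetrize) {
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
         c(3, 2, 1))
  } else list(c(1, 2, 3))
  zs <- cbind(z1, z2, z3)
  out <- numeric(nrow(zs))
  for (i in seq_len(nrow(zs))) {
    acc <- 0
    for (p in perms) {
      a <- zs[i, p[1]]; b <- zs[i, p[2]]; cc <- zs[i, p[3]]
      q <- A11 * a^2 + A22 * b^2 + A33 * cc^2 +
        2 * (A12 * a * b + A13 * a * cc + A23 * b * cc)
      acc <- acc + mean(cst * exp(-q / 2))
    }
    out[i] <- acc / length(perms)
  }
  out
}

#' Covariance of a histogram bin-count pair
#'
#' Second joint central moment of counts `(Y_b, Y_b')`:
#' `G(G-1) * delta_bin^2 * Q_rho(z_b, z_b') + delta_bb' * mu_b - mu_b mu_b'`.
#' The Kronecker term enters with a plus sign, as required by the derivation
#' from the same-gene term of the count expansion (the independence limit
#' must reduce to the multinomial covariance).
#'
#' @param G Number of genes.
#' @param spec A [histogram_spec()].
#' @param alpha Omnibus shape parameter (may be `Inf`).
#' @param b,b_prime Bin indices (vectors are paired elementwise).
#' @param convention,n_nodes Passed to [Q_rho()].
#' @return Covariances.
#' @export
bin_covariance <- function(G, spec, alpha, b, b_prime,
                           convention = "printed", n_nodes = 120) {
  zb <- spec$centers[b]; zbp <- spec$centers[b_prime]
  mu_b <- bin_mean(G, spec, b); mu_bp <- bin_mean(G, spec, b_prime)
  G * (G - 1) * spec$delta_bin^2 *
    Q_rho(zb, zbp, alpha, convention, n_nodes) +
    (b == b_prime) * mu_b - mu_b * mu_bp
}

#' Third central moment of a histogram bin-count triplet
#'
#' Third joint central moment of `(Y_b, Y_b', Y_b'')`, combining the
#' distinct-gene term `G(G-1)(G-2) * delta_bin^3 * Q_R`, the three
#' same-gene-pair Kronecker terms with `Q_rho`, the triple-coincidence mean
#' term, and the mean/covariance cross terms.  Symmetric in its bin indices.
#'
#' @inheritParams bin_covariance
#' @param b_pp Third bin index.
#' @param n_mc,seed,R_sample Passed to [Q_R()].
#' @return Third central moments.
#' @export
bin_third_moment <- function(G, spec, alpha, b, b_prime, b_pp,
                             convention = "printed", n_nodes = 120,
                             n_mc = 2e4, seed = 1, R_sample = NULL) {
  D <- spec$delta_bin
  z1 <- spec$centers[b]; z2 <- spec$centers[b_prime]; z3 <- spec$centers[b_pp]
  mu1 <- bin_mean(G, spec, b); mu2 <- bin_mean(G, spec, b_prime)
  mu3 <- bin_mean(G, spec, b_pp)
  G2 <- G * (G - 1); G3 <- G2 * (G - 2)
  E3 <- G3 * D^3 * Q_R(z1, z2, z3, alpha, n_mc, seed, convention, R_sample) +
    G2 * D^2 * ((b == b_prime) * Q_rho(z1, z3, alpha, convention, n_nodes) +
                (b == b_pp)    * Q_rho(z1, z2, alpha, convention, n_nodes) +
                (b_prime == b_pp) * Q_rho(z1, z2, alpha, convention,
                                          n_nodes)) +
    (b == b_prime & b_prime == b_pp) * mu1
  cov23 <- bin_covariance(G, spec, alpha, b_prime, b_pp, convention, n_nodes)
  cov13 <- bin_covariance(G, spec, alpha, b, b_pp, convention, n_nodes)
  cov12 <- bin_covariance(G, spec, alpha, b, b_prime, convention, n_nodes)
  E3 - mu1 * cov23 - mu2 * cov13 - mu3 * cov12 - mu1 * mu2 * mu3
}

# third central moment from the raw triple expectation and lower moments
.third_central <- function(T3, muU, muV, muW, covVW, covUW, covUV) {
  T3 - muU * covVW - muV * covUW - muW * covUV - muU * muV * muW
}

#' Moments of the tail and center counts
#'
#' Aggregates bin-count moments into means, second central moments, and
#' (for `order = 3`) the four third central moments of the pair `(F, C)`:
#' F is the count of z values in the semi-infinite rejection tail
#' `z <= delta` and C the count in the center area `|z| <= c`.
#'
#' The default `method = "region"` evaluates interval probabilities of the
#' bivariate/trivariate normal directly under the correlation mixture, so no
#' histogram truncation or midpoint error enters; `method = "bins"` sums the
#' per-bin formulas over the truncated grid (plus the analytic sub-`z_min`
#' tail mass for the mean) and exists as a cross-check of the region path.
#'
#' Supplying `rho_sample` (a vector of pairwise correlations) and, for
#' order 3, `R_sample` (an `n x 3` matrix of correlation triplets) replaces
#' the alpha-parameterized density by the empirical plug-in distributions.
#'
#' @param G Number of genes.
#' @param spec A [histogram_spec()].
#' @param alpha Omnibus shape parameter (may be `Inf` for independence).
#' @param order 2 or 3.
#' @param method `"region"` (default) or `"bins"`.
#' @param convention Density exponent convention.
#' @param n_mc Monte Carlo sample size for the triplet mixture.
#' @param seed Seed for the shared triplet sample.
#' @param n_nodes Quadrature size over the scalar correlation density.
#' @param n_x Quadrature size per interval for box probabilities.
#' @param rho_sample,R_sample Optional empirical plug-in samples.
#' @return Object of class `count_moments` with fields `mu_F`, `mu_C`,
#'   `var_F`, `var_C`, `cov_FC`, `corr_FC`, `gamma_FFF`, `gamma_FFC`,
#'   `gamma_FCC`, `gamma_CCC` (order 3 only) and `provenance`.
#' @export
count_moments <- function(G, spec = histogram_spec(), alpha, order = 3,
                          method = c("region", "bins"),
                          convention = "printed", n_mc = 2e4, seed = 1,
                          n_nodes = 120, n_x = 48,
                          rho_sample = NULL, R_sample = NULL) {
  method <- match.arg(method)
  stopifnot(order %in% c(2, 3), inherits(spec, "histogram_spec"))
  out <- if (method == "region") {
    .moments_region(G, spec, alpha, order, convention, n_mc, seed,
                    n_nodes, n_x, rho_sample, R_sample)
  } else {
    .moments_bins(G, spec, alpha, order, convention, n_mc, seed,
                  n_nodes, rho_sample, R_sample)
  }
  out$corr_FC <- out$cov_FC / sqrt(out$var_F * out$var_C)
  if (out$var_F < 0 || out$var_C < 0 || abs(out$corr_FC) > 1 + 1e-8)
    stop("inconsistent moment set (second-moment matrix not PSD); ",
         "increase n_mc / quadrature sizes")
  out$order <- order
  out$provenance <- list(G = G, alpha = alpha, spec = spec, method = method,
                         convention = convention, n_mc = n_mc, seed = seed)
  class(out) <- "count_moments"
  out
}

.moments_region <- function(G, spec, alpha, order, convention, n_mc, seed,
                            n_nodes, n_x, rho_sample, R_sample) {
  A <- c(-Inf, spec$delta)
  B <- c(-spec$c, spec$c)
  pA <- pnorm(spec$delta)
  pB <- pnorm(spec$c) - pnorm(-spec$c)
  G2 <- G * (G - 1); G3 <- G2 * (G - 2)
  indep <- is.null(rho_sample) && !is.null(alpha) && is.infinite(alpha)
  if (indep) {
    EAA <- pA^2; EBB <- pB^2; EAB <- pA * pB
  } else {
    mix <- .qrho_mix(alpha, convention, n_nodes, rho_sample)
    EAA <- sum(mix$w * .box2_given_rho(A, A, mix$xi, n_x))
    EBB <- sum(mix$w * .box2_given_rho(B, B, mix$xi, n_x))
    EAB <- sum(mix$w * .box2_given_rho(A, B, mix$xi, n_x))
  }
  out <- list(mu_F = G * pA, mu_C = G * pB,
              var_F = G2 * EAA + G * pA - (G * pA)^2,
              var_C = G2 * EBB + G * pB - (G * pB)^2,
              cov_FC = G2 * EAB - G^2 * pA * pB)
  if (order == 3) {
    if (indep) {
      EAAA <- pA^3; EAAB <- pA^2 * pB; EABB <- pA * pB^2; EBBB <- pB^3
    } else {
      if (is.null(R_sample))
        R_sample <- sample_qR(alpha, n_mc, seed = seed,
                              convention = convention, method = "halton")
      r12 <- R_sample[, 1]; r13 <- R_sample[, 2]; r23 <- R_sample[, 3]
      p3 <- function(U, V, W) mean(.box3_given_R(U, V, W, r12, r13, r23))
      EAAA <- p3(A, A, A)
      EAAB <- (p3(A, A, B) + p3(A, B, A) + p3(B, A, A)) / 3
      EABB <- (p3(A, B, B) + p3(B, A, B) + p3(B, B, A)) / 3
      EBBB <- p3(B, B, B)
    }
    T_FFF <- G3 * EAAA + 3 * G2 * EAA + G * pA
    T_FFC <- G3 * EAAB + G2 * EAB
    T_FCC <- G3 * EABB + G2 * EAB
    T_CCC <- G3 * EBBB + 3 * G2 * EBB + G * pB
    out$gamma_FFF <- .third_central(T_FFF, out$mu_F, out$mu_F, out$mu_F,
                                    out$var_F, out$var_F, out$var_F)
    out$gamma_FFC <- .third_central(T_FFC, out$mu_F, out$mu_F, out$mu_C,
                                    out$cov_FC, out$cov_FC, out$var_F)
    out$gamma_FCC <- .third_central(T_FCC, out$mu_F, out$mu_C, out$mu_C,
                                    out$var_C, out$cov_FC, out$cov_FC)
    out$gamma_CCC <- .third_central(T_CCC, out$mu_C, out$mu_C, out$mu_C,
                                    out$var_C, out$var_C, out$var_C)
  }
  out
}

.moments_bins <- function(G, spec, alpha, order, convention, n_mc, seed,
                          n_nodes, rho_sample, R_sample) {
  tail_b <- which(spec$region == "tail")
  cen_b <- which(spec$region == "center")
  bins <- c(tail_b, cen_b)
  is_tail <- c(rep(TRUE, length(tail_b)), rep(FALSE, length(cen_b)))
  z <- spec$centers[bins]
  mu <- bin_mean(G, spec, bins)
  D <- spec$delta_bin
  G2 <- G * (G - 1); G3 <- G2 * (G - 2)
  nb <- length(bins)
  indep <- is.null(rho_sample) && !is.null(alpha) && is.infinite(alpha)
  # pairwise mixture density on the bin grid
  if (indep) {
    Qm <- outer(dnorm(z), dnorm(z))
  } else {
    mix <- .qrho_mix(alpha, convention, n_nodes, rho_sample)
    Qm <- matrix(0, nb, nb)
    for (k in seq_along(mix$xi)) {
      r <- mix$xi[k]; s2 <- 1 - r^2
      Qm <- Qm + mix$w[k] *
        exp(-(outer(z^2, z^2, "+") - 2 * r * outer(z, z)) / (2 * s2)) /
        (2 * pi * sqrt(s2))
    }
  }
  phihat <- G2 * D^2 * Qm - outer(mu, mu) + diag(mu, nb)
  tail_mass <- G * pnorm(spec$z_min)   # analytic sub-z_min remainder (mean)
  out <- list(mu_F = sum(mu[is_tail]) + tail_mass,
              mu_C = sum(mu[!is_tail]),
              var_F = sum(phihat[is_tail, is_tail]),
              var_C = sum(phihat[!is_tail, !is_tail]),
              cov_FC = sum(phihat[is_tail, !is_tail]))
  if (order == 3) {
    if (indep) {
      QR <- function(i, j, k) dnorm(z[i]) * dnorm(z[j]) * dnorm(z[k])
      qr_all <- NULL
    } else {
      if (is.null(R_sample))
        R_sample <- sample_qR(alpha, n_mc, seed = seed,
                              convention = convention, method = "halton")
    }
    grid <- expand.grid(i = seq_len(nb), j = seq_len(nb), k = seq_len(nb))
    key <- apply(cbind(grid$i, grid$j, grid$k), 1L,
                 function(r) paste(sort(r), collapse = "_"))
    uniq <- !duplicated(key)
    if (indep) {
      qr_uniq <- QR(grid$i[uniq], grid$j[uniq], grid$k[uniq])
    } else {
      qr_uniq <- Q_R(z[grid$i[uniq]], z[grid$j[uniq]], z[grid$k[uniq]],
                     alpha = alpha, R_sample = R_sample)
    }
    qr_all <- qr_uniq[match(key, key[uniq])]
    i <- grid$i; j <- grid$j; k <- grid$k
    E3 <- G3 * D^3 * qr_all +
      G2 * D^2 * ((i == j) * Qm[cbind(i, k)] +
                  (i == k) * Qm[cbind(i, j)] +
                  (j == k) * Qm[cbind(i, j)]) +
      (i == j & j == k) * mu[i]
    g3 <- E3 - mu[i] * phihat[cbind(j, k)] - mu[j] * phihat[cbind(i, k)] -
      mu[k] * phihat[cbind(i, j)] - mu[i] * mu[j] * mu[k]
    ti <- is_tail[i]; tj <- is_tail[j]; tk <- is_tail[k]
    nt <- ti + tj + tk
    out$gamma_FFF <- sum(g3[nt == 3L])
    out$gamma_FFC <- sum(g3[nt == 2L]) / 3   # per ordered class (F,F,C)
    out$gamma_FCC <- sum(g3[nt == 1L]) / 3
    out$gamma_CCC <- sum(g3[nt == 0L])
  }
  out
}

#' @export
print.count_moments <- function(x, ...) {
  cat("count moments (order ", x$order, ", ", x$provenance$method,
      " path)\n", sep = "")
  cat(sprintf("  mu_F %.4g  mu_C %.4g\n", x$mu_F, x$mu_C))
  cat(sprintf("  var_F %.4g  var_C %.4g  cov_FC %.4g  corr %.4f\n",
              x$var_F, x$var_C, x$cov_FC, x$corr_FC))
  if (x$order == 3)
    cat(sprintf("  gamma FFF %.4g  FFC %.4g  FCC %.4g  CCC %.4g\n",
                x$gamma_FFF, x$gamma_FFC, x$gamma_FCC, x$gamma_CCC))
  invisible(x)
}
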