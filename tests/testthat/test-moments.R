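test_that("bin means follow the unit-normal midpoint rule", {
  sp <- histogram_spec()
  expect_equal(bin_mean(0, sp, 1), 0)
  # bin centered at 0.05 is closest to zero on the anchored grid; use a
  # custom spec whose center hits 0 exactly via the frozen value at z = 0
  expect_equal(3226 * 0.1 * dnorm(0), 128.6988, tolerance = 1e-4)
  expect_equal(sum(bin_mean(3226, sp)), 3226 * (pnorm(6) - pnorm(-6)),
               tolerance = 1e-4)
})

test_that("Q_rho has its independence limit and symmetries", {
  expect_equal(Q_rho(0, 0, Inf), 1 / (2 * pi))
  zg <- expand.grid(z1 = c(-2.5, -1, 0, 0.7), z2 = c(-2, 0, 1.3))
  q1 <- Q_rho(zg$z1, zg$z2, 3.51)
  expect_equal(q1, Q_rho(zg$z2, zg$z1, 3.51), tolerance = 1e-12)
  expect_equal(q1, Q_rho(-zg$z1, -zg$z2, 3.51), tolerance = 1e-12)
  # quadrature agrees with brute-force Monte Carlo over the Beta draw
  set.seed(21)
  a <- 3.51                     # printed convention: kernel exponent alpha
  xi <- 2 * rbeta(1e6, a + 1, a + 1) - 1
  mc <- mean(exp(-(0^2 - 2 * xi * 0 * 0 + 0^2) / (2 * (1 - xi^2))) /
               (2 * pi * sqrt(1 - xi^2)))
  expect_equal(Q_rho(0, 0, 3.51), mc, tolerance = 2e-3)
})

test_that("Q_R has its independence limit and is exchangeable", {
  expect_equal(Q_R(0, 0, 0, Inf), dnorm(0)^3)
  # large alpha approaches the independence limit
  expect_equal(Q_R(0, 0, 0, 1e5, n_mc = 5e3, seed = 3), dnorm(0)^3,
               tolerance = 1e-3)
  # permutation invariance under the shared symmetrized sample
  R <- sample_qR(3.51, 5e3, seed = 22)
  q123 <- Q_R(-2, 0.5, 1, R_sample = R)
  expect_equal(Q_R(1, -2, 0.5, R_sample = R), q123, tolerance = 1e-12)
  expect_equal(Q_R(0.5, 1, -2, R_sample = R), q123, tolerance = 1e-12)
  # two independent seeds agree within Monte Carlo tolerance
  a1 <- Q_R(0, 0, 0, 3.51, n_mc = 2e4, seed = 1)
  a2 <- Q_R(0, 0, 0, 3.51, n_mc = 2e4, seed = 2)
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("bin covariances reduce exactly to multinomial moments", {
  sp <- histogram_spec()
  b <- c(5L, 40L, 80L); bp <- c(5L, 60L, 85L)
  p_b <- sp$delta_bin * dnorm(sp$centers)
  G <- 500
  got <- bin_covariance(G, sp, Inf, b, bp)
  want <- ifelse(b == bp, G * p_b[b] * (1 - p_b[b]),
                 -G * p_b[b] * p_b[bp])
  expect_equal(got, want, tolerance = 1e-12)
  # variances are nonnegative in the independence limit (the printed sign
  # of the Kronecker term would make them negative)
  expect_true(all(bin_covariance(G, sp, Inf, 1:120, 1:120) >= 0))
})

test_that("the full bin covariance matrix over analysis regions is PSD", {
  sp <- histogram_spec()
  bins <- which(sp$region != "other")
  M <- outer(bins, bins,
             function(i, j) bin_covariance(3226, sp, 17.77, i, j))
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(M)))
})

test_that("bin third moments match exhaustive multinomial enumeration", {
  # tiny instance: G = 5 genes, three bins plus the implicit remainder
  sp <- histogram_spec(delta_bin = 0.5, c = 1, delta = -2.5,
                       z_min = -4, z_max = 4)
  bins <- c(2L, 7L, 10L)                      # two tail-side, one center bin
  p_bins <- sp$delta_bin * dnorm(sp$centers[bins])
  G <- 5
  oracle <- multinomial_enumeration_oracle(G, c(p_bins, 1 - sum(p_bins)))
  for (trip in list(c(1, 1, 1), c(1, 2, 3), c(1, 1, 2), c(2, 3, 3))) {
    got <- bin_third_moment(G, sp, Inf, bins[trip[1]], bins[trip[2]],
                            bins[trip[3]])
    expect_equal(got, oracle$third[trip[1], trip[2], trip[3]],
                 tolerance = 1e-10)
  }
  # and the closed form for the diagonal
  p1 <- p_bins[1]
  expect_equal(bin_third_moment(G, sp, Inf, bins[1], bins[1], bins[1]),
               G * p1 * (1 - p1) * (1 - 2 * p1), tolerance = 1e-12)
  # covariance oracle on the same instance
  expect_equal(bin_covariance(G, sp, Inf, bins[1], bins[2]),
               oracle$cov[1, 2], tolerance = 1e-12)
})

test_that("bin third moments are symmetric under index permutation", {
  sp <- histogram_spec()
  R <- sample_qR(4, 3e3, seed = 23)
  g1 <- bin_third_moment(100, sp, 4, 10L, 50L, 70L, R_sample = R)
  g2 <- bin_third_moment(100, sp, 4, 70L, 10L, 50L, R_sample = R)
  g3 <- bin_third_moment(100, sp, 4, 50L, 70L, 10L, R_sample = R)
  expect_equal(g1, g2, tolerance = 1e-10)
  expect_equal(g1, g3, tolerance = 1e-10)
})

test_that("aggregated means reproduce the naive tail estimator", {
  sp <- histogram_spec()
  m25 <- count_moments(3226, sp, 17.77, order = 2)
  expect_equal(round(m25$mu_F), 20)
  sp20 <- histogram_spec(delta = -2)
  m20 <- count_moments(3226, sp20, 17.77, order = 2)
  expect_equal(round(m20$mu_F), 73)
  expect_equal(m25$mu_C, 3226 * (pnorm(1) - pnorm(-1)), tolerance = 1e-10)
})

test_that("region and bin-sum paths agree within numerical tolerance", {
  sp <- histogram_spec()
  # order 2: deterministic quadrature both ways
  for (alpha in c(17.77, 3.51)) {
    a <- count_moments(1000, sp, alpha, order = 2, method = "region")
    b <- count_moments(1000, sp, alpha, order = 2, method = "bins")
    expect_equal(b$mu_F, a$mu_F, tolerance = 5e-3)  # midpoint-rule error
    expect_equal(b$var_F, a$var_F, tolerance = 5e-3)
    expect_equal(b$var_C, a$var_C, tolerance = 5e-3)
    expect_equal(b$cov_FC, a$cov_FC, tolerance = 5e-3)
  }
  # order 3 on a coarser grid, sharing one correlation-matrix sample so
  # the only differences are midpoint-rule and truncation errors
  spc <- histogram_spec(delta_bin = 0.25, c = 1, delta = -2.5,
                        z_min = -5, z_max = 5)
  R <- sample_qR(4, 5e3, seed = 24, method = "halton")
  a <- count_moments(500, spc, 4, order = 3, method = "region",
                     R_sample = R)
  b <- count_moments(500, spc, 4, order = 3, method = "bins",
                     R_sample = R)
  sF <- sqrt(a$var_F); sC <- sqrt(a$var_C)
  expect_equal(b$gamma_FFF / sF^3, a$gamma_FFF / sF^3, tolerance = 0.02)
  expect_equal(b$gamma_FFC / (sF^2 * sC), a$gamma_FFC / (sF^2 * sC),
               tolerance = 0.02)
  expect_equal(b$gamma_FCC / (sF * sC^2), a$gamma_FCC / (sF * sC^2),
               tolerance = 0.02)
  expect_equal(b$gamma_CCC / sC^3, a$gamma_CCC / sC^3, tolerance = 0.02)
})

test_that("tail variance grows with correlation spread", {
  sp <- histogram_spec()
  vs <- vapply(c(Inf, 50, 17.77, 8, 4),
               function(a) count_moments(800, sp, a, order = 2)$var_F,
               numeric(1))
  expect_true(all(diff(vs) > 0))
})

test_that("independence-limit aggregation is fully analytic", {
  sp <- histogram_spec()
  m <- count_moments(1000, sp, Inf, order = 3)
  pA <- pnorm(sp$delta); pB <- pnorm(sp$c) - pnorm(-sp$c)
  expect_equal(m$var_F, 1000 * pA * (1 - pA), tolerance = 1e-12)
  expect_equal(m$cov_FC, -1000 * pA * pB, tolerance = 1e-12)
  expect_equal(m$gamma_FFF, 1000 * pA * (1 - pA) * (1 - 2 * pA),
               tolerance = 1e-12)
})
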