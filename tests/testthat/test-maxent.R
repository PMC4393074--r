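# a count_moments-like stub for synthetic moment sets
stub_moments <- function(mu_F, mu_C, var_F, var_C, cov_FC, gamma = NULL,
                         G = 1e6) {
  m <- list(mu_F = mu_F, mu_C = mu_C, var_F = var_F, var_C = var_C,
            cov_FC = cov_FC, corr_FC = cov_FC / sqrt(var_F * var_C),
            provenance = list(G = G))
  if (!is.null(gamma)) {
    m$gamma_FFF <- gamma[1]; m$gamma_FFC <- gamma[2]
    m$gamma_FCC <- gamma[3]; m$gamma_CCC <- gamma[4]
  }
  structure(m, class = "count_moments")
}

# discrete moments of a probability matrix on a mesh
mesh_moments <- function(p, mesh) {
  f <- mesh$f[row(p)]; cc <- mesh$c[col(p)]
  mu_F <- sum(p * f); mu_C <- sum(p * cc)
  list(mu_F = mu_F, mu_C = mu_C,
       var_F = sum(p * (f - mu_F)^2), var_C = sum(p * (cc - mu_C)^2),
       cov_FC = sum(p * (f - mu_F) * (cc - mu_C)),
       gamma = c(sum(p * (f - mu_F)^3),
                 sum(p * (f - mu_F)^2 * (cc - mu_C)),
                 sum(p * (f - mu_F) * (cc - mu_C)^2),
                 sum(p * (cc - mu_C)^3)))
}

test_that("the mesh covers mean +/- k sd, clipped to the domain", {
  m <- stub_moments(20, 2000, 900, 10000, 0)
  mesh <- build_mesh(m, G = 1e6, n_F = 50, n_C = 50, k = 6)
  expect_equal(range(mesh$f), c(0, 200))            # clip at zero
  expect_equal(range(mesh$c), c(1400, 2600))
  expect_true(all(mesh$mask))
  # tiny G: infeasible cells are masked out
  m2 <- stub_moments(3, 5, 4, 4, 0, G = 10)
  mesh2 <- build_mesh(m2, G = 10, n_F = 30, n_C = 30)
  expect_false(all(mesh2$mask))
  expect_true(all(outer(mesh2$f, mesh2$c, "+")[mesh2$mask] <= 10))
})

test_that("uncorrelated order-2 maxent is the discretized Gaussian", {
  m <- stub_moments(50, 400, 100, 900, 0)
  mesh <- build_mesh(m, G = 1e6, n_F = 80, n_C = 120)
  # the discretized Gaussian on this mesh, with ITS mesh moments as
  # targets, is the exact maxent solution: recover it to high accuracy
  gau <- outer(dnorm(mesh$f, 50, 10), dnorm(mesh$c, 400, 30))
  gau <- gau / sum(gau)
  mm <- mesh_moments(gau, mesh)
  fit <- fit_maxent(stub_moments(mm$mu_F, mm$mu_C, mm$var_F, mm$var_C,
                                 mm$cov_FC),
                    mesh, order = 2)
  expect_lt(0.5 * sum(abs(fit$p - gau)), 1e-6)      # total variation
  expect_lt(max(abs(fit$p - gau)), 1e-8)
})

test_that("order 3 with matched third moments reduces to order 2", {
  m <- stub_moments(50, 400, 100, 900, -150)
  mesh <- build_mesh(m, G = 1e6, n_F = 60, n_C = 90)
  fit2 <- fit_maxent(m, mesh, order = 2)
  mm <- mesh_moments(fit2$p, mesh)
  m3 <- stub_moments(mm$mu_F, mm$mu_C, mm$var_F, mm$var_C, mm$cov_FC,
                     gamma = mm$gamma)
  fit3 <- fit_maxent(m3, mesh, order = 3)
  expect_lt(max(abs(fit3$lambda[6:9])), 1e-4)       # cubic terms vanish
  expect_lt(0.5 * sum(abs(fit3$p - fit2$p)), 1e-4)
})

test_that("maxent matches a brute-force primal solver on a 12 x 12 mesh", {
  m <- stub_moments(10, 20, 4, 9, -2.4,
                    gamma = c(2.4, -1.6, 1.2, -4.0))
  mesh <- structure(list(f = seq(2, 18, length.out = 12),
                         c = seq(8, 32, length.out = 12),
                         mask = matrix(TRUE, 12, 12), G = 1e6),
                    class = "support_mesh")
  fit <- fit_maxent(m, mesh, order = 3)
  # independent oracle: maximize entropy directly over the 144 cell
  # probabilities (softmax parameterization, augmented-Lagrangian on the
  # moment constraints, generic BFGS inner solver)
  sF <- 2; sC <- 3
  ft <- (mesh$f[row(mesh$mask)] - 10) / sF
  ct <- (mesh$c[col(mesh$mask)] - 20) / sC
  A <- cbind(ft, ct, ft^2, ft * ct, ct^2, ft^3, ft^2 * ct, ft * ct^2, ct^3)
  targ <- c(0, 0, 1, -2.4 / (sF * sC), 1, 2.4 / sF^3, -1.6 / (sF^2 * sC),
            1.2 / (sF * sC^2), -4.0 / sC^3)
  oracle <- softmax_entropy_oracle(A, targ)
  p_oracle <- matrix(oracle$p, 12, 12)
  expect_lt(max(abs(oracle$viol)), 1e-7)
  expect_lt(max(abs(fit$p - p_oracle)), 1e-6)
  # entropy of the dual fit is no smaller than the feasible oracle's
  ent <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  expect_gte(ent(fit$p), ent(p_oracle) - 1e-8)
})

test_that("achieved moments satisfy the optimality certificate", {
  sp <- histogram_spec()
  mom <- count_moments(500, sp, 4, order = 3, n_mc = 5e3, seed = 31)
  fit <- fit_maxent(mom, build_mesh(mom, 500, n_F = 60, n_C = 150),
                    order = 3)
  expect_lt(max(abs(fit$achieved - fit$targets)), 1e-6)
  expect_equal(sum(fit$p), 1, tolerance = 1e-10)
  expect_true(all(fit$p >= 0))
})

test_that("conditional slices behave as contracts require", {
  # independent joint: every conditional equals the F marginal
  m <- stub_moments(50, 400, 100, 900, 0)
  mesh <- build_mesh(m, G = 1e6, n_F = 60, n_C = 80)
  fit <- fit_maxent(m, mesh, order = 2)
  marg <- rowSums(fit$p)
  for (C0 in c(380, 400, 425)) {
    cond <- conditional(fit, C0)
    expect_equal(cond$p, marg / sum(marg), tolerance = 1e-8)
  }
  # strongly negative correlation: conditional mean decreases in C
  m2 <- stub_moments(50, 400, 100, 900, -270)
  fit2 <- fit_maxent(m2, build_mesh(m2, G = 1e6, n_F = 60, n_C = 80),
                     order = 2)
  means <- vapply(c(350, 400, 450), function(C0)
    conditional(fit2, C0)$mean, numeric(1))
  expect_true(all(diff(means) < 0))
  # out-of-mesh center count is an informative error
  expect_error(conditional(fit2, 4000), "outside the mesh")
  # interval nesting and exceedance bounds
  cond <- conditional(fit2, 400)
  i50 <- conditional_interval(cond, 0.5)
  i75 <- conditional_interval(cond, 0.75)
  expect_lte(i75[1], i50[1]); expect_gte(i75[2], i50[2])
  expect_equal(exceedance_prob(cond, min(cond$f)), 1)
  expect_lt(exceedance_prob(cond, cond$mean + 3 * 10), 0.05)
})

test_that("doubling the mesh resolution barely moves the conditional mean", {
  # the reference configuration: G = 3226, alpha = 17.77, 100 x 500 mesh
  sp <- histogram_spec()
  mom <- count_moments(3226, sp, 17.77, order = 2)
  C0 <- round(mom$mu_C)
  est <- vapply(c(1, 2), function(k) {
    fit <- fit_maxent(mom, build_mesh(mom, 3226, n_F = 100 * k,
                                      n_C = 500 * k), order = 2)
    conditional(fit, C0)$mean
  }, numeric(1))
  expect_lt(abs(est[2] - est[1]) / est[1], 0.01)
})

test_that("exceedance control selects thresholds monotonically in lambda", {
  # vacuous bound: the least extreme candidate is always accepted
  set.seed(32)
  z <- rnorm(500)
  ctrl <- control_discoveries(z, alpha = 8, gamma = 1, lambda = 0.999,
                              delta_grid = c(-3, -2.5, -2), order = 2)
  ok <- ctrl$table[!is.na(ctrl$table$pass) & ctrl$table$G_star > 0, ]
  expect_equal(ctrl$selected_delta, max(ok$delta))
  # simulated correlated null panel: selected G* shrinks as lambda drops
  panel <- make_correlated_panel(6, G = 500, M = 16, seed = 33)
  sc <- score_panel(panel)
  gs <- vapply(c(0.9, 0.5, 0.2), function(l) {
    r <- control_discoveries(sc$z, alpha = 6, gamma = 0.3, lambda = l,
                             delta_grid = c(-3, -2.5, -2, -1.5),
                             order = 2)
    if (is.na(r$G_star)) 0L else r$G_star
  }, integer(1))
  expect_true(all(diff(gs) <= 0))
})
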