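# Internal numerical utilities: Gauss-Legendre rules, bivariate/trivariate
# normal box probabilities, and quadrature nodes for the correlation density.

.fdm_cache <- new.env(parent = emptyenv())

# Golub-Welsch: nodes/weights for Gauss-Legendre on [-1, 1].
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.fdm_cache[[key]])) return(.fdm_cache[[key]])
  stopifnot(n >= 1)
  if (n == 1L) {
    out <- list(nodes = 0, weights = 2)
  } else {
    k <- seq_len(n - 1L)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1L)] <- beta
    J[cbind(k + 1L, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    out <- list(nodes = e$values[ord], weights = (2 * e$vectors[1, ]^2)[ord])
  }
  .fdm_cache[[key]] <- out
  out
}

# Rescale a Gauss-Legendre rule to [lo, hi]; semi-infinite ends are truncated
# at +/- 8.5 where the unit normal carries ~1e-17 mass.
.gl_interval <- function(lo, hi, n) {
  lo <- max(lo, -8.5)
  hi <- min(hi, 8.5)
  gq <- gauss_legendre(n)
  list(x = (hi + lo) / 2 + (hi - lo) / 2 * gq$nodes,
       w = (hi - lo) / 2 * gq$weights)
}

# Evaluate-and-restore RNG scoping so seeded helpers do not disturb the
# caller's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# P(x in U, y in V | rho), vectorized over rho.  One-dimensional quadrature
# over U with the exact conditional normal for the second coordinate.
.box2_given_rho <- function(U, V, rho, n_x = 48) {
  g <- .gl_interval(U[1], U[2], n_x)
  s <- sqrt(pmax(1 - rho^2, 1e-14))
  M <- outer(rho, g$x)                       # n_rho x n_x conditional means
  S <- matrix(s, length(rho), length(g$x))
  inner <- pnorm((V[2] - M) / S)
  if (is.finite(V[1])) inner <- inner - pnorm((V[1] - M) / S)
  as.vector(inner %*% (g$w * dnorm(g$x)))
}

# P(x in U, y in V, z in W | R), vectorized over draws of R given as three
# off-diagonal vectors (r12, r13, r23).  Two-dimensional quadrature over
# U x V with the exact conditional normal for the third coordinate.
.box3_given_R <- function(U, V, W, r12, r13, r23, n_x = 24,
                          chunk = 4000L) {
  gu <- .gl_interval(U[1], U[2], n_x)
  gv <- .gl_interval(V[1], V[2], n_x)
  x1 <- rep(gu$x, times = length(gv$x))
  x2 <- rep(gv$x, each = length(gu$x))
  wgrid <- as.vector(outer(gu$w, gv$w))      # length ngrid
  n <- length(r12)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    a12 <- r12[idx]; a13 <- r13[idx]; a23 <- r23[idx]
    den <- pmax(1 - a12^2, 1e-14)
    c1 <- (a13 - a12 * a23) / den
    c2 <- (a23 - a12 * a13) / den
    s3 <- sqrt(pmax(1 - a13 * c1 - a23 * c2, 1e-14))
    # bivariate normal density of (x1, x2) for each draw: n_i x ngrid
    q <- outer(1 / den, x1^2 + x2^2) - 2 * outer(a12 / den, x1 * x2)
    f12 <- exp(-q / 2) / (2 * pi * sqrt(den))
    m3 <- outer(c1, x1) + outer(c2, x2)
    S3 <- matrix(s3, length(idx), length(x1))
    inner <- pnorm((W[2] - m3) / S3)
    if (is.finite(W[1])) inner <- inner - pnorm((W[1] - m3) / S3)
    out[idx] <- (f12 * inner) %*% wgrid
  }
  out
}

# Halton low-discrepancy sequence (first `dim` prime bases, index offset 20)
.halton_matrix <- function(n, dim) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19)[seq_len(dim)]
  idx <- seq_len(n) + 20L
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- bases[d]
    i <- idx
    f <- 1 / b
    r <- numeric(n)
    while (any(i > 0)) {
      r <- r + f * (i %% b)
      i <- i %/% b
      f <- f / b
    }
    out[, d] <- r
  }
  out
}

# log normalization constant of (1 - xi^2)^a on [-1, 1]:
# integral = sqrt(pi) * Gamma(a + 1) / Gamma(a + 3/2).
.qrho_lognorm <- function(a) 0.5 * log(pi) + lgamma(a + 1) - lgamma(a + 1.5)

# Quadrature nodes (xi) and probability weights (w, summing to ~1) for the
# correlation density with kernel exponent `a`, via the substitution
# xi = sin(theta) which removes the endpoint singularity for a >= -1/2.
.qrho_nodes <- function(a, n = 120) {
  gq <- gauss_legendre(n)
  th <- gq$nodes * (pi / 2)
  w <- gq$weights * (pi / 2) * exp((2 * a + 1) * log(cos(th)) -
                                     .qrho_lognorm(a))
  list(xi = sin(th), w = w)
}
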