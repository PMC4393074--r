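# Maximum-entropy fit of the joint distribution p(F, C) from its moments.
#
# The joint distribution of the tail count F and center count C is
# approximated by the maximum-entropy distribution on an equispaced mesh
# over the feasible domain {f >= 0, c >= 0, f + c <= G} matching the
# estimated moments.  The fit has exponential-family form with monomial
# sufficient statistics (total degree <= order) in normalized coordinates
# (each axis centered and scaled by its standard deviation, which
# conditions the cubic terms), and is solved through the convex dual by a
# damped Newton iteration; the quadratic part of the known Gaussian
# solution provides the initial point.

#' Build the support mesh for the joint (F, C) distribution
#'
#' Equispaced grids covering mean +/- k standard deviations on each axis,
#' clipped to `[0, G]`, with cells violating `f + c <= G` masked out.
#' When the moment set carries third moments, each axis is extended by
#' `2 |skewness|` standard deviations on the side the skew points to: a
#' cubic-constrained maximum-entropy fit places mass well beyond the
#' Gaussian range there, and too tight a box can make strongly skewed
#' moment sets infeasible.
#'
#' @param moments A [count_moments()] object.
#' @param G Number of genes; defaults to the provenance value.
#' @param n_F,n_C Mesh sizes (defaults 100 x 500).
#' @param k Half-width of each axis in standard deviations (default 6).
#' @return Object of class `support_mesh` with axis grids `f`, `c`, logical
#'   `mask`, and `G`.
#' @export
build_mesh <- function(moments, G = moments$provenance$G, n_F = 100,
                       n_C = 500, k = 6) {
  sF <- sqrt(moments$var_F); sC <- sqrt(moments$var_C)
  if (sF <= 0 || sC <= 0) stop("degenerate (zero-variance) axis")
  skF <- if (is.null(moments$gamma_FFF)) 0 else moments$gamma_FFF / sF^3
  skC <- if (is.null(moments$gamma_CCC)) 0 else moments$gamma_CCC / sC^3
  f <- seq(max(0, moments$mu_F - (k + 2 * max(0, -skF)) * sF),
           min(G, moments$mu_F + (k + 2 * max(0, skF)) * sF),
           length.out = n_F)
  cg <- seq(max(0, moments$mu_C - (k + 2 * max(0, -skC)) * sC),
            min(G, moments$mu_C + (k + 2 * max(0, skC)) * sC),
            length.out = n_C)
  mask <- outer(f, cg, "+") <= G
  if (!any(mask)) stop("empty feasibility mask")
  structure(list(f = f, c = cg, mask = mask, G = G), class = "support_mesh")
}

.maxent_design <- function(ft, ct, order) {
  Tm <- cbind(f = ft, c = ct, ff = ft^2, fc = ft * ct, cc = ct^2)
  if (order == 3)
    Tm <- cbind(Tm, fff = ft^3, ffc = ft^2 * ct, fcc = ft * ct^2, ccc = ct^3)
  Tm
}

.maxent_targets <- function(moments, order) {
  sF <- sqrt(moments$var_F); sC <- sqrt(moments$var_C)
  r <- moments$cov_FC / (sF * sC)
  t <- c(0, 0, 1, r, 1)
  if (order == 3) {
    if (is.null(moments$gamma_FFF))
      stop("order 3 requires the four third central moments")
    t <- c(t, moments$gamma_FFF / sF^3, moments$gamma_FFC / (sF^2 * sC),
           moments$gamma_FCC / (sF * sC^2), moments$gamma_CCC / sC^3)
  }
  t
}

#' Fit the maximum-entropy joint distribution of (F, C)
#'
#' @param moments A [count_moments()] object (order 3 moments required for
#'   `order = 3`).
#' @param mesh A [build_mesh()] object (default built from `moments`).
#' @param order Moment order to match, 2 or 3.
#' @param tol Convergence tolerance on the maximum constraint violation.
#' @param max_iter Newton iteration cap.
#' @return Object of class `joint_count_distribution`: mesh, probability
#'   matrix `p` (masked cells zero), `lambda`, achieved and target moments,
#'   and a convergence report.
#' @export
fit_maxent <- function(moments, mesh = build_mesh(moments), order = 3,
                       tol = 1e-8, max_iter = 300) {
  stopifnot(order %in% c(2, 3))
  mu <- c(moments$mu_F, moments$mu_C)
  sF <- sqrt(moments$var_F); sC <- sqrt(moments$var_C)
  idx <- which(mesh$mask)
  fi <- (row(mesh$mask))[idx]; ci <- (col(mesh$mask))[idx]
  ft <- (mesh$f[fi] - mu[1]) / sF
  ct <- (mesh$c[ci] - mu[2]) / sC
  Tm <- .maxent_design(ft, ct, order)
  targ <- .maxent_targets(moments, order)
  # standardize the sufficient statistics w.r.t. the uniform mesh measure:
  # an affine reparameterization of the same exponential family that keeps
  # the Newton system well conditioned when cubic terms span a wide mesh
  m0 <- colMeans(Tm); s0 <- apply(Tm, 2L, stats::sd)
  Ts <- sweep(sweep(Tm, 2L, m0), 2L, s0, "/")
  ts <- (targ - m0) / s0
  r <- targ[4]
  Qi <- solve(matrix(c(1, r, r, 1), 2))
  lam0 <- numeric(ncol(Tm))
  lam0[3] <- -0.5 * Qi[1, 1]; lam0[4] <- -Qi[1, 2]; lam0[5] <- -0.5 * Qi[2, 2]
  lambda <- lam0 * s0                      # same density in scaled coordinates
  dual <- function(l) {
    eta <- Ts %*% l
    m <- max(eta)
    m + log(sum(exp(eta - m))) - sum(l * ts)
  }
  conv <- FALSE; gmax <- Inf; damp <- 1e-8
  f0 <- dual(lambda)
  for (it in seq_len(max_iter)) {
    eta <- drop(Ts %*% lambda)
    eta <- eta - max(eta)
    w <- exp(eta); w <- w / sum(w)
    m1 <- drop(crossprod(Ts, w))
    g <- m1 - ts
    gmax <- max(abs(g * s0))     # violation on the reported statistics
    if (gmax < tol) { conv <- TRUE; break }
    H <- crossprod(Ts * w, Ts) - tcrossprod(m1)
    # Levenberg-Marquardt damping: retry with heavier damping until the
    # convex dual decreases
    repeat {
      step <- tryCatch(solve(H + diag(damp, ncol(Ts)), g),
                       error = function(e) NULL)
      fnew <- if (is.null(step)) Inf else dual(lambda - step)
      if (fnew < f0 + abs(f0) * 1e-14) {
        lambda <- lambda - step
        f0 <- min(fnew, f0)
        damp <- max(damp / 10, 1e-12)
        break
      }
      damp <- damp * 10
      if (damp > 1e12) break
    }
    if (damp > 1e12) break   # dual stagnates at floating-point resolution
  }
  if (!conv && gmax < 1e-6) conv <- TRUE
  if (!conv)
    stop("maxent dual did not converge in ", it,
         " iterations (max violation ", signif(gmax, 3),
         "); the moment set may be infeasible on this mesh")
  eta <- drop(Ts %*% lambda); eta <- eta - max(eta)
  w <- exp(eta); w <- w / sum(w)
  lambda <- lambda / s0                    # report on the unscaled monomials
  p <- matrix(0, length(mesh$f), length(mesh$c))
  p[idx] <- w
  structure(list(mesh = mesh, p = p, lambda = lambda,
                 achieved = drop(crossprod(Tm, w)), targets = targ,
                 order = order,
                 convergence = list(iterations = it, grad_max = gmax,
                                    converged = conv)),
            class = "joint_count_distribution")
}

#' @export
print.joint_count_distribution <- function(x, ...) {
  cat("maxent joint distribution of (F, C): order ", x$order, ", ",
      length(x$mesh$f), " x ", length(x$mesh$c), " mesh, ",
      x$convergence$iterations, " iterations (max violation ",
      signif(x$convergence$grad_max, 2), ")\n", sep = "")
  invisible(x)
}

#' Conditional distribution of F given the observed center count
#'
#' Slices the joint distribution at the mesh column nearest to `C_obs`
#' (ties resolved to the lower value) and renormalizes.
#'
#' @param joint A [fit_maxent()] result.
#' @param C_obs Observed center count; must lie within the mesh C range.
#' @return Object of class `conditional_F` with the F grid, probabilities,
#'   `mean`, `median` and the C value used.
#' @export
conditional <- function(joint, C_obs) {
  mesh <- joint$mesh
  if (C_obs < min(mesh$c) - 1e-9 || C_obs > max(mesh$c) + 1e-9)
    stop("C_obs = ", C_obs, " is outside the mesh C range [",
         signif(min(mesh$c), 6), ", ", signif(max(mesh$c), 6),
         "]; rebuild the mesh with a larger k or check the center count")
  d <- abs(mesh$c - C_obs)
  j <- which(d == min(d))[1L]
  p <- joint$p[, j]
  if (sum(p) <= 0) stop("zero-mass conditional slice at C = ", mesh$c[j])
  p <- p / sum(p)
  cdf <- cumsum(p)
  structure(list(f = mesh$f, p = p, C_used = mesh$c[j], C_obs = C_obs,
                 mean = sum(mesh$f * p),
                 median = mesh$f[which(cdf >= 0.5)[1L]]),
            class = "conditional_F")
}

#' Central credible interval of a conditional F distribution
#'
#' @param cond A [conditional()] result.
#' @param level Interval mass (default 0.5; the reference analyses report
#'   50 and 75 percent intervals).
#' @return Length-2 vector of F values.
#' @export
conditional_interval <- function(cond, level = 0.5) {
  cdf <- cumsum(cond$p)
  lo <- cond$f[which(cdf >= (1 - level) / 2)[1L]]
  hi <- cond$f[which(cdf >= 1 - (1 - level) / 2)[1L]]
  c(lower = lo, upper = hi)
}

#' Conditional exceedance probability P(F >= f0 | C)
#'
#' @param cond A [conditional()] result.
#' @param f0 Threshold.
#' @return Probability.
#' @export
exceedance_prob <- function(cond, f0) sum(cond$p[cond$f >= f0])

#' @export
print.conditional_F <- function(x, ...) {
  ci50 <- conditional_interval(x, 0.5)
  cat("p(F | C = ", signif(x$C_obs, 6), "): mean ", signif(x$mean, 4),
      ", median ", signif(x$median, 4), ", 50% interval [",
      signif(ci50[1], 4), ", ", signif(ci50[2], 4), "]\n", sep = "")
  invisible(x)
}

#' Exceedance-bound discovery control over a tail-threshold grid
#'
#' Scans candidate tail thresholds delta from most to least extreme; for
#' each, recomputes the count moments, the maxent joint, and the
#' conditional distribution of F at the observed center count, and
#' evaluates the exceedance bound `P(F / G_star >= gamma | C) <= lambda`
#' where `G_star` is the number of scores at or below delta.  Returns the
#' least extreme delta whose bound holds, with the full scan table.
#'
#' @param z Vector of z values.
#' @param alpha Omnibus correlation parameter.
#' @param gamma Tolerated false-discovery proportion, in (0, 1].
#' @param lambda Probability bound, in (0, 1).
#' @param delta_grid Candidate thresholds (each must sit on a bin edge).
#' @param spec A [histogram_spec()] providing the bin width, center
#'   half-width and truncation range.
#' @param order Moment order for the maxent fit.
#' @param n_F,n_C Mesh sizes.
#' @param ... Passed to [count_moments()].
#' @return List with `selected_delta` (NA if no candidate passes),
#'   `G_star`, and the scan `table`.
#' @export
control_discoveries <- function(z, alpha, gamma = 0.15, lambda = 0.5,
                                delta_grid = seq(-3.5, -1.5, by = 0.5),
                                spec = histogram_spec(), order = 3,
                                n_F = 60, n_C = 200, ...) {
  stopifnot(gamma > 0, gamma <= 1, lambda > 0, lambda < 1)
  delta_grid <- sort(delta_grid)          # most extreme (most negative) first
  G <- length(z)
  rows <- lapply(delta_grid, function(d) {
    sp <- histogram_spec(delta_bin = spec$delta_bin, c = spec$c, delta = d,
                         z_min = spec$z_min, z_max = spec$z_max)
    cnt <- observed_counts(z, sp)
    if (cnt["tail"] < 1L)
      return(data.frame(delta = d, G_star = 0L, C_obs = cnt["center"],
                        p_exceed = NA_real_, pass = NA))
    res <- tryCatch({
      mom <- count_moments(G, sp, alpha, order = order, ...)
      joint <- fit_maxent(mom, build_mesh(mom, G, n_F = n_F, n_C = n_C),
                          order = order)
      cond <- conditional(joint, cnt["center"])
      pe <- exceedance_prob(cond, gamma * cnt["tail"])
      data.frame(delta = d, G_star = as.integer(cnt["tail"]),
                 C_obs = cnt["center"], p_exceed = pe, pass = pe <= lambda)
    }, error = function(e)
      data.frame(delta = d, G_star = as.integer(cnt["tail"]),
                 C_obs = cnt["center"], p_exceed = NA_real_, pass = NA))
    res
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- which(!is.na(tab$pass) & tab$pass)
  sel <- if (length(ok)) max(ok) else NA_integer_  # least extreme passing
  list(selected_delta = if (is.na(sel)) NA_real_ else tab$delta[sel],
       G_star = if (is.na(sel)) NA_integer_ else tab$G_star[sel],
       table = tab)
}
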