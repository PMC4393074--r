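#' Estimate the false-discovery count distribution for a panel
#'
#' Runs the complete analysis on an expression panel: pooled two-sample t
#' statistics, probit transform to z values, observed tail and center
#' counts, estimation of the omnibus correlation parameter alpha from the
#' standardized residuals, moment propagation, maxent fit of the joint
#' (F, C) distribution, and the conditional distribution of the
#' false-discovery count F given the observed center count.
#'
#' @param panel An [expression_panel()].
#' @param spec A [histogram_spec()].
#' @param order Moment order (2 or 3).
#' @param alpha Optional: fix the omnibus parameter instead of estimating.
#' @param n_F,n_C Mesh sizes (defaults 100 x 500).
#' @param n_mc Monte Carlo size for the triplet mixture.
#' @param seed Seed for all internal randomness.
#' @param max_pairs,sampling_var Passed to [estimate_alpha()].
#' @return Object of class `fd_estimate`: the alpha model, observed counts,
#'   the [count_moments()], the maxent joint, the conditional distribution,
#'   the posterior-mean point estimate and 50/75 percent intervals, and the naive
#'   mean estimate `G * pnorm(delta)` for reference.
#' @export
estimate_false_discoveries <- function(panel, spec = histogram_spec(),
                                       order = 3, alpha = NULL, n_F = 100,
                                       n_C = 500, n_mc = 2e4, seed = 1,
                                       max_pairs = 5e5,
                                       sampling_var = NULL) {
  stopifnot(inherits(panel, "expression_panel"))
  G <- nrow(panel$values)
  sc <- score_panel(panel, spec)
  model <- NULL
  if (is.null(alpha)) {
    model <- estimate_alpha(panel, max_pairs = max_pairs, seed = seed,
                            sampling_var = sampling_var)
    alpha <- model$alpha
  }
  mom <- count_moments(G, spec, alpha, order = order, n_mc = n_mc,
                       seed = seed)
  joint <- fit_maxent(mom, build_mesh(mom, G, n_F = n_F, n_C = n_C),
                      order = order)
  cond <- conditional(joint, sc$counts["center"])
  structure(list(alpha = alpha, alpha_model = model, counts = sc$counts,
                 z = sc$z, moments = mom, joint = joint,
                 conditional = cond, estimate = cond$mean,
                 interval50 = conditional_interval(cond, 0.5),
                 interval75 = conditional_interval(cond, 0.75),
                 mean_estimator = G * pnorm(spec$delta), spec = spec),
            class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat("false-discovery estimate (order ", x$moments$order, ")\n", sep = "")
  cat("  alpha          ", signif(x$alpha, 5), "\n", sep = "")
  cat("  observed counts: tail ", x$counts["tail"], ", center ",
      x$counts["center"], "\n", sep = "")
  cat("  corr(F, C)     ", sprintf("%.3f", x$moments$corr_FC), "\n",
      sep = "")
  cat("  E[F | C]       ", signif(x$estimate, 5),
      "  (naive mean ", signif(x$mean_estimator, 4), ")\n", sep = "")
  cat("  50% interval   [", signif(x$interval50[1], 4), ", ",
      signif(x$interval50[2], 4), "]\n", sep = "")
  invisible(x)
}
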