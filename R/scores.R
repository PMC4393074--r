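#' Pooled-variance two-sample t statistics
#'
#' Computes the usual equal-variance two-sample t statistic per gene
#' (group 1 minus group 2), with M - 2 degrees of freedom.
#'
#' @param panel An [expression_panel()].
#' @return List with `t` (per-gene statistics) and `df`.
#' @export
two_sample_t <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  X <- panel$values
  g1 <- panel$groups == 1L
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 arrays")
  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, g2, drop = FALSE])
  ss1 <- rowSums((X[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((X[, g2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  bad <- sp2 <= 0
  if (any(bad))
    stop("zero pooled variance; t undefined for gene(s): ",
         paste(utils::head(panel$gene_ids[bad], 5L), collapse = ", "),
         if (sum(bad) > 5L) ", ...")
  list(t = (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)), df = df)
}

#' Transform t statistics to z values
#'
#' Maps each t statistic through its putative null Student-t cdf and the
#' unit-normal quantile function, `z = qnorm(pt(t, df))`, so that under the
#' null every z is a unit normal variate.  Evaluated on the log scale so
#' extreme statistics do not saturate.
#'
#' @param t Numeric vector of t statistics.
#' @param df Degrees of freedom (>= 1).
#' @return Numeric vector of z values.
#' @export
t_to_z <- function(t, df) {
  if (df < 1) stop("df must be >= 1")
  if (any(!is.finite(t))) stop("non-finite t statistic")
  qnorm(pt(t, df, log.p = TRUE), log.p = TRUE)
}

#' Histogram specification for z values
#'
#' Defines the binning grid and the two analysis regions: the semi-infinite
#' rejection tail (left-sided by default, z <= delta) and the zero-symmetric
#' center area |z| <= c assumed to contain only null scores.  Bin edges are
#' anchored at zero, so `c`, `delta`, `z_min` and `z_max` must be integer
#' multiples of the bin width.
#'
#' @param delta_bin Bin width (default 0.1).
#' @param c Center half-width (default 1).
#' @param delta Tail threshold (default -2.5).
#' @param z_min,z_max Truncation bounds of the binned range (defaults -6, 6);
#'   the unit normal carries only ~1e-9 mass beyond |z| = 6.
#' @param tail_side Only `"left"` is implemented.
#' @return Object of class `histogram_spec` with bin edges, centers, and a
#'   per-bin region label in `"tail"`, `"center"`, `"other"`.
#' @export
histogram_spec <- function(delta_bin = 0.1, c = 1, delta = -2.5,
                           z_min = -6, z_max = 6, tail_side = "left") {
  tail_side <- match.arg(tail_side, "left")
  stopifnot(delta_bin > 0)
  if (!(z_min < delta && delta <= -c && -c < 0 && 0 < c && c < z_max))
    stop("need z_min < delta <= -c < 0 < c < z_max")
  on_edge <- function(x) abs(x / delta_bin - round(x / delta_bin)) < 1e-8
  if (!all(on_edge(c(z_min, z_max, c, delta))))
    stop("z_min, z_max, c and delta must fall on bin edges ",
         "(integer multiples of delta_bin)")
  edges <- seq(z_min, z_max, by = delta_bin)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  lo <- edges[-length(edges)]; hi <- edges[-1L]
  region <- rep("other", length(centers))
  region[hi <= delta + 1e-12] <- "tail"
  region[lo >= -c - 1e-12 & hi <= c + 1e-12] <- "center"
  structure(list(delta_bin = delta_bin, c = c, delta = delta,
                 z_min = z_min, z_max = z_max, tail_side = tail_side,
                 edges = edges, centers = centers, region = region),
            class = "histogram_spec")
}

#' Bin z values on the histogram grid
#'
#' Assigns each score to a half-open bin `[edge, edge)`; scores at or beyond
#' `z_max`, or below `z_min`, are counted as out of range (a score exactly at
#' a boundary such as -c therefore lands in the bin to its right, i.e. on the
#' center side).
#'
#' @param z Numeric vector of z values.
#' @param spec A [histogram_spec()].
#' @return Object of class `bin_counts`: integer `counts` per bin, bin
#'   `centers`, `region` labels, and `n_out_of_range`.
#' @export
bin_scores <- function(z, spec) {
  stopifnot(inherits(spec, "histogram_spec"))
  if (any(!is.finite(z))) stop("non-finite z value")
  idx <- findInterval(z, spec$edges, left.open = FALSE)
  B <- length(spec$centers)
  inside <- idx >= 1L & idx <= B
  counts <- tabulate(idx[inside], nbins = B)
  structure(list(counts = counts, centers = spec$centers,
                 region = spec$region,
                 n_out_of_range = sum(!inside)),
            class = "bin_counts")
}

#' Observed tail and center counts
#'
#' Counts scores from the raw z values (not the truncated bins): the tail
#' count is `#\{z <= delta\}` and the center count is `#\{|z| <= c\}`.
#'
#' @param z Numeric vector of z values.
#' @param spec A [histogram_spec()].
#' @return Named integer vector `c(tail = ..., center = ...)`.
#' @export
observed_counts <- function(z, spec) {
  stopifnot(inherits(spec, "histogram_spec"))
  c(tail = sum(z <= spec$delta), center = sum(abs(z) <= spec$c))
}

#' Full score pipeline: panel to z values and counts
#'
#' Convenience wrapper: pooled two-sample t, probit transform to z, and the
#' observed (tail, center) counts.
#'
#' @param panel An [expression_panel()].
#' @param spec A [histogram_spec()].
#' @return List with `z`, `df`, and `counts` (named tail/center vector).
#' @export
score_panel <- function(panel, spec = histogram_spec()) {
  ts <- two_sample_t(panel)
  z <- t_to_z(ts$t, ts$df)
  list(z = z, df = ts$df, counts = observed_counts(z, spec))
}
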