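#' Construct an expression panel
#'
#' An expression panel couples a gene-by-array matrix of expression values
#' with a two-group design.  Genes are rows, arrays (microarrays) are
#' columns, and each column belongs to treatment group 1 or 2.
#'
#' @param values Numeric matrix, genes in rows, arrays in columns.
#' @param groups Vector of length `ncol(values)` assigning each array to
#'   group 1 or 2 (coerced with `as.integer`; labels `"1"`/`"2"` accepted).
#' @param gene_ids Character vector of unique row identifiers; defaults to
#'   `rownames(values)` or `gene_1..gene_G`.
#' @param log_transformed Logical flag recording whether `values` are on the
#'   natural-log scale.
#' @return An object of class `expression_panel` with elements `values`,
#'   `gene_ids`, `groups` and `log_transformed`.
#' @export
expression_panel <- function(values, groups, gene_ids = NULL,
                             log_transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("expression values contain missing entries")
  G <- nrow(values); M <- ncol(values)
  if (G < 4L) stop("need at least 4 genes, got ", G)
  if (M < 4L) stop("need at least 4 arrays, got ", M)
  groups <- as.integer(as.character(groups))
  if (length(groups) != M) stop("design length (", length(groups),
                                ") does not match number of arrays (", M, ")")
  if (anyNA(groups) || !all(groups %in% c(1L, 2L)))
    stop("unknown group label: groups must be 1 or 2")
  if (!all(c(1L, 2L) %in% groups)) stop("both treatment groups must be non-empty")
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(G))
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene_ids are not unique")
  rownames(values) <- gene_ids
  if (is.null(colnames(values))) colnames(values) <- paste0("array_", seq_len(M))
  structure(list(values = values, gene_ids = gene_ids, groups = groups,
                 log_transformed = isTRUE(log_transformed)),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("expression panel: ", nrow(x$values), " genes x ", ncol(x$values),
      " arrays (groups ", sum(x$groups == 1L), "/", sum(x$groups == 2L),
      if (x$log_transformed) ", log scale" else "", ")\n", sep = "")
  invisible(x)
}

#' Read an expression matrix with a two-group design
#'
#' Reads a delimited text table (genes in rows, first column = gene id,
#' header row = array names) into an [expression_panel()].
#'
#' @param path Path to a TSV/CSV file.
#' @param design Either a vector of group labels (1/2), one per array column,
#'   or the path to a two-column delimited file mapping array id to group.
#' @param log_transform If `TRUE`, natural logs are taken; all values must
#'   then be strictly positive.
#' @param sep Field separator (default tab).
#' @return An [expression_panel()].
#' @export
load_expression <- function(path, design, log_transform = FALSE, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs a gene-id column and arrays")
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))
    stop("non-numeric cell(s) in array column(s): ",
         paste(colnames(tab)[-1L][bad], collapse = ", "))
  }
  if (length(design) == 1L && is.character(design) && file.exists(design)) {
    dtab <- utils::read.table(design, header = FALSE, sep = sep,
                              stringsAsFactors = FALSE)
    m <- match(colnames(mat), as.character(dtab[[1L]]))
    if (anyNA(m)) stop("design file is missing arrays: ",
                       paste(colnames(mat)[is.na(m)], collapse = ", "))
    design <- dtab[[2L]][m]
  }
  if (log_transform) {
    if (any(mat <= 0)) stop("nonpositive under log: ", sum(mat <= 0),
                            " value(s) are <= 0")
    mat <- log(mat)
  }
  expression_panel(mat, design, gene_ids = ids, log_transformed = log_transform)
}

#' Write an expression matrix
#'
#' Writes the panel in the same dialect [load_expression()] reads:
#' tab-separated, gene id in the first column, array names as header.
#'
#' @param panel An [expression_panel()] or `residual_panel`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(panel, path, sep = "\t") {
  mat <- panel$values
  # %.17g keeps doubles exact across a write/read round trip
  txt <- matrix(sprintf("%.17g", mat), nrow(mat))
  colnames(txt) <- colnames(mat)
  df <- data.frame(gene = rownames(mat), txt, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove per-gene within-group means
#'
#' Subtracts from each gene's row its average within each treatment group,
#' leaving the residual expression matrix on which all correlation estimation
#' is based.  Each group must contribute at least two arrays.
#'
#' @param panel An [expression_panel()].
#' @return An object of class `residual_panel` with elements `values`,
#'   `groups`, `effective_df` (= M - number of groups) and `standardized`.
#' @export
residualize <- function(panel) {
  if (inherits(panel, "residual_panel")) return(panel)
  stopifnot(inherits(panel, "expression_panel"))
  X <- panel$values
  groups <- panel$groups
  for (k in unique(groups)) {
    cols <- which(groups == k)
    if (length(cols) < 2L)
      stop("group ", k, " has a single array; residuals are degenerate")
    X[, cols] <- X[, cols, drop = FALSE] -
      rowMeans(X[, cols, drop = FALSE])
  }
  structure(list(values = X, groups = groups,
                 effective_df = ncol(X) - length(unique(groups)),
                 standardized = FALSE),
            class = "residual_panel")
}

#' Standardize the columns of a residual matrix
#'
#' Rescales every array (column) to sample mean zero and unit sample
#' variance (denominator G - 1).  Column standardization normalizes
#' brightness across arrays and forces the sum of all pairwise row
#' covariances toward zero, which is what justifies fitting a zero-symmetric
#' density to the pairwise correlations downstream.
#'
#' @param panel A `residual_panel` (or an [expression_panel()], which is
#'   residualized first).
#' @return A `residual_panel` with `standardized = TRUE`.
#' @export
standardize_columns <- function(panel) {
  res <- residualize(panel)
  X <- res$values
  mu <- colMeans(X)
  X <- sweep(X, 2L, mu)
  v <- colSums(X^2) / (nrow(X) - 1L)
  if (any(v <= 1e-24)) {
    bad <- colnames(X)[v <= 1e-24]
    stop("constant column(s), cannot standardize: ",
         paste(bad, collapse = ", "))
  }
  res$values <- sweep(X, 2L, sqrt(v), "/")
  res$standardized <- TRUE
  res
}
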