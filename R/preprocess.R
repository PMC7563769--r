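#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) onto the same empirical distribution — the
#' per-rank mean of the input columns. This is the cross-array normalization
#' step appropriate for synthetic or linear-scale input; matrices that arrive
#' already normalized (e.g. RMA output) should skip it.
#'
#' @param x Numeric genes x samples matrix.
#' @return Matrix of the same shape and dimnames, quantile-normalized.
#' @export
quantile_normalize <- function(x) {
  check_expression_matrix(x)
  if (ncol(x) < 2L) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Filter genes with low expression
#'
#' A gene is kept when its signal reaches `signal_threshold` (value >=
#' threshold, non-strict) in more than `min_arrays` arrays; with
#' `strict = FALSE` the count requirement becomes `>=` instead of `>`.
#' Defaults (threshold 5 on the log2 scale, more than 3 arrays) follow the
#' usual "present in more than k arrays" presence rule for small designs.
#'
#' @param x Numeric genes x samples matrix.
#' @param signal_threshold Signal level a value must reach to count as present.
#' @param min_arrays Number of arrays the presence count is compared against.
#' @param strict Logical; compare the presence count with `>` (default) or `>=`.
#' @return A list with `expr` (the surviving rows, order preserved) and
#'   `kept` (named logical mask over the input genes).
#' @export
filter_low_expression <- function(x, signal_threshold = 5, min_arrays = 3, strict = TRUE) {
  check_expression_matrix(x)
  stopifnot(is.finite(signal_threshold) || signal_threshold == -Inf,
            min_arrays >= 0, min_arrays <= ncol(x))
  if (strict && min_arrays >= ncol(x)) {
    warning("min_arrays >= number of samples with strict counting: no gene can pass")
  }
  present <- rowSums(x >= signal_threshold)
  kept <- if (strict) present > min_arrays else present >= min_arrays
  names(kept) <- rownames(x)
  list(expr = x[kept, , drop = FALSE], kept = kept)
}

#' Histogram summary of per-gene mean expression
#'
#' Support for choosing filtering constants: bins the per-gene mean expression
#' values so the low-signal mode is visible.
#'
#' @param x Numeric genes x samples matrix.
#' @param breaks Passed to [graphics::hist()] breaks selection (default 50).
#' @return A data.frame with columns `mid`, `count`.
#' @export
mean_expression_histogram <- function(x, breaks = 50) {
  check_expression_matrix(x)
  h <- graphics::hist(rowMeans(x), breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
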