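#' Center and standardize genes across samples
#'
#' Transforms every gene row to mean 0 and standard deviation 1 across
#' samples. Genes with zero variance carry no information for a
#' decomposition and are dropped with a warning; their ids are recorded in
#' the `dropped` attribute of the result.
#'
#' @param x Numeric genes x samples matrix.
#' @return The standardized matrix (possibly with fewer rows), with attribute
#'   `dropped` listing excluded zero-variance gene ids.
#' @export
scale_center <- function(x) {
  check_expression_matrix(x)
  if (ncol(x) < 2L) stop("standardization needs at least 2 samples")
  sds <- apply(x, 1L, stats::sd)
  zero <- sds == 0
  if (all(zero)) stop("all genes have zero variance; nothing to standardize")
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) excluded from standardization")
  }
  xs <- x[!zero, , drop = FALSE]
  out <- (xs - rowMeans(xs)) / sds[!zero]
  attr(out, "dropped") <- rownames(x)[zero]
  out
}

#' Principal component analysis of samples by SVD
#'
#' Genes are variables and samples observations: each gene row is centered
#' across samples (and optionally standardized with `scale = TRUE`), the
#' samples x genes matrix is decomposed by SVD, and each component is
#' reported as unit-norm per-gene loadings with per-sample scores. Zero
#' variance genes are excluded before the decomposition, so `N` is the
#' number of genes actually decomposed — the denominator of the signature
#' threshold in [select_signature()].
#'
#' The default keeps gene amplitudes (`scale = FALSE`, centering only).
#' Standardizing every gene to unit variance bounds each unit-norm loading by
#' `1/sqrt(f_k * N)` (`f_k` the component's variance fraction), which makes
#' the loading threshold `W/sqrt(N)` unsatisfiable on any component with
#' `f_k > 1/W^2`; see the package vignette.
#'
#' Each component is oriented so that its largest-magnitude loading is
#' positive (the SVD sign is arbitrary; this makes results reproducible).
#'
#' @param x Numeric genes x samples matrix (>= 3 samples).
#' @param k Number of components to keep; default `min(n_samples - 1, 10)`.
#' @param scale Standardize genes to unit variance before decomposition
#'   (default `FALSE`: center only).
#' @return An object of class `pca_result`: list with `loadings` (genes x k,
#'   unit-norm columns), `scores` (samples x k), `var_fraction` (length k),
#'   `sdev`, `N` (genes decomposed), `k`, `scaled`, `dropped`.
#' @export
run_pca_svd <- function(x, k = NULL, scale = FALSE) {
  check_expression_matrix(x)
  if (ncol(x) < 3L) stop("PCA needs at least 3 samples for a meaningful second component")
  sds <- apply(x, 1L, stats::sd)
  zero <- sds == 0
  if (all(zero)) stop("all genes have zero variance")
  if (any(zero)) warning(sum(zero), " zero-variance gene(s) excluded from PCA")
  xc <- x[!zero, , drop = FALSE]
  xc <- xc - rowMeans(xc)
  if (scale) xc <- xc / sds[!zero]
  n_comp_max <- min(nrow(xc), ncol(xc) - 1L)
  if (is.null(k)) k <- min(ncol(xc) - 1L, 10L)
  k <- min(k, n_comp_max)
  sv <- svd(t(xc), nu = k, nv = k)
  # sign convention: largest-magnitude loading positive in every component
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE], 2L, sv$d[seq_len(k)] * flip, `*`)
  rownames(loadings) <- rownames(xc)
  rownames(scores) <- colnames(xc)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    loadings = loadings,
    scores = scores,
    var_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2),
    sdev = sv$d[seq_len(k)] / sqrt(ncol(xc) - 1L),
    N = nrow(xc),
    k = k,
    scaled = scale,
    dropped = rownames(x)[zero]
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA by SVD:", x$N, "genes,", nrow(x$scores), "samples,", x$k, "components\n")
  vf <- round(100 * x$var_fraction, 1)
  cat("Variance explained (%):", paste0(colnames(x$loadings), "=", vf, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pca_result <- function(x, pcs = c(1L, 2L), ...) {
  vf <- round(100 * x$var_fraction[pcs], 1)
  graphics::plot(x$scores[, pcs[1L]], x$scores[, pcs[2L]],
                 xlab = sprintf("PC%d (%s%%)", pcs[1L], vf[1L]),
                 ylab = sprintf("PC%d (%s%%)", pcs[2L], vf[2L]), ...)
  graphics::text(x$scores[, pcs[1L]], x$scores[, pcs[2L]],
                 labels = rownames(x$scores), pos = 3, cex = 0.7)
  invisible(x)
}

#' Select a gene signature from a principal component by loading threshold
#'
#' Declares genes significant contributors to component `pc` when the
#' absolute loading strictly exceeds `W / sqrt(N)`, `N` being the number of
#' genes in the decomposition. The recommended weight is W > 3; the default
#' is 3.5. An empty signature is legal and simply reported as such.
#'
#' @param pca A `pca_result`.
#' @param pc 1-based component index.
#' @param W Positive weight parameter of the threshold `W/sqrt(N)`.
#' @return An object of class `gene_signature`: a data.frame with columns
#'   `gene_id`, `loading`, `abs_loading`, sorted by `abs_loading` decreasing,
#'   with attributes `pc`, `W`, `threshold`, `N`.
#' @export
select_signature <- function(pca, pc = 2L, W = 3.5) {
  stopifnot(inherits(pca, "pca_result"), W > 0)
  if (pc < 1L || pc > pca$k) stop("pc must be between 1 and ", pca$k)
  threshold <- W / sqrt(pca$N)
  v <- pca$loadings[, pc]
  sel <- abs(v) > threshold
  df <- data.frame(gene_id = rownames(pca$loadings)[sel],
                   loading = unname(v[sel]),
                   abs_loading = unname(abs(v[sel])),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$abs_loading), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, pc = as.integer(pc), W = W, threshold = threshold, N = pca$N,
            class = c("gene_signature", "data.frame"))
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature from PC%d: %d gene(s); |loading| > %.4g (W = %g, N = %d)\n",
              attr(x, "pc"), nrow(x), attr(x, "threshold"), attr(x, "W"), attr(x, "N")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Associate principal components with experimental factors
#'
#' For each component, computes eta-squared — the between-group sum of
#' squares of the sample scores over the total sum of squares — for a
#' grouping derived from the annotation: `"cell_line"`, the full
#' three-level `"condition"`, or `"overexpression"` (overexpressing vs both
#' control types pooled).
#'
#' @param pca A `pca_result`.
#' @param ann Sample annotation matching the score rows.
#' @param factor One of `"cell_line"`, `"condition"`, `"overexpression"`.
#' @return A data.frame with columns `pc`, `eta_squared`; the attribute
#'   `best_pc` names the component with maximal eta-squared.
#' @export
pc_factor_association <- function(pca, ann, factor = c("cell_line", "condition", "overexpression")) {
  factor <- match.arg(factor)
  stopifnot(inherits(pca, "pca_result"))
  g <- factor_groups(ann, factor, rownames(pca$scores))
  if (nlevels(g) < 2L) stop("factor '", factor, "' defines fewer than 2 nonempty groups")
  eta <- apply(pca$scores, 2L, eta_squared, g = g)
  out <- data.frame(pc = seq_len(pca$k), eta_squared = unname(eta))
  attr(out, "best_pc") <- out$pc[which.max(out$eta_squared)]
  out
}

eta_squared <- function(scores, g) {
  gm <- stats::ave(scores, g)
  tot <- sum((scores - mean(scores))^2)
  if (tot == 0) return(0)
  sum((gm - mean(scores))^2) / tot
}

# Map an annotation factor name to a grouping over the given sample ids.
factor_groups <- function(ann, factor, sample_ids) {
  idx <- match(sample_ids, ann$sample_id)
  if (anyNA(idx)) stop("annotation is missing sample(s): ",
                       paste(sample_ids[is.na(idx)], collapse = ", "))
  a <- ann[idx, , drop = FALSE]
  g <- switch(factor,
    cell_line = a$cell_line,
    condition = as.character(a$condition),
    overexpression = ifelse(a$condition == "OVEREXPR", "OVEREXPR", "CONTROL"))
  droplevels(as.factor(g))
}
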