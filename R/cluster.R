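#' Hierarchical clustering of samples on a gene signature
#'
#' Clusters samples by agglomerative hierarchical clustering of the
#' expression matrix restricted to signature genes. The default distance is
#' Euclidean with average linkage: gene-wise differences cancel each gene's
#' baseline, so a shared expression shift between groups separates them.
#' Pearson dissimilarity (1 - r between sample profiles across genes) is
#' available, but note that it discards each sample's mean over the
#' signature genes, so it cannot see a shift that is uniform across the
#' signature; complete and Ward linkage are also available.
#'
#' @param x Numeric genes x samples matrix.
#' @param genes Optional gene ids (character vector or `gene_signature`) to
#'   restrict to; default all rows.
#' @param distance `"euclidean"` (default) or `"pearson"` (1 - correlation).
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2).
#' @return An object of class `sample_clustering`: list with `hclust` (the
#'   [stats::hclust] tree over samples), `sample_ids`, `leaf_order`
#'   (sample ids in dendrogram order), `distance`, `linkage`, `n_genes`.
#' @export
hierarchical_cluster <- function(x, genes = NULL,
                                 distance = c("euclidean", "pearson"),
                                 linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  check_expression_matrix(x)
  if (!is.null(genes)) {
    ids <- if (inherits(genes, "gene_signature")) genes$gene_id else as.character(genes)
    miss <- setdiff(ids, rownames(x))
    if (length(miss)) stop("signature gene(s) absent from matrix: ", paste(miss, collapse = ", "))
    x <- x[ids, , drop = FALSE]
  }
  if (nrow(x) < 1L) stop("no genes to cluster on")
  if (ncol(x) < 2L) stop("need at least 2 samples")
  d <- switch(distance,
    euclidean = stats::dist(t(x)),
    pearson = {
      if (nrow(x) < 2L) stop("pearson dissimilarity needs at least 2 genes")
      stats::as.dist(1 - stats::cor(x))
    })
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  structure(list(hclust = hc,
                 sample_ids = colnames(x),
                 leaf_order = colnames(x)[hc$order],
                 distance = distance,
                 linkage = linkage,
                 n_genes = nrow(x)),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$sample_ids), "samples on",
      x$n_genes, "genes (", x$distance, "/", x$linkage, ")\n")
  cat("Leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Cut a sample clustering into k groups
#'
#' @param clustering A `sample_clustering`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels (1..k) per sample.
#' @export
cut_clusters <- function(clustering, k) {
  stopifnot(inherits(clustering, "sample_clustering"))
  if (k > length(clustering$sample_ids)) stop("k exceeds the number of samples")
  stats::cutree(clustering$hclust, k = k)
}

#' Concordance between a clustering cut and an annotation factor
#'
#' Replaces the visual heat-map judgment of whether a gene set separates
#' samples by a factor: the tree is cut into `k` clusters (`k` = number of
#' factor levels) and the concordance is the maximum, over all cluster-to-
#' level bijections, of the fraction of samples whose cluster maps onto
#' their true level. 1 means a cut reproduces the factor exactly.
#'
#' @param clustering A `sample_clustering`.
#' @param ann Sample annotation covering the clustered samples.
#' @param factor One of `"cell_line"`, `"condition"`, `"overexpression"`.
#' @param k Number of clusters; defaults to the number of factor levels.
#' @return Concordance in `[0, 1]`.
#' @export
cluster_concordance <- function(clustering, ann, factor = "overexpression", k = NULL) {
  stopifnot(inherits(clustering, "sample_clustering"))
  g <- factor_groups(ann, factor, clustering$sample_ids)
  if (is.null(k)) k <- nlevels(g)
  if (k > length(clustering$sample_ids)) stop("k exceeds the number of samples")
  cl <- cut_clusters(clustering, k)
  concordance_score(cl, g)
}

# Max over bijections cluster -> level of the matched fraction.
concordance_score <- function(clusters, labels) {
  cl <- as.integer(as.factor(clusters))
  lb <- as.integer(as.factor(labels))
  k <- max(cl, lb)
  tab <- matrix(0L, k, k)
  for (i in seq_along(cl)) tab[cl[i], lb[i]] <- tab[cl[i], lb[i]] + 1L
  best <- 0L
  for (perm in all_permutations(k)) {
    hit <- sum(tab[cbind(seq_len(k), perm)])
    if (hit > best) best <- hit
  }
  best / length(cl)
}

# All permutations of 1..k as a list (k is small: factor levels).
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in all_permutations(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
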