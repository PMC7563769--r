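#' Pipeline configuration
#'
#' Aggregates the tunable parameters of [run_pipeline()] with the defaults
#' used throughout the package: presence filter at signal 5 in more than 3
#' arrays, signature weight W = 3.5 on components 1-2, adjusted-p cutoff
#' 1e-4 for differential expression, raw-p 0.05 for over-representation,
#' Euclidean/average clustering, and a component declared
#' overexpression-related when its overexpression concordance reaches 0.9
#' and (for the pan analysis) exceeds its cell-line concordance.
#'
#' @param signal_threshold,min_arrays,strict Presence-filter parameters, see
#'   [filter_low_expression()].
#' @param quantile Quantile-normalize before filtering (default `FALSE`;
#'   input is assumed already normalized).
#' @param W Signature weight, see [select_signature()].
#' @param pcs Components examined for attribution (default `1:2`).
#' @param scale Standardize genes before PCA (default `FALSE`, see
#'   [run_pca_svd()]).
#' @param alpha_adj Adjusted-p threshold of the significance call.
#' @param ora_alpha Raw-p threshold of the pathway screen.
#' @param distance,linkage Clustering parameters, see [hierarchical_cluster()].
#' @param concordance_min Minimum overexpression concordance for a component
#'   to be declared overexpression-related.
#' @param vector_only Also run the empty-vector-only comparison (default `TRUE`).
#' @return A classed list of parameters.
#' @export
pipeline_config <- function(signal_threshold = 5, min_arrays = 3, strict = TRUE,
                            quantile = FALSE, W = 3.5, pcs = 1:2, scale = FALSE,
                            alpha_adj = 1e-4, ora_alpha = 0.05,
                            distance = "euclidean", linkage = "average",
                            concordance_min = 0.9, vector_only = TRUE) {
  structure(list(signal_threshold = signal_threshold, min_arrays = min_arrays,
                 strict = strict, quantile = quantile, W = W, pcs = pcs,
                 scale = scale, alpha_adj = alpha_adj, ora_alpha = ora_alpha,
                 distance = distance, linkage = linkage,
                 concordance_min = concordance_min, vector_only = vector_only),
            class = "pipeline_config")
}

#' Run the variance-attribution workflow end to end
#'
#' Orchestrates the full decision workflow for a two-cell-line,
#' three-condition overexpression experiment:
#' \enumerate{
#'   \item presence filtering (optionally preceded by quantile normalization);
#'   \item pan-PCA over all samples with eta-squared and clustering-concordance
#'     attribution of each component to the cell-line and overexpression factors;
#'   \item PCA within each cell line;
#'   \item hierarchical clustering of each line's samples on each examined
#'     component's signature, marking a component overexpression-related when
#'     its overexpression concordance reaches `concordance_min` (and, in the
#'     pan analysis, exceeds the cell-line concordance);
#'   \item over-representation analysis of each line's overexpression-related
#'     signature against the gene-set collection, universe = the genes that
#'     entered that line's decomposition;
#'   \item moderated-t differential expression per line against each control
#'     type, with the cross-line intersection of significant genes;
#'   \item optionally, a re-run of the per-line signature step using only
#'     empty-vector controls, with the Jaccard overlap against step 4.
#' }
#' Finding no overexpression-related component is a reported outcome, not an
#' error.
#'
#' @param expr Numeric genes x samples matrix (log2 scale).
#' @param ann Sample annotation (see [read_sample_annotation()]).
#' @param gene_sets A `gene_set_collection`.
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`; see Details for the stage
#'   fields. Key elements: `n_genes_input`, `n_genes_filtered`, `pan`
#'   (pca, eta-squared tables, concordance table), `per_line` (per cell line:
#'   pca, signatures, concordance table, `oe_pc`, `oe_signature`, ora),
#'   `de` (fits per line and control type, intersections), `vector_only`
#'   (signature overlap per line), `config`.
#' @export
run_pipeline <- function(expr, ann, gene_sets, config = pipeline_config()) {
  check_expression_matrix(expr)
  check_annotation(expr, ann)
  stopifnot(inherits(config, "pipeline_config"))
  lines <- sort(unique(ann$cell_line))
  if (length(lines) != 2L) stop("the workflow expects exactly 2 cell lines")

  if (config$quantile) expr <- quantile_normalize(expr)
  filt <- filter_low_expression(expr, config$signal_threshold,
                                config$min_arrays, config$strict)
  fx <- filt$expr

  # --- stage 2: pan analysis ---------------------------------------------
  pan_pca <- run_pca_svd(fx, scale = config$scale)
  pan_eta <- list(
    cell_line = pc_factor_association(pan_pca, ann, "cell_line"),
    overexpression = pc_factor_association(pan_pca, ann, "overexpression"))
  pan_pcs <- attribute_components(fx, pan_pca, ann, config, pan = TRUE)

  # --- stages 3-5: per-line analysis -------------------------------------
  per_line <- lapply(lines, function(ln) {
    samples <- ann$sample_id[ann$cell_line == ln]
    lx <- fx[, samples, drop = FALSE]
    pca <- run_pca_svd(lx, scale = config$scale)
    att <- attribute_components(lx, pca, ann, config, pan = FALSE)
    oe_pc <- att$oe_pc
    oe_signature <- if (!is.na(oe_pc)) att$signatures[[as.character(oe_pc)]] else NULL
    ora <- if (!is.null(oe_signature) && nrow(oe_signature) > 0) {
      run_ora(oe_signature, gene_sets, universe = rownames(pca$loadings),
              alpha = config$ora_alpha)
    } else NULL
    list(cell_line = ln, samples = samples, pca = pca,
         signatures = att$signatures, concordance = att$concordance,
         oe_pc = oe_pc, oe_signature = oe_signature, ora = ora)
  })
  names(per_line) <- lines

  # --- stage 6: differential expression ----------------------------------
  de <- de_stage(fx, ann, lines, config)

  # --- stage 7: empty-vector-only re-run ---------------------------------
  vector_only <- NULL
  if (config$vector_only) {
    vector_only <- lapply(lines, function(ln) {
      keep <- ann$cell_line == ln & ann$condition %in% c("VECTOR", "OVEREXPR")
      lx <- fx[, ann$sample_id[keep], drop = FALSE]
      pca <- run_pca_svd(lx, scale = config$scale)
      att <- attribute_components(lx, pca, ann, config, pan = FALSE)
      sig <- if (!is.na(att$oe_pc)) att$signatures[[as.character(att$oe_pc)]] else NULL
      main_sig <- per_line[[ln]]$oe_signature
      jac <- if (!is.null(sig) && !is.null(main_sig)) {
        jaccard(sig$gene_id, main_sig$gene_id)
      } else NA_real_
      list(cell_line = ln, oe_pc = att$oe_pc, signature = sig,
           jaccard_vs_full = jac)
    })
    names(vector_only) <- lines
  }

  structure(list(
    n_genes_input = nrow(expr),
    n_genes_filtered = nrow(fx),
    kept = filt$kept,
    pan = list(pca = pan_pca, eta_squared = pan_eta,
               concordance = pan_pcs$concordance, signatures = pan_pcs$signatures,
               oe_pc = pan_pcs$oe_pc),
    per_line = per_line,
    de = de,
    vector_only = vector_only,
    config = config,
    version = as.character(utils::packageVersion("pcsig"))
  ), class = "pipeline_report")
}

# Signatures, clustering concordances and the overexpression-attribution rule
# for the examined components of one PCA. In the pan analysis a component
# must also beat its own cell-line concordance to be called
# overexpression-related; within one line the cell-line factor is constant
# and only the concordance floor applies.
attribute_components <- function(x, pca, ann, config, pan) {
  pcs <- config$pcs[config$pcs <= pca$k]
  signatures <- list()
  rows <- list()
  for (pc in pcs) {
    sig <- select_signature(pca, pc, config$W)
    signatures[[as.character(pc)]] <- sig
    if (nrow(sig) < 2L) {
      rows[[length(rows) + 1L]] <- data.frame(pc = pc, n_genes = nrow(sig),
                                              conc_overexpr = NA_real_,
                                              conc_cell_line = NA_real_)
      next
    }
    cl <- hierarchical_cluster(x, sig, config$distance, config$linkage)
    co <- cluster_concordance(cl, ann, "overexpression", k = 2)
    cc <- if (pan) cluster_concordance(cl, ann, "cell_line") else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(pc = pc, n_genes = nrow(sig),
                                            conc_overexpr = co, conc_cell_line = cc)
  }
  conc <- do.call(rbind, rows)
  ok <- !is.na(conc$conc_overexpr) & conc$conc_overexpr >= config$concordance_min
  if (pan) ok <- ok & conc$conc_overexpr > conc$conc_cell_line
  oe_pc <- if (any(ok)) {
    cand <- conc[ok, , drop = FALSE]
    cand$pc[which.max(cand$conc_overexpr)]
  } else NA_integer_
  list(signatures = signatures, concordance = conc, oe_pc = oe_pc)
}

# Moderated-t fits per line and control type, with cross-line intersections.
de_stage <- function(fx, ann, lines, config) {
  fits <- list()
  for (ln in lines) {
    for (ctrl in c("VECTOR", "WT")) {
      oe <- ann$sample_id[ann$cell_line == ln & ann$condition == "OVEREXPR"]
      ct <- ann$sample_id[ann$cell_line == ln & ann$condition == ctrl]
      fits[[paste(ln, ctrl, sep = ".")]] <-
        moderated_t_fit(fx, oe, ct, alpha_adj = config$alpha_adj)
    }
  }
  intersections <- list(
    VECTOR = call_and_intersect(fits[[paste(lines[1], "VECTOR", sep = ".")]],
                                fits[[paste(lines[2], "VECTOR", sep = ".")]],
                                config$alpha_adj),
    WT = call_and_intersect(fits[[paste(lines[1], "WT", sep = ".")]],
                            fits[[paste(lines[2], "WT", sep = ".")]],
                            config$alpha_adj))
  list(fits = fits, intersections = intersections)
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Variance-attribution workflow report\n")
  cat(sprintf("  Filter: %d of %d genes kept\n", x$n_genes_filtered, x$n_genes_input))
  vf <- round(100 * x$pan$pca$var_fraction[1:2], 1)
  cat(sprintf("  Pan-PCA: PC1 = %s%%, PC2 = %s%% of variance\n", vf[1], vf[2]))
  e1 <- x$pan$eta_squared$cell_line
  cat(sprintf("  Cell-line factor: max eta^2 = %.3f on PC%d\n",
              max(e1$eta_squared), attr(e1, "best_pc")))
  for (ln in names(x$per_line)) {
    pl <- x$per_line[[ln]]
    if (is.na(pl$oe_pc)) {
      cat(sprintf("  %s: no overexpression-related component\n", ln))
    } else {
      cat(sprintf("  %s: overexpression-related PC%d, %d signature genes, %d significant pathway(s)\n",
                  ln, pl$oe_pc, nrow(pl$oe_signature),
                  if (is.null(pl$ora)) 0L else sum(pl$ora$significant)))
    }
  }
  iv <- x$de$intersections$VECTOR
  cat(sprintf("  DE (vs empty vector), adj_p < %g: %d and %d per line, %d in both\n",
              iv$alpha_adj, length(iv$set_a), length(iv$set_b), length(iv$intersection)))
  invisible(x)
}
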