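#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(Nu, m, n)`: the probability of
#' drawing at least `k` members of an `m`-gene pathway when `n` genes are
#' drawn without replacement from a universe of `Nu`. Computed via
#' [stats::phyper()] (log-space internally); `k = 0` gives exactly 1.
#'
#' @param Nu Universe size.
#' @param m Pathway size within the universe.
#' @param n Signature (draw) size within the universe.
#' @param k Observed overlap.
#' @return The upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(Nu, m, n, k) {
  stopifnot(Nu >= 0, m >= 0, n >= 0, m <= Nu, n <= Nu)
  if (k > min(m, n) || k < max(0, m + n - Nu)) {
    stop(sprintf("infeasible overlap k = %d for (Nu = %d, m = %d, n = %d)", k, Nu, m, n))
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, m, Nu - m, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene signature
#'
#' Tests every gene set in a collection for over-representation in a
#' signature by the one-sided hypergeometric test against a stated universe
#' (conventionally the filtered gene list the signature was drawn from).
#' Signature members outside the universe are dropped with a message. The
#' BH-adjusted column is informative only — the significance flag uses the
#' raw p against `alpha`, as is usual for exploratory pathway screens.
#'
#' @param signature Character vector of gene ids, or a `gene_signature`.
#' @param collection A `gene_set_collection` (or named list of id vectors).
#' @param universe Character vector of gene ids forming the background.
#' @param alpha Raw-p significance threshold (default 0.05).
#' @return An object of class `ora_result` (a data.frame): one row per gene
#'   set with nonzero intersection with the universe, columns `rank`,
#'   `pathway`, `n_pathway` (full parsed set size), `n_pathway_universe`
#'   (size within the universe, the `m` of the test), `n_overlap`,
#'   `n_signature`, `n_universe`, `p_value`, `adj_p`, `significant`;
#'   sorted by `p_value` ascending, ties by pathway name.
#' @export
run_ora <- function(signature, collection, universe, alpha = 0.05) {
  if (inherits(signature, "gene_signature")) signature <- signature$gene_id
  signature <- unique(as.character(signature))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe is empty")
  stopifnot(alpha > 0, alpha < 1)
  dropped <- setdiff(signature, universe)
  if (length(dropped)) {
    message(length(dropped), " signature gene(s) outside the universe dropped")
    signature <- intersect(signature, universe)
  }
  n <- length(signature)
  Nu <- length(universe)
  rows <- lapply(names(collection), function(nm) {
    full <- unique(collection[[nm]])
    in_univ <- intersect(full, universe)
    m <- length(in_univ)
    if (m == 0L) return(NULL)
    k <- length(intersect(in_univ, signature))
    data.frame(pathway = nm, n_pathway = length(full), n_pathway_universe = m,
               n_overlap = k, n_signature = n, n_universe = Nu,
               p_value = hypergeom_upper_tail(Nu, m, n, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set intersects the universe")
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  out$adj_p <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("rank", "pathway", "n_pathway", "n_pathway_universe", "n_overlap",
                 "n_signature", "n_universe", "p_value", "adj_p", "significant")]
  structure(out, alpha = alpha, class = c("ora_result", "data.frame"))
}

#' @export
print.ora_result <- function(x, n = 10L, ...) {
  cat(sprintf("Over-representation analysis: %d gene sets tested, %d significant at p < %g\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  print.data.frame(utils::head(as.data.frame(x)[, c("rank", "pathway", "n_pathway",
                                                    "n_overlap", "p_value", "adj_p")], n),
                   row.names = FALSE)
  invisible(x)
}
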