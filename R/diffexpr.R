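#' Gene-wise two-group summary statistics
#'
#' For each gene: the mean difference (group A minus group B), the pooled
#' within-group variance and its residual degrees of freedom
#' `d_g = nA + nB - 2`.
#'
#' @param x Numeric genes x samples matrix.
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @return A list with `gene_id`, `mean_diff`, `s2_g` (vectors over genes),
#'   `d_g`, `n_a`, `n_b`.
#' @export
genewise_stats <- function(x, group_a, group_b) {
  check_expression_matrix(x)
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  miss <- setdiff(c(group_a, group_b), colnames(x))
  if (length(miss)) stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 samples")
  a <- x[, group_a, drop = FALSE]
  b <- x[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  ssa <- rowSums((a - ma)^2)
  ssb <- rowSums((b - mb)^2)
  d_g <- na + nb - 2L
  list(gene_id = rownames(x),
       mean_diff = unname(ma - mb),
       s2_g = unname((ssa + ssb) / d_g),
       d_g = d_g, n_a = na, n_b = nb)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior of the moderated t-test by
#' moment matching on log variances: with `z_g = log(s2_g)` and
#' `e_g = z_g - digamma(d_g/2) + log(d_g/2)`, the excess of `var(e)` over
#' `trigamma(d_g/2)` equals `trigamma(d0/2)`, solved for `d0` by monotone
#' bisection on (1e-4, 1e4); `s2_0` then follows from the mean of `e`.
#' When the empirical spread of the log variances does not exceed what the
#' residual degrees of freedom alone imply, `d0 = Inf` (complete shrinkage)
#' and `s2_0` is the (geometric-mean-based) common variance.
#'
#' Zero variances are excluded from estimation (they carry no log-scale
#' information); fewer than 50 positive variances triggers a stability
#' warning.
#'
#' @param s2 Vector of gene-wise residual variances.
#' @param d_g Residual degrees of freedom shared by all genes.
#' @return List with `d0` (> 0, possibly `Inf`) and `s2_0` (> 0).
#' @export
estimate_eb_prior <- function(s2, d_g) {
  stopifnot(d_g >= 1, all(s2 >= 0))
  pos <- s2[s2 > 0]
  if (length(pos) < 2L) stop("need at least 2 positive gene variances to estimate a prior")
  if (length(pos) < 50L)
    warning("prior estimated from fewer than 50 genes; estimates may be unstable")
  if (max(pos) == min(pos)) {
    return(list(d0 = Inf, s2_0 = pos[1L]))
  }
  e <- log(pos) - digamma(d_g / 2) + log(d_g / 2)
  excess <- stats::var(e) - trigamma(d_g / 2)
  lo <- 1e-4; hi <- 1e4
  if (!is.finite(excess) || excess <= trigamma(hi / 2)) {
    return(list(d0 = Inf, s2_0 = exp(mean(e))))
  }
  if (excess >= trigamma(lo / 2)) {
    d0 <- lo
  } else {
    # trigamma(d0/2) is strictly decreasing in d0: bisect
    f <- function(d0) trigamma(d0 / 2) - excess
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-10 * hi) break
    }
    d0 <- (lo + hi) / 2
  }
  list(d0 = d0, s2_0 = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
}

#' Moderated t statistics from gene-wise statistics and a variance prior
#'
#' Shrinks each gene's variance toward the prior,
#' `s2_post = (d0 * s2_0 + d_g * s2_g) / (d0 + d_g)`, and tests the mean
#' difference with `t = mean_diff / sqrt(s2_post * (1/nA + 1/nB))` on
#' `d0 + d_g` degrees of freedom (two-sided). With `d0 = 0` this is exactly
#' the classical pooled two-sample t-test; with `d0 = Inf` every gene is
#' tested against the common variance `s2_0`.
#'
#' @param stats Output of [genewise_stats()].
#' @param prior List with `d0` and `s2_0`, e.g. from [estimate_eb_prior()].
#' @return A data.frame with columns `gene_id`, `mean_diff`, `s2_g`,
#'   `s2_post`, `t_mod`, `df_total`, `p`, plus a `zero_variance_flagged`
#'   attribute naming genes whose posterior variance degenerated to 0 with a
#'   nonzero difference (their p is floored at the smallest positive double).
#' @export
moderated_t <- function(stats, prior) {
  stopifnot(is.list(stats), !is.null(stats$s2_g), prior$d0 >= 0)
  if (is.null(prior$s2_0)) {
    if (prior$d0 == 0) prior$s2_0 <- 1 else stop("prior needs s2_0 when d0 > 0")
  }
  stopifnot(prior$s2_0 > 0 || prior$d0 == 0)
  d0 <- prior$d0; s2_0 <- prior$s2_0
  d_g <- stats$d_g
  s2_post <- if (is.infinite(d0)) rep(s2_0, length(stats$s2_g)) else {
    (d0 * s2_0 + d_g * stats$s2_g) / (d0 + d_g)
  }
  se2 <- s2_post * (1 / stats$n_a + 1 / stats$n_b)
  df_total <- d0 + d_g
  t_mod <- ifelse(se2 > 0, stats$mean_diff / sqrt(se2),
                  ifelse(stats$mean_diff == 0, 0, Inf * sign(stats$mean_diff)))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  flagged <- character(0)
  degen <- se2 == 0 & stats$mean_diff != 0
  if (any(degen)) {
    p[degen] <- .Machine$double.xmin
    flagged <- stats$gene_id[degen]
    warning(sum(degen), " gene(s) with zero posterior variance and nonzero difference; p floored")
  }
  out <- data.frame(gene_id = stats$gene_id,
                    mean_diff = stats$mean_diff,
                    s2_g = stats$s2_g,
                    s2_post = s2_post,
                    t_mod = t_mod,
                    df_total = df_total,
                    p = p,
                    stringsAsFactors = FALSE)
  attr(out, "zero_variance_flagged") <- flagged
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit a moderated t-test between two sample groups
#'
#' The one-call fitting interface: computes gene-wise statistics
#' ([genewise_stats()]), estimates the empirical-Bayes variance prior
#' ([estimate_eb_prior()]), forms moderated t statistics ([moderated_t()])
#' and BH-adjusted p-values, and records the significance call at
#' `alpha_adj` (strict `adj_p < alpha_adj`).
#'
#' @param x Numeric genes x samples matrix.
#' @param group_a,group_b Disjoint sample-id sets (>= 2 each); the reported
#'   `mean_diff` is A minus B (conventionally overexpression minus control).
#' @param alpha_adj Adjusted-p significance threshold (default 1e-4).
#' @param prior Optional list `(d0, s2_0)` overriding the estimated prior
#'   (e.g. `d0 = 0` for the classical t-test).
#' @return An object of class `moderated_fit`: list with `table` (per-gene
#'   data.frame with `gene_id`, `mean_diff`, `s2_g`, `s2_post`, `t_mod`,
#'   `df_total`, `p`, `adj_p`, `significant`), `prior`, `d_g`, `n_a`, `n_b`,
#'   `alpha_adj`, `groups`.
#' @export
moderated_t_fit <- function(x, group_a, group_b, alpha_adj = 1e-4, prior = NULL) {
  st <- genewise_stats(x, group_a, group_b)
  if (is.null(prior)) {
    prior <- estimate_eb_prior(st$s2_g[st$s2_g > 0], st$d_g)
  }
  tab <- moderated_t(st, prior)
  tab$adj_p <- bh_adjust(tab$p)
  tab$significant <- tab$adj_p < alpha_adj
  structure(list(table = tab,
                 prior = prior,
                 d_g = st$d_g, n_a = st$n_a, n_b = st$n_b,
                 alpha_adj = alpha_adj,
                 groups = list(a = as.character(group_a), b = as.character(group_b))),
            class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("Moderated t fit: %d genes, %d vs %d samples (d_g = %d)\n",
              nrow(x$table), x$n_a, x$n_b, x$d_g))
  cat(sprintf("EB prior: d0 = %.4g, s2_0 = %.4g; df_total = %.4g\n",
              x$prior$d0, x$prior$s2_0, x$prior$d0 + x$d_g))
  cat(sprintf("Significant at adj_p < %g: %d gene(s)\n",
              x$alpha_adj, sum(x$table$significant)))
  invisible(x)
}

#' @export
summary.moderated_fit <- function(object, n = 10L, ...) {
  print(object)
  tab <- object$table[order(object$table$p), ]
  cat("Top genes:\n")
  print(utils::head(tab[, c("gene_id", "mean_diff", "t_mod", "p", "adj_p")], n),
        row.names = FALSE)
  invisible(tab)
}

#' @export
coef.moderated_fit <- function(object, ...) {
  stats::setNames(object$table$mean_diff, object$table$gene_id)
}

#' Significant genes of a moderated fit
#' @param fit A `moderated_fit`.
#' @param alpha_adj Optional override of the stored threshold.
#' @return Character vector of gene ids with `adj_p < alpha_adj`.
#' @export
significant_genes <- function(fit, alpha_adj = NULL) {
  stopifnot(inherits(fit, "moderated_fit"))
  if (is.null(alpha_adj)) alpha_adj <- fit$alpha_adj
  fit$table$gene_id[fit$table$adj_p < alpha_adj]
}

#' Significance calls for two fits and their intersection
#'
#' Applies the strict `adj_p < alpha_adj` rule to two moderated fits over
#' the same gene universe (typically one per cell line) and intersects the
#' significant sets to find genes responding in both.
#'
#' @param fit_a,fit_b `moderated_fit` objects over identical gene universes.
#' @param alpha_adj Adjusted-p threshold (default 1e-4).
#' @return An object of class `significance_call`: list with `alpha_adj`,
#'   `set_a`, `set_b`, `intersection`.
#' @export
call_and_intersect <- function(fit_a, fit_b, alpha_adj = 1e-4) {
  stopifnot(inherits(fit_a, "moderated_fit"), inherits(fit_b, "moderated_fit"))
  ua <- fit_a$table$gene_id; ub <- fit_b$table$gene_id
  if (!setequal(ua, ub)) {
    stop("gene universes differ; symmetric difference: ",
         paste(c(setdiff(ua, ub), setdiff(ub, ua)), collapse = ", "))
  }
  sa <- significant_genes(fit_a, alpha_adj)
  sb <- significant_genes(fit_b, alpha_adj)
  structure(list(alpha_adj = alpha_adj, set_a = sa, set_b = sb,
                 intersection = intersect(sa, sb)),
            class = "significance_call")
}

#' @export
print.significance_call <- function(x, ...) {
  cat(sprintf("Significance call at adj_p < %g: |A| = %d, |B| = %d, |A n B| = %d\n",
              x$alpha_adj, length(x$set_a), length(x$set_b), length(x$intersection)))
  invisible(x)
}
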