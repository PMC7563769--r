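# Small builders shared across test files.

# Tiny deterministic expression matrix with gene/sample dimnames.
tiny_matrix <- function(values, n_genes, n_samples,
                        gene_ids = sprintf("g%d", seq_len(n_genes)),
                        sample_ids = sprintf("s%d", seq_len(n_samples))) {
  m <- matrix(values, n_genes, n_samples)
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

# Random gene x sample matrix.
random_matrix <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  tiny_matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples)
}

# A small synthetic design for fast structural tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 1000L, n_reps = 3L, n_de_genes = 25L,
         n_pathways = 8L, pathway_size = 12L, seed = 11L),
    list(...))
  do.call(sim_config, args)
}

# Annotation for a single two-group contrast embedded in the package design.
two_group_ids <- function(ann, line, cond_a, cond_b) {
  list(a = ann$sample_id[ann$cell_line == line & ann$condition == cond_a],
       b = ann$sample_id[ann$cell_line == line & ann$condition == cond_b])
}

# Upper-tail hypergeometric oracle: direct summation of the density written
# with binomial coefficients (independent of phyper).
hyper_tail_oracle <- function(Nu, m, n, k) {
  lo <- max(0, m + n - Nu)
  hi <- min(m, n)
  js <- seq(max(k, lo), hi)
  if (!length(js) || k > hi) return(if (k <= lo) 1 else 0)
  sum(choose(m, js) * choose(Nu - m, n - js)) / choose(Nu, n)
}

# Naive BH oracle: min-over-tail of p_(j) * m / j in sorted order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force average-linkage agglomeration over a distance matrix:
# returns the merge heights in order.
average_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
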