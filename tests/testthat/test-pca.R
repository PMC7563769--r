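test_that("scale_center standardizes rows and is idempotent", {
  x <- random_matrix(50, 6, seed = 21, sd = 3) + 7
  s <- scale_center(x)
  expect_equal(unname(rowMeans(s)), rep(0, 50), tolerance = 1e-12)
  expect_equal(unname(apply(s, 1, sd)), rep(1, 50), tolerance = 1e-12)
  s2 <- scale_center(s)
  expect_equal(unname(s2), unname(s), tolerance = 1e-12)
})

test_that("scale_center drops constant genes and refuses all-constant input", {
  x <- random_matrix(10, 4, seed = 22)
  x["g3", ] <- 2
  expect_warning(s <- scale_center(x), "zero-variance")
  expect_identical(nrow(s), 9L)
  expect_identical(attr(s, "dropped"), "g3")
  flat <- tiny_matrix(rep(1, 8), 2, 4)
  expect_error(scale_center(flat), "zero variance")
})

test_that("PCA satisfies its structural invariants", {
  x <- random_matrix(40, 8, seed = 23)
  p <- run_pca_svd(x)
  expect_identical(p$k, 7L)
  expect_identical(p$N, 40L)
  # unit-norm, pairwise-orthogonal loadings
  g <- crossprod(p$loadings)
  expect_equal(unname(g), diag(7), tolerance = 1e-8)
  # variance fractions: non-increasing, summing to 1 at full rank
  expect_true(all(diff(p$var_fraction) <= 1e-12))
  expect_equal(sum(p$var_fraction), 1, tolerance = 1e-8)
  # scores are the data projected on the loadings
  xc <- x - rowMeans(x)
  expect_equal(unname(p$scores), unname(t(xc) %*% p$loadings), tolerance = 1e-8)
  # sign convention: the largest-magnitude loading of each component is positive
  for (j in 1:7) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(run_pca_svd(x[, 1:2]), "3 samples")
})

test_that("rank-1 data concentrates all variance on PC1 and duplicated genes load equally", {
  pattern <- c(-2, -1, 0, 1, 2, 0)
  x <- tiny_matrix(outer(seq(0.5, 5, length.out = 10), pattern), 10, 6)
  p <- run_pca_svd(x)
  expect_equal(p$var_fraction[1], 1, tolerance = 1e-12)

  y <- random_matrix(12, 5, seed = 24)
  y["g2", ] <- y["g1", ]
  py <- run_pca_svd(y)
  expect_equal(abs(py$loadings["g1", ]), abs(py$loadings["g2", ]), tolerance = 1e-8)
})

test_that("loadings, scores and variance fractions match a covariance eigendecomposition", {
  for (seed in c(31, 32, 33)) {
    x <- random_matrix(10, 6, seed = seed)
    p <- run_pca_svd(x, k = 5)
    # oracle: dense eigendecomposition of the gene-gene covariance
    xc <- x - rowMeans(x)
    ev <- eigen(tcrossprod(xc) / (ncol(x) - 1), symmetric = TRUE)
    for (j in 1:5) {
      v <- ev$vectors[, j]
      v <- v * sign(v[which.max(abs(v))])
      expect_equal(unname(p$loadings[, j]), v, tolerance = 1e-8)
      expect_equal(unname(p$scores[, j]), unname(drop(t(xc) %*% v)), tolerance = 1e-8)
    }
    expect_equal(p$var_fraction[1:5],
                 (ev$values / sum(ev$values))[1:5], tolerance = 1e-8)
  }
})

test_that("signature selection applies the strict W/sqrt(N) rule", {
  # hand evaluation: N = 4, loadings (0.9, 0.3, 0.3, 0.1), W = 1 -> threshold
  # 0.5, only the first gene passes
  fake <- structure(list(
    loadings = matrix(c(0.9, 0.3, 0.3, 0.1), 4, 1,
                      dimnames = list(sprintf("g%d", 1:4), "PC1")),
    N = 4L, k = 1L), class = "pca_result")
  sig <- select_signature(fake, pc = 1, W = 1)
  expect_identical(sig$gene_id, "g1")
  expect_equal(attr(sig, "threshold"), 0.5)

  # a vanishing weight admits every gene with a nonzero loading
  sig_all <- select_signature(fake, pc = 1, W = 1e-8)
  expect_identical(nrow(sig_all), 4L)
  expect_true(all(diff(sig_all$abs_loading) <= 0))
  expect_error(select_signature(fake, pc = 2), "between 1 and 1")
})

test_that("signature membership is invariant under a global sign flip", {
  x <- random_matrix(60, 6, seed = 25)
  p <- run_pca_svd(x)
  sig <- select_signature(p, 1, W = 1)
  p_flipped <- p
  p_flipped$loadings[, 1] <- -p_flipped$loadings[, 1]
  sig_f <- select_signature(p_flipped, 1, W = 1)
  expect_setequal(sig$gene_id, sig_f$gene_id)
})

test_that("few genes pass W = 3.5 on the leading component of pure-noise data", {
  fractions <- vapply(41:45, function(seed) {
    x <- random_matrix(2000, 12, seed = seed)
    p <- run_pca_svd(x, k = 2)
    nrow(select_signature(p, 1, W = 3.5)) / p$N
  }, 0)
  expect_true(all(fractions <= 0.05))
})

test_that("eta-squared attribution separates factors and matches the exchangeable null", {
  scores <- matrix(rep(c(-1, 2, 5), each = 4), 12, 1)
  rownames(scores) <- sprintf("s%d", 1:12)
  colnames(scores) <- "PC1"
  fake <- structure(list(scores = scores, k = 1L), class = "pca_result")
  ann <- data.frame(sample_id = sprintf("s%d", 1:12),
                    cell_line = rep(c("A", "B", "C"), each = 4),
                    condition = factor("WT", levels = c("WT", "VECTOR", "OVEREXPR")))
  out <- pc_factor_association(fake, ann, "cell_line")
  expect_equal(out$eta_squared, 1, tolerance = 1e-12)
  expect_identical(attr(out, "best_pc"), 1L)

  # permutation oracle: E[eta^2] = (G-1)/(n-1) under label exchangeability
  set.seed(26)
  sc <- rnorm(12)
  g <- rep(c("A", "B"), each = 6)
  etas <- replicate(10000, pcsig:::eta_squared(sc, sample(g)))
  expect_lt(abs(mean(etas) - 1 / 11), 0.006)
})
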