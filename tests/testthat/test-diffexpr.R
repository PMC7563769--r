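test_that("gene-wise statistics match hand-pooled values and are order-invariant", {
  # A = (1,3), B = (0,2): mean_diff 1, pooled s2 = 2, d = 2
  x <- tiny_matrix(c(1, 3, 0, 2), 1, 4, gene_ids = "g1")
  st <- genewise_stats(x, c("s1", "s2"), c("s3", "s4"))
  expect_equal(st$mean_diff, 1)
  expect_equal(st$s2_g, 2)
  expect_identical(st$d_g, 2L)

  y <- random_matrix(30, 8, seed = 61)
  a <- genewise_stats(y, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  b <- genewise_stats(y, c("s3", "s1", "s2"), c("s6", "s4", "s5"))
  expect_equal(a$mean_diff, b$mean_diff)
  expect_equal(a$s2_g, b$s2_g)

  expect_error(genewise_stats(y, c("s1", "s2"), c("s2", "s3")), "overlap")
  expect_error(genewise_stats(y, "s1", c("s2", "s3")), "at least 2")
})

test_that("identical groups of identical samples give zero difference and variance", {
  x <- tiny_matrix(rep(c(3, 7), 4), 2, 4)
  st <- genewise_stats(x, c("s1", "s2"), c("s3", "s4"))
  expect_equal(st$mean_diff, c(0, 0))
  expect_equal(st$s2_g, c(0, 0))
})

test_that("the variance prior collapses to d0 = Inf when variances are identical", {
  pr <- estimate_eb_prior(rep(0.3, 100), 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s2_0, 0.3)
})

test_that("the variance prior is scale-equivariant in s2_0 with d0 unchanged", {
  set.seed(62)
  s2 <- 0.05 * 4 / rchisq(2000, 4) * rchisq(2000, 4) / 4
  p1 <- estimate_eb_prior(s2, 4)
  p2 <- estimate_eb_prior(2 * s2, 4)
  expect_equal(p2$d0, p1$d0, tolerance = 1e-8)
  expect_equal(p2$s2_0, 2 * p1$s2_0, tolerance = 1e-8)
})

test_that("prior estimation agrees with limma's moment-matching fit", {
  set.seed(63)
  sigma2 <- 0.1 * 5 / rchisq(1000, 5)
  s2 <- sigma2 * rchisq(1000, 6) / 6
  pr <- estimate_eb_prior(s2, 6)
  lf <- limma::fitFDist(s2, df1 = 6)
  expect_equal(pr$d0, lf$df2, tolerance = 1e-6)
  expect_equal(pr$s2_0, lf$scale, tolerance = 1e-6)
})

test_that("the shrinkage formula matches its closed form and bounds", {
  # d0 = 4, s2_0 = 1, s2_g = 3, d_g = 2 -> s2_post = (4 + 6)/6 = 5/3
  st <- list(gene_id = "g1", mean_diff = 1, s2_g = 3, d_g = 2L, n_a = 2L, n_b = 2L)
  out <- moderated_t(st, list(d0 = 4, s2_0 = 1))
  expect_equal(out$s2_post, 5 / 3)
  expect_equal(out$df_total, 6)

  # posterior variance always lies between the observed and prior variances
  set.seed(64)
  x <- random_matrix(200, 6, seed = 64)
  stt <- genewise_stats(x, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  pr <- estimate_eb_prior(stt$s2_g, stt$d_g)
  res <- moderated_t(stt, pr)
  expect_true(all(res$s2_post >= pmin(res$s2_g, pr$s2_0) - 1e-12))
  expect_true(all(res$s2_post <= pmax(res$s2_g, pr$s2_0) + 1e-12))
})

test_that("d0 = 0 reduces exactly to the classical pooled t-test", {
  x <- random_matrix(100, 7, seed = 65)
  ga <- c("s1", "s2", "s3"); gb <- c("s4", "s5", "s6", "s7")
  st <- genewise_stats(x, ga, gb)
  out <- moderated_t(st, list(d0 = 0, s2_0 = 1))
  for (i in c(1, 17, 58, 100)) {
    tt <- t.test(x[i, ga], x[i, gb], var.equal = TRUE)
    expect_equal(out$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(out$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("d0 = Inf pins every posterior variance at s2_0 and zero difference gives p = 1", {
  x <- random_matrix(50, 6, seed = 66)
  st <- genewise_stats(x, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  out <- moderated_t(st, list(d0 = Inf, s2_0 = 0.5))
  expect_true(all(out$s2_post == 0.5))

  st0 <- list(gene_id = "g", mean_diff = 0, s2_g = 1, d_g = 4L, n_a = 3L, n_b = 3L)
  r0 <- moderated_t(st0, list(d0 = 0, s2_0 = 1))
  expect_equal(r0$t_mod, 0)
  expect_equal(r0$p, 1)
})

test_that("|t| grows and p falls as the mean difference grows at fixed variance", {
  st <- list(gene_id = sprintf("g%d", 1:5), mean_diff = c(0.5, 1, 2, 4, 8),
             s2_g = rep(1, 5), d_g = 4L, n_a = 3L, n_b = 3L)
  out <- moderated_t(st, list(d0 = 2, s2_0 = 1))
  expect_true(all(diff(abs(out$t_mod)) > 0))
  expect_true(all(diff(out$p) < 0))
})

test_that("the full moderated fit reproduces limma's empirical-Bayes pipeline", {
  set.seed(67)
  x <- random_matrix(400, 6, seed = 67, sd = 0.4)
  x[1:40, 4:6] <- x[1:40, 4:6] + 1.5
  fit <- moderated_t_fit(x, group_a = c("s4", "s5", "s6"), group_b = c("s1", "s2", "s3"))
  design <- cbind(intercept = 1, oe = c(0, 0, 0, 1, 1, 1))
  lfit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(fit$prior$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior$s2_0, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t_mod, unname(lfit$t[, "oe"]), tolerance = 1e-8)
  expect_equal(fit$table$p, unname(lfit$p.value[, "oe"]), tolerance = 1e-8)
  expect_equal(fit$table$adj_p,
               unname(p.adjust(lfit$p.value[, "oe"], "BH")), tolerance = 1e-8)
  expect_equal(unname(coef(fit)), fit$table$mean_diff)
})

test_that("BH adjustment handles ties, hand cases and input bounds", {
  expect_equal(bh_adjust(rep(0.04, 7)), rep(0.04, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.9, 0.001, 0.04, 0.5)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")
})

test_that("significance calls intersect per-line sets and police the universe", {
  x <- random_matrix(60, 12, seed = 68, sd = 0.3)
  x[1:10, 4:6] <- x[1:10, 4:6] + 4       # strong effect, line A samples s1..s6
  x[6:15, 10:12] <- x[6:15, 10:12] + 4   # overlapping effect in line B
  fa <- moderated_t_fit(x, sprintf("s%d", 4:6), sprintf("s%d", 1:3), alpha_adj = 0.05)
  fb <- moderated_t_fit(x, sprintf("s%d", 10:12), sprintf("s%d", 7:9), alpha_adj = 0.05)
  call <- call_and_intersect(fa, fb, alpha_adj = 0.05)
  expect_true(all(call$intersection %in% call$set_a))
  expect_true(all(call$intersection %in% call$set_b))
  expect_setequal(call$intersection, intersect(call$set_a, call$set_b))

  # identical fits intersect to themselves
  same <- call_and_intersect(fa, fa, alpha_adj = 0.05)
  expect_setequal(same$intersection, same$set_a)

  fb_small <- suppressWarnings(
    moderated_t_fit(x[1:30, ], sprintf("s%d", 10:12), sprintf("s%d", 7:9)))
  expect_error(call_and_intersect(fa, fb_small), "universes differ")
})
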