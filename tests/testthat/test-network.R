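test_that("correlation matrix matches direct Pearson computation", {
  # perfect linear dependence and sign flips
  a <- c(1, 2, 3, 4, 5)
  x <- cbind(a = a, b = 2 * a, c = -a)
  cm <- correlation_matrix(x)
  expect_equal(cm$weights["a", "b"], 1.0)
  expect_equal(cm$weights["a", "c"], -1.0)

  # hand-checkable 4-participant pair
  y <- cbind(A = c(1, 2, 3, 4), C = c(1, 3, 2, 4))
  expect_equal(correlation_matrix(y)$weights["A", "C"], 0.8)

  # random table against the naive two-pass oracle
  set.seed(42)
  z <- matrix(rnorm(80), 10, 8)
  w <- correlation_matrix(z)$weights
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(w[i, j], bf_pearson(z[, i], z[, j]), tolerance = 1e-10)
  }
  expect_true(isSymmetric(w))
  expect_equal(unname(diag(w)), rep(1, 8))
})

test_that("correlation matrix rejects tiny subsets and flat regions", {
  x <- cbind(a = rnorm(10), flat = rep(2, 10))
  expect_error(correlation_matrix(x), "flat")
  expect_error(correlation_matrix(cbind(rnorm(10), rnorm(10)), 1:2),
               "at least 3")
})

test_that("correlation decomposes into covariance and SD-product means", {
  # identical series with sd 2: covariance 4, SD product 4
  base <- c(-1.2, 0.4, 1.9, -0.8, -0.3) * 2 / sd(c(-1.2, 0.4, 1.9, -0.8, -0.3))
  x <- cbind(base, base, base)
  d <- decompose_correlation(x)
  expect_equal(d$mean_covariance, 4, tolerance = 1e-12)
  expect_equal(d$mean_sd_product, 4, tolerance = 1e-12)
  expect_equal(d$ratio, 1)

  # independent standard normals: covariance near 0, SD product near 1
  set.seed(1)
  z <- matrix(rnorm(3000), 1000, 3)
  dz <- decompose_correlation(z)
  expect_lt(abs(dz$mean_covariance), 0.1)
  expect_equal(dz$mean_sd_product, 1, tolerance = 0.1)

  # 3-region toy table against elementwise brute force
  set.seed(2)
  t3 <- matrix(rnorm(18), 6, 3)
  dt <- decompose_correlation(t3)
  cv <- cov(t3); s <- sqrt(diag(cv))
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  expect_equal(dt$mean_covariance,
               mean(apply(pairs, 1, function(p) cv[p[1], p[2]])),
               tolerance = 1e-12)
  expect_equal(dt$mean_sd_product,
               mean(apply(pairs, 1, function(p) s[p[1]] * s[p[2]])),
               tolerance = 1e-12)
})

test_that("bootstrap p-values behave at the extremes", {
  set.seed(3)
  n <- 60
  f <- rnorm(n)
  strong <- cbind(f + 0.1 * rnorm(n), f + 0.1 * rnorm(n))  # r ~ 0.99
  p <- bootstrap_edge_pvalues(strong, n_boot = 200, seed = 1)
  expect_equal(p[1, 2], 0)
  p1 <- bootstrap_edge_pvalues(strong, n_boot = 200, seed = 1,
                               smoothing = "add_one")
  expect_equal(p1[1, 2], 2 / 201)

  # add-one smoothing at the B = 2 boundary: only 2/3 or 1 possible
  weak <- cbind(rnorm(20), rnorm(20))
  p2 <- replicate(20, bootstrap_edge_pvalues(
    weak, n_boot = 2, seed = sample.int(1e6, 1),
    smoothing = "add_one")[1, 2])
  expect_true(all(p2 %in% c(2 / 3, 1)))
})

test_that("bootstrap p-values are approximately uniform under the null", {
  set.seed(7)
  pvals <- replicate(500, {
    x <- cbind(rnorm(60), rnorm(60))
    bootstrap_edge_pvalues(x, n_boot = 200,
                           seed = sample.int(1e6, 1))[1, 2]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("bootstrap p-values are deterministic given the seed", {
  set.seed(8)
  x <- matrix(rnorm(300), 30, 10)
  expect_identical(bootstrap_edge_pvalues(x, n_boot = 50, seed = 4),
                   bootstrap_edge_pvalues(x, n_boot = 50, seed = 4))
})

test_that("BH adjustment matches hand computation and handles edge cases", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_error(fdr_adjust(c(0.1, NA)), "NA")
  set.seed(5)
  p <- runif(40)
  expect_equal(fdr_adjust(p), bf_bh(p), tolerance = 1e-12)
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("thresholding retains exactly the sub-alpha edges", {
  set.seed(6)
  x <- matrix(rnorm(200), 20, 10)
  cm <- correlation_matrix(x)
  flat <- matrix(0.5, 10, 10)
  empty <- threshold_network(cm, flat, alpha = 0.01)
  expect_equal(sum(empty$mask), 0)
  expect_true(all(empty$weights == 0))
  full <- threshold_network(cm, matrix(0.001, 10, 10), alpha = 0.01)
  expect_equal(sum(full$mask[upper.tri(full$mask)]), 45)
  expect_equal(full$weights[2, 7], cm$weights[2, 7])
  expect_error(threshold_network(cm, matrix(0.5, 9, 9)), "dimension")
})

test_that("retention probability is nondecreasing in the population correlation", {
  retention <- sapply(c(0, 0.2, 0.4, 0.6), function(r) {
    hits <- sapply(1:8, function(s) {
      set.seed(1000 + s + round(1000 * r))
      g <- rnorm(60)
      x <- sapply(1:6, function(j) sqrt(r) * g + sqrt(1 - r) * rnorm(60))
      net <- build_network(x, n_boot = 200, seed = s)
      mean(net$mask[upper.tri(net$mask)])
    })
    mean(hits)
  })
  expect_true(all(diff(retention) >= 0))
  expect_lt(retention[1], 0.05)
  expect_gt(retention[4], 0.5)
})

test_that("edge list export carries observed correlations and retention", {
  set.seed(9)
  x <- matrix(rnorm(150), 15, 10)
  net <- build_network(x, n_boot = 100, seed = 2)
  el <- edge_list(net)
  expect_equal(nrow(el), 45)
  cm <- correlation_matrix(x)
  i <- which(el$region_i == 2 & el$region_j == 5)
  expect_equal(el$r[i], cm$weights[2, 5])
  expect_equal(el$retained, el$p_adj < net$alpha)
})
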