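test_that("k-means recovers separable groups exactly and is deterministic under seed", {
  X <- make_blobs(1, m = 4, K = 3, s = 0)  # three duplicated points
  fit <- kmeans_fit(X, 3, seed = 11)
  expect_equal(fit$sse, 0)
  expect_equal(sort(fit$sizes), c(4, 4, 4))
  expect_identical(kmeans_fit(X, 3, seed = 11)$assignments, fit$assignments)

  # 1-D {0,1,10,11}: the optimal 2-partition (verified by brute force over
  # all 2^4 assignments) is {0,1} vs {10,11} with centroids 0.5, 10.5
  X1 <- matrix(c(0, 1, 10, 11), ncol = 1)
  f2 <- kmeans_fit(X1, 2, seed = 3)
  expect_equal(sort(f2$centroids[, 1]), c(0.5, 10.5))
  expect_equal(f2$sse, 1.0)

  # K = n gives singletons with zero SSE
  fn <- kmeans_fit(X1, 4, seed = 5)
  expect_equal(fn$sse, 0)
  expect_equal(sort(fn$sizes), rep(1, 4))
  expect_error(kmeans_fit(X1, 5, seed = 1), "exceeds")
})

test_that("k-means agrees with the reference implementation on separable data", {
  X <- make_blobs(2, m = 15, K = 3)
  ours <- kmeans_fit(X, 3, seed = 1)
  ref <- stats::kmeans(X, centers = 3, nstart = 10)
  expect_equal(ours$sse, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(length(unique(paste(ours$assignments, ref$cluster))), 3)
})

test_that("uniformity score follows the chi-squared tail and label permutation invariance", {
  expect_equal(unif_score(c(4, 4, 4)), 1)
  # sizes (6,3,3): X2 = 1.5 by hand; p from the chi-squared df=2 tail
  expect_equal(unif_score(c(6, 3, 3)), pchisq(1.5, 2, lower.tail = FALSE))
  expect_equal(unif_score(c(3, 6, 3)), unif_score(c(6, 3, 3)))
  # sizes (12,0): X2 = 12 by direct arithmetic
  expect_equal(unif_score(c(12, 0)), pchisq(12, 1, lower.tail = FALSE))
})

test_that("multi k-means selects the planted K and excludes empty/sparse configurations", {
  X <- make_blobs(5, m = 4, K = 3, s = 0)  # 12 vectors, 3 equal groups
  cfg <- study_config(seed = 1L)
  res <- multi_kmeans(X, cfg, seed = 2)
  expect_equal(res$K_star, 3)
  expect_equal(unif_score(res$best), 1)
  expect_gte(res$K_star, cfg$k_min)
  # any sweep entry with an undersized cluster is flagged with a reason
  if (nrow(res$excluded_Ks) > 0) {
    expect_true(all(res$excluded_Ks$reason %in% c("empty", "sparse")))
  }
})

test_that("BIC penalises K at equal SSE and matches a hand-evaluated instance", {
  X <- make_blobs(6, m = 10, K = 2, d = 2)
  fit3 <- list(K = 3, sse = 5.0, sizes = c(7, 7, 6))
  fit4 <- list(K = 4, sse = 5.0, sizes = c(5, 5, 5, 5))
  class(fit3) <- class(fit4) <- "pc_clustering"
  expect_gt(bic_score(fit4, X), bic_score(fit3, X))

  # 6 points in 2-D with a fixed assignment: evaluate the formula directly
  X6 <- matrix(c(0, 0, 1, 0, 0, 1, 10, 10, 11, 10, 10, 11),
               ncol = 2, byrow = TRUE)
  assign6 <- c(1, 1, 1, 2, 2, 2)
  cent <- rbind(colMeans(X6[1:3, ]), colMeans(X6[4:6, ]))
  sse <- sum((X6 - cent[assign6, ])^2)
  fit <- structure(list(K = 2, sse = sse, sizes = c(3, 3),
                        centroids = cent, assignments = assign6),
                   class = "pc_clustering")
  n <- 6; d <- 2
  sigma2 <- sse / (d * (n - 2))
  logL <- sum(c(3, 3) * log(c(3, 3) / n)) -
    n * d / 2 * log(2 * pi * sigma2) - sse / (2 * sigma2)
  expect_equal(bic_score(fit, X6), -2 * logL + (2 * d + 2 + 1) * log(n))

  # zero SSE (duplicated groups) stays finite via the variance floor
  X0 <- make_blobs(7, m = 5, K = 2, d = 2, s = 0)
  f0 <- kmeans_fit(X0, 2, seed = 1)
  expect_true(is.finite(bic_score(f0, X0)))
})

test_that("BIC improves for a strictly better clustering at the same K", {
  X <- make_blobs(8, m = 10, K = 3)
  good <- kmeans_fit(X, 3, seed = 1, restarts = 10)
  # force a worse assignment: random labels at the same K
  set.seed(9)
  lab <- sample(1:3, nrow(X), replace = TRUE)
  cent <- do.call(rbind, lapply(1:3, function(k)
    colMeans(X[lab == k, , drop = FALSE])))
  worse <- structure(list(K = 3, assignments = lab, centroids = cent,
                          sse = sum((X - cent[lab, ])^2),
                          sizes = tabulate(lab, 3)),
                     class = "pc_clustering")
  expect_gt(worse$sse, good$sse)
  expect_gt(bic_score(worse, X), bic_score(good, X))
})

test_that("the two sweeps share the K range and recover planted K across seeds", {
  X <- make_blobs(10, m = 20, K = 3)
  cfg <- study_config(seed = 1L)
  mk <- multi_kmeans(X, cfg)
  xm <- xmeans_sweep(X, cfg)
  expect_equal(mk$selection_scores$K, xm$selection_scores$K)
  expect_equal(mk$K_star, 3)
  expect_equal(xm$K_star, 3)

  hits_mk <- hits_xm <- 0L
  for (s in 1:50) {
    Xs <- make_blobs(s, m = 20, K = 3)
    hits_mk <- hits_mk + (multi_kmeans(Xs, cfg, seed = s)$K_star == 3)
    hits_xm <- hits_xm + (xmeans_sweep(Xs, cfg, seed = s + 1000L)$K_star == 3)
  }
  expect_gte(hits_mk, 45)
  expect_gte(hits_xm, 45)
})

test_that("k-means iteration never worsens the returned SSE relative to any restart", {
  X <- make_blobs(12, m = 10, K = 4, s = 1.5)
  best10 <- kmeans_fit(X, 4, seed = 1, restarts = 10)$sse
  best1 <- kmeans_fit(X, 4, seed = 1, restarts = 1)$sse
  expect_lte(best10, best1 + 1e-12)
})

test_that("BIC selection fragments the feature space at least as much as the uniformity criterion", {
  # on the default synthetic study (one dominant common pattern plus
  # smaller tiers) the BIC sweep picks at least as many clusters
  res <- default_assessment()
  expect_gte(res$xmeans$K_star, res$multikmeans$K_star)
})
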