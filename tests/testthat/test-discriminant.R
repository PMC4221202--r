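test_that("coincident groups give Wilks' Lambda near 1 and phi near 0", {
  set.seed(31)
  y <- matrix(rnorm(30), ncol = 3)
  fit <- cva_fit(rbind(y, y), rep(c("a", "b"), each = 10))  # identical groups
  expect_gt(fit$wilks_lambda, 0.99)
  expect_lt(fit$phi, 0.2)
  expect_gt(fit$p_chi2, 0.9)
})

test_that("discriminant axis is parallel to the closed-form Fisher direction", {
  gc <- gaussian_clusters(40, 2, gap = 5, seed = 32)
  fit <- cva_fit(gc$scores, gc$groups)
  # independent closed-form LDA direction W^-1 (mu1 - mu2)
  x1 <- gc$scores[gc$groups == "a", ]; x2 <- gc$scores[gc$groups == "b", ]
  W <- crossprod(scale(x1, scale = FALSE)) + crossprod(scale(x2, scale = FALSE))
  fisher <- solve(W) %*% (colMeans(x1) - colMeans(x2))
  cosine <- sum(fit$discriminant_vector * fisher) /
    sqrt(sum(fit$discriminant_vector^2) * sum(fisher^2))
  expect_gt(abs(cosine), 0.999)
  # and to MASS::lda's scaling vector
  ld <- MASS::lda(gc$scores, grouping = gc$groups)$scaling[, 1]
  cos2 <- sum(fit$discriminant_vector * ld) /
    sqrt(sum(fit$discriminant_vector^2) * sum(ld^2))
  expect_gt(abs(cos2), 0.999)
  # pooled within-group variance of cv scores is 1
  cv <- fit$cv_scores
  wv <- (sum((cv[gc$groups == "a"] - mean(cv[gc$groups == "a"]))^2) +
         sum((cv[gc$groups == "b"] - mean(cv[gc$groups == "b"]))^2)) /
        (length(cv) - 2)
  expect_equal(wv, 1, tolerance = 1e-8)
})

test_that("phi is invariant to affine recoding of the score columns", {
  gc <- gaussian_clusters(25, 3, gap = 2, seed = 33)
  fit <- cva_fit(gc$scores, gc$groups)
  A <- matrix(c(2, 0.3, -1, 0.5, 1.5, 0.2, 0, -0.7, 3), 3, 3)
  b <- c(5, -2, 1)
  xt <- sweep(gc$scores %*% A, 2, b, `+`)
  fit2 <- cva_fit(xt, gc$groups)
  expect_equal(fit2$phi, fit$phi, tolerance = 1e-6)
  expect_equal(fit2$wilks_lambda, fit$wilks_lambda, tolerance = 1e-8)
})

test_that("classification assigns by proximity with deterministic tie-breaking", {
  gc <- gaussian_clusters(30, 2, gap = 8, seed = 34)
  fit <- cva_fit(gc$scores, gc$groups)
  res <- cva_classify(fit, gc$scores, gc$groups)
  expect_equal(res$confusion$percent_correct, 100)
  expect_equal(sum(res$confusion$counts), 60)
  # a point exactly at a centroid is assigned that group with distance 0
  v <- fit$discriminant_vector
  pt <- fit$grand_mean + fit$centroids["a"] * v / sum(v^2)
  one <- cva_classify(fit, matrix(pt, 1))$assignments
  expect_equal(one$assigned, "a")
  expect_equal(one$dist_a, 0, tolerance = 1e-9)
  # midpoint between centroids ties to the alphabetically first group
  mid <- fit$grand_mean + mean(fit$centroids) * v / sum(v^2)
  tie <- cva_classify(fit, matrix(mid, 1))$assignments
  expect_true(tie$tie)
  expect_equal(tie$assigned, "a")
})

test_that("jackknife equals an independent naive re-loop exactly", {
  gc <- gaussian_clusters(12, 2, gap = 1.5, seed = 35)
  jk <- cva_jackknife(gc$scores, gc$groups)
  naive <- character(24)
  for (i in 1:24) {
    f <- cva_fit(gc$scores[-i, ], gc$groups[-i])
    cv <- as.numeric((gc$scores[i, ] - f$grand_mean) %*% f$discriminant_vector)
    naive[i] <- names(f$centroids)[which.min(abs(cv - f$centroids))]
  }
  expect_identical(jk$assignments$assigned, naive)
  expect_equal(jk$percent_correct, 100 * sum(naive == gc$groups) / 24)
})

test_that("resubstitution accuracy dominates the jackknife on average", {
  set.seed(36)
  diffs <- replicate(40, {
    gc <- gaussian_clusters(10, 2, gap = runif(1, 0.5, 2.5))
    fit <- cva_fit(gc$scores, gc$groups)
    resub <- cva_classify(fit, gc$scores, gc$groups)$confusion$percent_correct
    jk <- cva_jackknife(gc$scores, gc$groups)$percent_correct
    resub - jk
  })
  expect_gte(mean(diffs), 0)
})

test_that("null distributions behave at the degenerate and separated extremes", {
  gc <- gaussian_clusters(20, 2, gap = 6, seed = 37)
  mc <- null_montecarlo(gc$scores, gc$groups, R = 200, seed = 1)
  bt <- null_bootstrap(gc$scores, gc$groups, R = 200, seed = 1)
  expect_equal(mc$p_value, 0)       # separation far beyond any null draw
  expect_equal(bt$p_value, 0)
  expect_true(all(bt$phi_values < mc$phi_observed))
  r1 <- null_montecarlo(gc$scores, gc$groups, R = 1, seed = 2)
  expect_true(r1$p_value %in% c(0, 1))
  expect_equal(r1$p_conservative, (r1$p_value * 1 + 1) / 2)
})

test_that("bootstrap nulls ignore the labelling (group structure destroyed)", {
  gc <- gaussian_clusters(20, 2, gap = 4, seed = 38)
  shuffled <- sample(gc$groups)
  b1 <- null_bootstrap(gc$scores, gc$groups, R = 300, seed = 9)
  b2 <- null_bootstrap(gc$scores, shuffled, R = 300, seed = 9)
  expect_equal(mean(b1$phi_values), mean(b2$phi_values), tolerance = 1e-8)
})

test_that("chi-squared and Monte Carlo decisions usually agree near the threshold", {
  set.seed(39)
  agree <- replicate(60, {
    gap <- runif(1, 0, 1.2)
    gc <- gaussian_clusters(15, 3, gap = gap)
    fit <- cva_fit(gc$scores, gc$groups)
    mc <- null_montecarlo(gc$scores, gc$groups, R = 199)
    (fit$p_chi2 < 0.05) == (mc$p_value < 0.05)
  })
  expect_gte(mean(agree), 0.9)
})

test_that("unknown projection reports distances and out-of-range flags", {
  fit <- aligned_fixture(n = 16, p = 12, seed = 40)
  pca <- pca_fit(fit, k = 3)
  groups <- rep(c("browser", "grazer"), each = 8)
  cva <- cva_fit(pca$scores[, 1:3], groups)
  # a held-out specimen equal to a training one lands on its assignment
  unk <- fit$configs[1]
  names(unk) <- "mystery"
  res <- project_unknowns(cva, pca, unk)
  expect_named(res, c("id", "cv_score", "dist_browser", "dist_grazer",
                      "assigned", "tie", "outside_range"))
  expect_false(res$outside_range)
  expect_true(res$assigned %in% c("browser", "grazer"))
})
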