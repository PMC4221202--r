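test_that("Blomberg's K is exactly 1 on a star phylogeny", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1);")
  set.seed(61)
  x <- setNames(rnorm(6), star$tip.label)
  res <- blomberg_k(x, star, permutations = 0)
  expect_equal(res$K, 1, tolerance = 1e-12)
})

test_that("K and lambda are invariant to affine trait transformation", {
  sim <- simulate_tree_bm(16, sigma2 = 1, seed = 62)
  k1 <- blomberg_k(sim$trait, sim$tree, permutations = 0)
  k2 <- blomberg_k(3.5 * sim$trait - 11, sim$tree, permutations = 0)
  expect_equal(k1$K, k2$K, tolerance = 1e-8)
  l1 <- pagel_lambda(sim$trait, sim$tree)
  l2 <- pagel_lambda(3.5 * sim$trait - 11, sim$tree)
  expect_equal(l1$lambda, l2$lambda, tolerance = 1e-6)
})

test_that("K agrees with picante and phytools on BM data", {
  sim <- simulate_tree_bm(20, sigma2 = 2, seed = 63)
  mine <- blomberg_k(sim$trait, sim$tree, permutations = 0)
  expect_equal(mine$K,
               as.numeric(picante::Kcalc(sim$trait[sim$tree$tip.label], sim$tree)),
               tolerance = 1e-6)
  ph <- phytools::phylosig(sim$tree, sim$trait, method = "K")
  expect_equal(mine$K, unname(as.numeric(ph)), tolerance = 1e-6)
})

test_that("lambda likelihood at 1 matches a direct-determinant evaluation and phytools", {
  sim <- simulate_tree_bm(15, sigma2 = 1.5, seed = 64)
  x <- sim$trait[sim$tree$tip.label]
  C <- ape::vcv.phylo(sim$tree)
  # independent direct evaluation of the BM log-likelihood at lambda = 1
  Ci <- solve(C)
  one <- rep(1, 15)
  a <- as.numeric(t(one) %*% Ci %*% x) / as.numeric(t(one) %*% Ci %*% one)
  s2 <- as.numeric(t(x - a) %*% Ci %*% (x - a)) / 15
  ll_direct <- as.numeric(-15 / 2 * log(2 * pi * s2) -
                          0.5 * determinant(C)$modulus - 15 / 2)
  expect_equal(snoutmorph:::lambda_loglik(x, C, 1), ll_direct, tolerance = 1e-6)
  ph <- phytools::phylosig(sim$tree, sim$trait, method = "lambda")
  mine <- pagel_lambda(sim$trait, sim$tree)
  expect_equal(mine$lambda, ph$lambda, tolerance = 1e-3)
  expect_equal(mine$logL, ph$logL, tolerance = 1e-4)
})

test_that("lambda recovery separates structured from unstructured data", {
  set.seed(65)
  tree <- simulate_tree_bm(24, seed = 650)$tree
  lam_bm <- replicate(40, {
    tr <- ape::rTraitCont(tree, sigma = 1)
    pagel_lambda(tr, tree)$lambda
  })
  lam_iid <- replicate(40, {
    tr <- setNames(rnorm(24), tree$tip.label)
    pagel_lambda(tr, tree)$lambda
  })
  expect_gte(median(lam_bm), 0.9)
  expect_lte(median(lam_iid), 0.1)
})

test_that("iid traits on an imbalanced tree depress K and its significance", {
  # deeply imbalanced (pectinate) 16-tip tree
  txt <- paste0(paste(rep("(", 15), collapse = ""), "t1:1",
                paste(sprintf(",t%d:%d):1", 2:15, 1:14), collapse = ""),
                ",t16:15);")
  tree <- ape::read.tree(text = txt)
  set.seed(66)
  ks <- replicate(60, {
    x <- setNames(rnorm(16), tree$tip.label)
    blomberg_k(x, tree, permutations = 0)$K
  })
  expect_lt(mean(ks), 1)
  ps <- replicate(20, {
    x <- setNames(rnorm(16), tree$tip.label)
    blomberg_k(x, tree, permutations = 99)$p_K
  })
  expect_gt(mean(ps), 0.2)
})

test_that("independent contrasts match the closed form, ape::pic, and zero on constants", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  ct <- independent_contrasts(setNames(c(3, 1), c("a", "b")), two)
  expect_equal(abs(unname(ct)), 2 / sqrt(2), tolerance = 1e-12)
  four <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  x <- setNames(c(1, 3, 6, 2), c("a", "b", "c", "d"))
  mine <- independent_contrasts(x, four)
  expect_equal(sort(abs(unname(mine))),
               sort(abs(unname(ape::pic(x, four)))), tolerance = 1e-10)
  const <- independent_contrasts(setNames(rep(2, 4), c("a", "b", "c", "d")), four)
  expect_equal(unname(const), rep(0, 3))
})

test_that("BM contrasts are standard normal after rate standardisation", {
  set.seed(67)
  tree <- simulate_tree_bm(32, seed = 670)$tree
  pooled <- unlist(lapply(1:20, function(i) {
    independent_contrasts(ape::rTraitCont(tree, sigma = 1), tree)
  }))
  expect_gt(stats::shapiro.test(pooled)$p.value, 0.01)
  expect_equal(stats::var(pooled), 1, tolerance = 0.15)
})

test_that("contrast rank correlation handles concordance and sign positivisation", {
  sim <- simulate_tree_bm(12, seed = 68)
  cx <- independent_contrasts(sim$trait, sim$tree)
  expect_equal(contrast_correlation(cx, cx, "spearman")$estimate, 1)
  expect_equal(contrast_correlation(cx, cx, "kendall")$estimate, 1)
  expect_equal(contrast_correlation(cx, -cx, "spearman")$estimate, -1)
})

test_that("contrast correlation holds its type-I error for independent traits", {
  set.seed(69)
  tree <- simulate_tree_bm(20, seed = 690)$tree
  rej <- replicate(200, {
    c1 <- independent_contrasts(ape::rTraitCont(tree, sigma = 1), tree)
    c2 <- independent_contrasts(ape::rTraitCont(tree, sigma = 1), tree)
    contrast_correlation(c1, c2, "spearman")$p_value < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("mass residuals are OLS residuals on log10 mass", {
  set.seed(70)
  mass <- setNames(exp(rnorm(5, 11, 1)), letters[1:5])
  sc <- setNames(2 - 0.8 * log10(mass) + c(0.1, -0.2, 0.05, 0.03, 0.02),
                 letters[1:5])
  res <- mass_residuals(sc, mass)
  expect_equal(sum(res), 0, tolerance = 1e-10)
  # normal-equations oracle
  X <- cbind(1, log10(mass))
  beta <- solve(t(X) %*% X, t(X) %*% sc)
  expect_equal(unname(res), unname(as.numeric(sc - X %*% beta)), tolerance = 1e-10)
  # exact linear relation leaves zero residuals
  sc2 <- setNames(1 + 2 * log10(mass), letters[1:5])
  expect_equal(max(abs(mass_residuals(sc2, mass))), 0, tolerance = 1e-10)
  expect_error(mass_residuals(sc, setNames(rep(100, 5), letters[1:5])), "constant")
})
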