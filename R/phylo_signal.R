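# trait vectors are named numeric vectors keyed by species id

check_trait_tree <- function(trait, tree) {
  if (is.null(names(trait))) stop("trait must be a named vector keyed by species")
  if (!all(names(trait) %in% tree$tip.label) ||
      !all(tree$tip.label %in% names(trait))) {
    stop("trait names and tree tips do not match")
  }
  if (!all(is.finite(trait))) stop("trait has non-finite values")
  trait[tree$tip.label]
}

#' Blomberg's K phylogenetic signal statistic
#'
#' K compares the observed ratio of tip variance around the GLS
#' (phylogenetic) mean to the tree-corrected variance, against its
#' expectation under Brownian motion on the supplied tree:
#' \deqn{K = \frac{MSE_0 / MSE}{(\mathrm{tr}\,C - n / (1'C^{-1}1)) / (n-1)}}
#' with \eqn{MSE_0 = (x - \hat a 1)'(x - \hat a 1)/(n-1)},
#' \eqn{MSE = (x - \hat a 1)'C^{-1}(x - \hat a 1)/(n-1)} and
#' \eqn{\hat a} the GLS root state. E(K) = 1 under Brownian motion; K = 1
#' exactly on a star phylogeny (C = I). Significance is assessed by
#' permuting trait values across tips and recomputing K
#' (`p = (1 + #\{K_perm >= K_obs\}) / (1 + permutations)`).
#'
#' @param trait Named numeric vector keyed by species id.
#' @param tree `phylo` tree with >= 4 tips matching the trait names.
#' @param permutations Number of tip-label permutations (default 999;
#'   0 skips the test and returns `p_K = NA`).
#' @param seed Optional integer seed.
#' @return List with `K` and `p_K`.
#' @export
blomberg_k <- function(trait, tree, permutations = 999L, seed = NULL) {
  x <- check_trait_tree(trait, tree)
  n <- length(x)
  if (n < 4L) stop("need >= 4 tips")
  C <- ape::vcv.phylo(tree)
  ci <- tryCatch(chol(C), error = function(e) stop("singular tree covariance"))
  Cinv <- chol2inv(ci)
  one <- rep(1, n)
  s1 <- as.numeric(t(one) %*% Cinv %*% one)
  expected <- (sum(diag(C)) - n / s1) / (n - 1)
  k_stat <- function(x) {
    a <- as.numeric(t(one) %*% Cinv %*% x) / s1
    r <- x - a
    mse0 <- sum(r^2) / (n - 1)
    mse <- as.numeric(t(r) %*% Cinv %*% r) / (n - 1)
    (mse0 / mse) / expected
  }
  K <- k_stat(x)
  p_K <- NA_real_
  if (permutations > 0L) {
    if (!is.null(seed)) set.seed(seed)
    kp <- vapply(seq_len(permutations), function(i) k_stat(sample(x)), 1.0)
    p_K <- (1 + sum(kp >= K)) / (1 + permutations)
  }
  list(K = K, p_K = p_K)
}

# Multivariate-normal log-likelihood of a trait under the lambda-scaled
# tree covariance, with GLS mean and ML-profiled rate.
lambda_loglik <- function(x, C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  n <- length(x)
  ch <- chol(Cl)
  Cinv <- chol2inv(ch)
  one <- rep(1, n)
  a <- as.numeric(t(one) %*% Cinv %*% x) / as.numeric(t(one) %*% Cinv %*% one)
  r <- x - a
  q <- as.numeric(t(r) %*% Cinv %*% r)
  sigma2 <- q / n
  logdet <- 2 * sum(log(diag(ch)))
  -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
}

#' Pagel's lambda by maximum likelihood
#'
#' Multiplies the off-diagonal elements of the Brownian-motion tree
#' covariance by lambda and maximises the multivariate-normal
#' log-likelihood (GLS mean, profiled rate) over lambda in [0, 1].
#' lambda = 0 corresponds to no phylogenetic structure (a star tree),
#' lambda = 1 to Brownian motion on the supplied tree. The p-value is a
#' likelihood-ratio test of the fitted lambda against `against` (default
#' 0) with one degree of freedom.
#'
#' @inheritParams blomberg_k
#' @param against Null value of lambda for the LR test (0 or 1).
#' @return List with `lambda`, `logL`, `logL0`, `p_lambda`.
#' @export
pagel_lambda <- function(trait, tree, against = 0) {
  x <- check_trait_tree(trait, tree)
  if (length(x) < 4L) stop("need >= 4 tips")
  C <- ape::vcv.phylo(tree)
  f <- function(l) lambda_loglik(x, C, l)
  opt <- stats::optimise(f, c(0, 1), maximum = TRUE, tol = 1e-8)
  # optimise never evaluates the interval ends; check them explicitly
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, f(0), f(1))
  best <- which.max(ll)
  lambda <- cand[best]; logL <- ll[best]
  logL0 <- f(against)
  lr <- max(0, 2 * (logL - logL0))
  list(lambda = lambda, logL = logL, logL0 = logL0,
       p_lambda = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Felsenstein's phylogenetically independent contrasts
#'
#' Standardised contrasts by the pruning algorithm: at each internal node
#' joining daughters a and b with values x_a, x_b and (lengthened) branch
#' lengths v_a, v_b, the contrast is (x_a - x_b)/sqrt(v_a + v_b), the node
#' value is the precision-weighted average, and the node's own branch is
#' lengthened by v_a v_b / (v_a + v_b). Polytomies are resolved arbitrarily
#' with zero-length branches (with a message).
#'
#' @inheritParams blomberg_k
#' @return Named numeric vector of n - 1 contrasts, names being the
#'   internal node numbers of the (resolved) tree.
#' @export
independent_contrasts <- function(trait, tree) {
  if (!ape::is.binary(tree)) {
    message("resolving polytomies with zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  x <- check_trait_tree(trait, tree)
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  n <- ape::Ntip(tree)
  tree <- stats::reorder(tree, "postorder")
  nnode <- n + tree$Nnode
  val <- c(unname(x), rep(NA_real_, tree$Nnode))
  blen <- numeric(nnode)
  blen[tree$edge[, 2L]] <- tree$edge.length
  contrasts <- stats::setNames(rep(NA_real_, tree$Nnode), seq_len(tree$Nnode) + n)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  for (node in unique(tree$edge[, 1L])) {  # postorder parents
    ch <- kids[[as.character(node)]]
    if (length(ch) != 2L) stop("internal error: non-binary node after resolution")
    va <- blen[ch[1L]]; vb <- blen[ch[2L]]
    contrasts[as.character(node)] <- (val[ch[1L]] - val[ch[2L]]) / sqrt(va + vb)
    val[node] <- (val[ch[1L]] / va + val[ch[2L]] / vb) / (1 / va + 1 / vb)
    if (!is.finite(val[node])) {  # both daughter branches zero
      val[node] <- mean(val[ch])
    }
    blen[node] <- blen[node] + va * vb / (va + vb)
  }
  contrasts
}

#' Rank correlation of two sets of independent contrasts
#'
#' Contrast signs are arbitrary (each depends on the order of daughter
#' lineages), so the x contrasts are positivised and the y contrasts have
#' their signs flipped in tandem before a two-sided rank correlation test.
#'
#' @param cx,cy Named contrast vectors from [independent_contrasts()] on
#'   the same tree (same node ids).
#' @param method `"spearman"` or `"kendall"`.
#' @return List with `estimate` (rho or tau) and `p_value`.
#' @export
contrast_correlation <- function(cx, cy, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  if (!identical(names(cx), names(cy))) stop("contrast node ids do not match")
  if (length(cx) < 3L) stop("need >= 3 contrasts")
  flip <- ifelse(cx < 0, -1, 1)
  ct <- suppressWarnings(stats::cor.test(cx * flip, cy * flip, method = method,
                                         alternative = "two.sided", exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Residuals of shape scores on log10 body mass
#'
#' Ordinary least-squares regression of a shape score on log10(body mass),
#' over the species shared by both vectors; returns the residuals keyed by
#' species. Mass is log-transformed before the fit.
#'
#' @param scores Named numeric vector of shape scores.
#' @param mass_g Named numeric vector of body masses in grams (> 0).
#' @return Named numeric vector of residuals.
#' @export
mass_residuals <- function(scores, mass_g) {
  shared <- intersect(names(scores), names(mass_g))
  if (length(shared) < 3L) stop("need >= 3 shared species")
  m <- mass_g[shared]
  if (any(!is.finite(m) | m <= 0)) stop("body mass must be positive and finite")
  lm10 <- log10(m)
  if (stats::sd(lm10) == 0) stop("constant body mass")
  fit <- stats::lm(scores[shared] ~ lm10)
  stats::setNames(stats::residuals(fit), shared)
}
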