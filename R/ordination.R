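#' Covariance-based PCA of aligned shape coordinates
#'
#' Eigendecomposition of the sample covariance matrix (divisor n - 1) of
#' the flattened, superimposed coordinates. Because the decomposition acts
#' on the Procrustes-aligned coordinates directly, the full-rank scores
#' preserve the partial Procrustes distances among specimens. Eigenvector
#' signs follow the convention that the largest-magnitude loading is
#' positive, so axes are reproducible across linear-algebra backends.
#'
#' @param aligned A `gpa_fit`, or a named list of aligned p x 2 matrices.
#' @param k Number of axes to retain; `NULL` (default) retains all axes
#'   with positive variance.
#' @return An object of class `pca_model`: `mean_vector` (length 2p),
#'   `eigenvectors` (2p x k, orthonormal columns), `eigenvalues`,
#'   `variance_fraction` (eigenvalue / total variance), `scores` (n x k,
#'   zero column means), `ids`.
#' @export
pca_fit <- function(aligned, k = NULL) {
  configs <- if (inherits(aligned, "gpa_fit")) aligned$configs else aligned
  if (length(configs) < 2L) stop("need at least 2 specimens")
  x <- flatten_configs(configs)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  eval <- sv$d^2 / (nrow(x) - 1L)
  total <- sum(eval)
  pos <- which(eval > max(eval) * 1e-12)
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  vec <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- xc %*% vec
  rownames(scores) <- names(configs)
  structure(list(mean_vector = mu,
                 eigenvectors = vec,
                 eigenvalues = eval[seq_len(k)],
                 variance_fraction = eval[seq_len(k)] / total,
                 total_variance = total,
                 scores = scores,
                 ids = names(configs)),
            class = "pca_model")
}

#' Project aligned configurations into a fitted PCA space
#'
#' @param model A `pca_model` (or `phylo_pca_model`).
#' @param configs Named list of p x 2 configurations already aligned into
#'   the model's consensus frame (see [gpa_align_to()]).
#' @return An n x k score matrix.
#' @export
pca_project <- function(model, configs) {
  x <- flatten_configs(configs)
  if (ncol(x) != length(model$mean_vector)) stop("dimension mismatch")
  scores <- sweep(x, 2L, model$mean_vector) %*% model$eigenvectors
  rownames(scores) <- names(configs)
  scores
}

#' Reconstruct configurations from PCA scores
#'
#' Inverse of [pca_project()] for the retained axes.
#'
#' @param model A `pca_model`.
#' @param scores An n x k matrix (or length-k vector) of scores.
#' @return A list of p x 2 matrices (a single matrix for a vector input).
#' @export
pca_reconstruct <- function(model, scores) {
  single <- is.null(dim(scores))
  scores <- rbind(scores)
  flat <- sweep(scores %*% t(model$eigenvectors), 2L, -model$mean_vector)
  out <- lapply(seq_len(nrow(flat)), function(i) unflatten_config(flat[i, ]))
  if (single) out[[1L]] else out
}

#' Phylogenetic PCA of aligned shape coordinates
#'
#' PCA of the evolutionary covariance matrix: with C the Brownian-motion
#' tree covariance (shared path lengths from root), the GLS root mean is
#' \eqn{a = (1' C^{-1} 1)^{-1} 1' C^{-1} X} and the evolutionary covariance
#' \eqn{E = (X - 1a')' C^{-1} (X - 1a') / (n - 1)} is eigendecomposed.
#' Scores are the root-mean-centred data projected on the eigenvectors.
#'
#' @param aligned A `gpa_fit` or named list of aligned p x 2 matrices;
#'   names must match the tree's tip labels exactly.
#' @param tree An `ape` phylo tree whose tips are exactly the specimen ids.
#' @param k Axes to retain (`NULL` = all positive-variance axes, at most
#'   n - 1).
#' @return A `phylo_pca_model` (inherits `pca_model`) with additional
#'   fields `gls_root_mean` (= `mean_vector`) and `tree_covariance`.
#' @export
phylo_pca_fit <- function(aligned, tree, k = NULL) {
  configs <- if (inherits(aligned, "gpa_fit")) aligned$configs else aligned
  ids <- names(configs)
  if (!setequal(ids, tree$tip.label)) stop("tree tips do not match specimen ids")
  x <- flatten_configs(configs)
  C <- ape::vcv.phylo(tree)[ids, ids]
  ci <- tryCatch(chol(C), error = function(e)
    stop("singular tree covariance (zero-length duplicate tips?); jitter branch lengths"))
  Cinv <- chol2inv(ci)
  one <- rep(1, nrow(x))
  denom <- as.numeric(t(one) %*% Cinv %*% one)
  a <- as.numeric(t(one) %*% Cinv %*% x) / denom
  xc <- sweep(x, 2L, a)
  E <- t(xc) %*% Cinv %*% xc / (nrow(x) - 1L)
  eig <- eigen(E, symmetric = TRUE)
  eval <- pmax(eig$values, 0)
  total <- sum(eval)
  pos <- which(eval > max(eval) * 1e-12)
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- xc %*% vec
  rownames(scores) <- ids
  structure(list(mean_vector = a,
                 gls_root_mean = a,
                 eigenvectors = vec,
                 eigenvalues = eval[seq_len(k)],
                 variance_fraction = eval[seq_len(k)] / total,
                 total_variance = total,
                 scores = scores,
                 ids = ids,
                 tree_covariance = C),
            class = c("phylo_pca_model", "pca_model"))
}
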