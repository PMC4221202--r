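#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks to
#' their centroid; the size measure removed when entering shape space.
#'
#' @param config A p x 2 matrix (p >= 3).
#' @return A positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 3L) stop("configuration needs >= 3 points")
  cs <- sqrt(sum(scale(config, scale = FALSE)^2))
  if (cs <= .Machine$double.eps^0.5 * max(1, max(abs(config)))) {
    stop("degenerate configuration: all points coincident")
  }
  cs
}

centre_config <- function(config) {
  sweep(config, 2L, colMeans(config))
}

#' Optimal rigid rotation of one configuration onto another
#'
#' Returns the proper 2 x 2 rotation R (det +1; reflections disallowed)
#' minimising \eqn{\sum \|A R - B\|^2} for two centred configurations with
#' matching landmarks, via the SVD solution of the orthogonal Procrustes
#' problem.
#'
#' @param config_a,config_b Centred p x 2 matrices with equal p.
#' @return A 2 x 2 rotation matrix to be applied as `config_a %*% R`.
#' @export
optimal_rotation <- function(config_a, config_b) {
  if (!all(dim(config_a) == dim(config_b))) stop("mismatched landmark counts")
  m <- crossprod(config_a, config_b)
  if (sum(m^2) == 0 || qr(config_a)$rank == 0L) stop("degenerate configuration")
  sv <- svd(m)
  s <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  sv$u %*% s %*% t(sv$v)
}

#' Partial Procrustes distance between two shapes
#'
#' Square root of the minimised sum of squared coordinate differences after
#' optimal proper rotation of `config_a` onto `config_b`. Both inputs must
#' already be centred and scaled to unit centroid size.
#'
#' @param config_a,config_b Centred unit-centroid-size p x 2 matrices.
#' @return A non-negative scalar.
#' @export
procrustes_distance <- function(config_a, config_b) {
  if (!all(dim(config_a) == dim(config_b))) stop("mismatched landmark counts")
  r <- optimal_rotation(config_a, config_b)
  sqrt(sum((config_a %*% r - config_b)^2))
}

#' Generalized Procrustes superimposition
#'
#' Classical generalized least-squares superimposition into shape space:
#' each configuration is centred and scaled once to unit centroid size, all
#' are rotated to an initial reference (the first specimen), then the
#' consensus is iterated — mean, rescale to unit size, rotate all
#' specimens to the mean — until the partial Procrustes distance between
#' successive consensus shapes falls below `tolerance`. Only proper
#' rotations are used (no reflections), and specimens are not rescaled
#' after the initial unit-size standardisation.
#'
#' @param dataset A `coord_dataset` (or plain named list of p x 2 matrices),
#'   all sharing the same p, with n >= 2 specimens.
#' @param tolerance Convergence tolerance on the consensus displacement,
#'   in partial Procrustes distance units. Default `1e-4`.
#' @param max_iter Maximum consensus iterations. Default 1000.
#' @return An object of class `gpa_fit`: list with `configs` (named list of
#'   aligned p x 2 matrices, centred, unit centroid size), `consensus`
#'   (p x 2 unit-size mean shape), `centroid_sizes` (pre-scaling sizes),
#'   `iterations`, and `final_change`.
#' @export
gpa <- function(dataset, tolerance = 1e-4, max_iter = 1000L) {
  n <- length(dataset)
  if (n < 2L) stop("need at least 2 specimens")
  p <- nrow(dataset[[1L]])
  if (!all(vapply(dataset, nrow, 1L) == p)) stop("mismatched landmark counts")
  cs <- vapply(dataset, centroid_size, 1.0)
  configs <- lapply(seq_len(n), function(i) centre_config(as.matrix(dataset[[i]])) / cs[i])
  names(configs) <- names(dataset)

  unit_mean <- function(cfgs) {
    m <- Reduce(`+`, cfgs) / length(cfgs)
    m <- centre_config(m)
    m / sqrt(sum(m^2))
  }
  ref <- configs[[1L]]
  configs <- lapply(configs, function(cf) cf %*% optimal_rotation(cf, ref))
  consensus <- unit_mean(configs)
  change <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    configs <- lapply(configs, function(cf) cf %*% optimal_rotation(cf, consensus))
    new_consensus <- unit_mean(configs)
    change <- procrustes_distance(consensus, new_consensus)
    consensus <- new_consensus
    if (change < tolerance) break
  }
  if (change >= tolerance) {
    stop("GPA did not converge in ", max_iter,
         " iterations (last consensus change ", signif(change, 4), ")")
  }
  structure(list(configs = configs, consensus = consensus,
                 centroid_sizes = cs, iterations = iter,
                 final_change = change),
            class = "gpa_fit")
}

#' Align new specimens into an existing consensus frame
#'
#' Centres, scales to unit centroid size and rotates each new configuration
#' onto a fitted consensus, without altering the consensus. Used to place
#' specimens of unknown group into the shape space defined by the training
#' sample.
#'
#' @param fit A `gpa_fit`.
#' @param dataset Named list of p x 2 matrices (same p as the fit).
#' @return Named list of aligned p x 2 matrices.
#' @export
gpa_align_to <- function(fit, dataset) {
  p <- nrow(fit$consensus)
  lapply(dataset, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != p) stop("mismatched landmark counts")
    m <- centre_config(m) / centroid_size(m)
    m %*% optimal_rotation(m, fit$consensus)
  })
}

# flatten n configs into an n x 2p matrix (x1..xp then y1..yp per row)
flatten_configs <- function(configs) {
  t(vapply(configs, function(m) c(m[, 1L], m[, 2L]),
           numeric(2L * nrow(configs[[1L]]))))
}

unflatten_config <- function(v) {
  p <- length(v) / 2L
  m <- cbind(v[seq_len(p)], v[p + seq_len(p)])
  colnames(m) <- c("x", "y")
  m
}
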