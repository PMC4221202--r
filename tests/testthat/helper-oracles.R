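# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths (explicit loops, angle formulas, polynomial
# roots) so that agreement is evidence, not tautology.

random_config <- function(p, scale = 1) {
  matrix(stats::rnorm(2 * p, sd = scale), ncol = 2)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# closed-form angle minimising ||A %*% rot2(theta) - B||^2 (row-point
# convention): maximise tr(rot2(theta)' A'B) = den*cos + num*sin
oracle_rotation_angle <- function(a, b) {
  num <- sum(a[, 2] * b[, 1] - a[, 1] * b[, 2])
  den <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  atan2(num, den)
}

# brute-force rotation search refined to a 0.001-degree grid, objective
# evaluated pointwise rather than via the closed form
grid_rotation_angle <- function(a, b, step_deg = 0.001) {
  scan <- function(lo, hi, step) {
    th <- seq(lo, hi, by = step)
    obj <- vapply(th, function(t) sum((a %*% rot2(t) - b)^2), 1.0)
    th[which.min(obj)]
  }
  coarse <- scan(0, 2 * pi, 0.1 * pi / 180)
  fine <- step_deg * pi / 180
  scan(coarse - 0.2 * pi / 180, coarse + 0.2 * pi / 180, fine) %% (2 * pi)
}

# long-run alternating-optimisation GPA oracle: explicit loops, angle
# formula instead of SVD, run to a 1e-12 consensus displacement
oracle_gpa_consensus <- function(configs, tol = 1e-12, max_iter = 10000) {
  cfgs <- lapply(configs, function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  })
  ref <- cfgs[[1]]
  for (i in seq_along(cfgs)) {
    cfgs[[i]] <- cfgs[[i]] %*% rot2(oracle_rotation_angle(cfgs[[i]], ref))
  }
  mean_shape <- function(cfgs) {
    m <- Reduce(`+`, cfgs) / length(cfgs)
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  cons <- mean_shape(cfgs)
  for (it in seq_len(max_iter)) {
    for (i in seq_along(cfgs)) {
      cfgs[[i]] <- cfgs[[i]] %*% rot2(oracle_rotation_angle(cfgs[[i]], cons))
    }
    newc <- mean_shape(cfgs)
    delta <- newc %*% rot2(oracle_rotation_angle(newc, cons)) - cons
    cons <- newc
    if (sqrt(sum(delta^2)) < tol) break
  }
  cons
}

# eigenvalues of a symmetric 3x3 matrix as roots of its characteristic
# polynomial, via the invariant coefficients and polyroot()
charpoly_eigenvalues_3x3 <- function(m) {
  stopifnot(nrow(m) == 3, ncol(m) == 3)
  tr <- sum(diag(m))
  minors <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) +
            (m[1, 1] * m[3, 3] - m[1, 3] * m[3, 1]) +
            (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2])
  dt <- det(m)
  # lambda^3 - tr lambda^2 + minors lambda - det = 0
  sort(Re(polyroot(c(-dt, minors, -tr, 1))), decreasing = TRUE)
}

# dense piecewise-linear arc-length table for resampling checks
dense_arclength_points <- function(outline, targets, n_dense = 1e5) {
  seg <- sqrt(rowSums(diff(outline)^2))
  s <- c(0, cumsum(seg))
  tt <- seq(0, s[length(s)], length.out = n_dense)
  dx <- stats::approx(s, outline[, 1], xout = tt)$y
  dy <- stats::approx(s, outline[, 2], xout = tt)$y
  idx <- vapply(targets, function(g) which.min(abs(tt - g)), 1L)
  cbind(dx[idx], dy[idx])
}

# two Gaussian clusters in k dims with centroid gap `gap` (in sd units)
gaussian_clusters <- function(n_per, k, gap, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- c(gap, rep(0, k - 1))
  x <- rbind(matrix(rnorm(n_per * k), ncol = k),
             sweep(matrix(rnorm(n_per * k), ncol = k), 2, mu, `+`))
  list(scores = x, groups = rep(c("a", "b"), each = n_per))
}

# small aligned dataset for ordination/model tests
aligned_fixture <- function(n = 12, p = 20, seed = 42) {
  set.seed(seed)
  base <- template_outline(0.5, p = p)
  cfgs <- lapply(seq_len(n), function(i) {
    base + matrix(rnorm(2 * p, sd = 0.01), ncol = 2)
  })
  names(cfgs) <- sprintf("s%02d", seq_len(n))
  gpa(cfgs, tolerance = 1e-10)
}
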