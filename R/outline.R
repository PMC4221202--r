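#' Resample an outline to equally spaced semilandmarks
#'
#' Places `p` semilandmarks at equal arc-length intervals along an ordered
#' polyline, interpolating linearly between input vertices. For an open
#' curve both endpoints are retained (positions k*L/(p-1), k = 0..p-1); for
#' a closed curve the p positions are k*L/p starting at the first point,
#' with the closing segment back to point 1 included in the total length L.
#'
#' The first point is the homologous starting landmark (for snout profiles,
#' where the maxilla-premaxilla suture meets the left-lateral margin), so
#' correspondence of semilandmark indices across specimens follows from the
#' equal-spacing rule. No semilandmark sliding is performed.
#'
#' @param outline An m x 2 numeric matrix of ordered vertices (m >= 2, not
#'   all coincident).
#' @param p Number of semilandmarks (>= 3). Default 100.
#' @param closed Treat the outline as a closed contour. Default `FALSE`.
#' @return A p x 2 matrix of semilandmarks.
#' @export
resample_outline <- function(outline, p = 100L, closed = FALSE) {
  outline <- as.matrix(outline)
  if (ncol(outline) != 2L || nrow(outline) < 2L) {
    stop("outline must be an m x 2 matrix with m >= 2")
  }
  if (!all(is.finite(outline))) stop("outline has non-finite coordinates")
  if (p < 3L) stop("p must be >= 3")
  pts <- outline
  if (closed) pts <- rbind(pts, pts[1L, , drop = FALSE])
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (sum(seg) <= 0) stop("outline has zero total arc length")
  # drop zero-length segments so the arc-length parameter is strictly increasing
  keep <- c(TRUE, seg > 0)
  pts <- pts[keep, , drop = FALSE]
  s <- c(0, cumsum(seg[seg > 0]))
  L <- s[length(s)]
  target <- if (closed) L * (seq_len(p) - 1L) / p else L * (seq_len(p) - 1L) / (p - 1L)
  target <- pmin(pmax(target, 0), L)  # guard one-ulp overshoot
  out <- cbind(
    stats::approx(s, pts[, 1L], xout = target, method = "linear", ties = "ordered")$y,
    stats::approx(s, pts[, 2L], xout = target, method = "linear", ties = "ordered")$y
  )
  colnames(out) <- c("x", "y")
  out
}

#' Resample every specimen in a coordinate dataset
#'
#' @param dataset A `coord_dataset`.
#' @inheritParams resample_outline
#' @return A `coord_dataset` of p x 2 matrices.
#' @export
resample_dataset <- function(dataset, p = 100L, closed = FALSE) {
  out <- lapply(dataset, resample_outline, p = p, closed = closed)
  validate_coord_dataset(out)
}
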