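#' Model shapes along a principal component axis
#'
#' Back-projects five positions along one PC axis — the two observed score
#' extremes, the centre (0), and the two medial interpolants — into
#' landmark space: model(s) = mean_vector + s * eigenvector. Position 0 is
#' the consensus shape exactly.
#'
#' @param pca A `pca_model`.
#' @param axis Axis index (1-based, within the retained axes).
#' @param scores Optional score matrix supplying the observed range;
#'   defaults to the model's own training scores.
#' @return An `axis_model_series`: `axis` (label), `positions` (length 5),
#'   `model_shapes` (list of 5 p x 2 matrices).
#' @export
model_pc_axis <- function(pca, axis, scores = pca$scores) {
  if (axis < 1L || axis > ncol(pca$eigenvectors)) stop("axis out of range")
  s <- range(scores[, axis])
  positions <- c(s[1L], s[1L] / 2, 0, s[2L] / 2, s[2L])
  shapes <- lapply(positions, function(pos) {
    unflatten_config(pca$mean_vector + pos * pca$eigenvectors[, axis])
  })
  structure(list(axis = paste0("PC", axis), positions = positions,
                 model_shapes = shapes),
            class = "axis_model_series")
}

#' Model shapes along the canonical variates axis
#'
#' Five positions along CV-1 (extremes, centre, medial interpolants of the
#' observed cv scores) are mapped back into PC space — a cv position c
#' corresponds to the PC-space point `grand_mean + c * v / (v'v)`, the
#' inverse of the discriminant projection — and then through the PCA
#' eigenvectors into landmark space. Position 0 reconstructs the grand
#' mean shape.
#'
#' @param cva A `cva_model` fitted on scores from `pca`.
#' @param pca The `pca_model` defining the landmark back-projection.
#' @param cv_scores Optional cv scores supplying the observed range;
#'   defaults to the model's own.
#' @return An `axis_model_series` for axis `"CV1"`.
#' @export
model_cv_axis <- function(cva, pca, cv_scores = cva$cv_scores) {
  s <- range(cv_scores)
  positions <- c(s[1L], s[1L] / 2, 0, s[2L] / 2, s[2L])
  v <- cva$discriminant_vector
  d <- v / sum(v^2)  # cva_transform(grand_mean + c*d) == c
  shapes <- lapply(positions, function(pos) {
    pc_point <- cva$grand_mean + pos * d
    flat <- pca$mean_vector +
      as.numeric(pca$eigenvectors[, seq_len(cva$k), drop = FALSE] %*% pc_point)
    unflatten_config(flat)
  })
  structure(list(axis = "CV1", positions = positions, model_shapes = shapes),
            class = "axis_model_series")
}

#' Strobe (overlay) plot of an axis model series
#'
#' Writes an SVG overlay of the model outlines, colour-graded from the
#' negative (blue) to the positive (red) end of the axis. The SVG is
#' emitted by a small deterministic writer (one `<polyline>` per model),
#' so identical input yields byte-identical output and the file structure
#' can be checked programmatically.
#'
#' @param series An `axis_model_series`.
#' @param path Output path (`.svg`).
#' @param width,height Canvas size in pixels.
#' @return `path`, invisibly.
#' @export
strobe_plot <- function(series, path, width = 480, height = 480) {
  shapes <- series$model_shapes
  n <- length(shapes)
  all_pts <- do.call(rbind, shapes)
  rng_x <- range(all_pts[, 1L]); rng_y <- range(all_pts[, 2L])
  span <- max(rng_x[2L] - rng_x[1L], rng_y[2L] - rng_y[1L], .Machine$double.eps)
  pad <- 20
  sc <- (min(width, height) - 2 * pad) / span
  to_px <- function(m) {
    cbind(pad + (m[, 1L] - rng_x[1L]) * sc,
          height - pad - (m[, 2L] - rng_y[1L]) * sc)  # y up -> SVG y down
  }
  ramp <- grDevices::colorRampPalette(c("#2166ac", "#999999", "#b2182b"))(n)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write strobe plot to ", path))
  on.exit(close(con))
  writeLines(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height), con)
  writeLines(sprintf('<title>%s axis models</title>', series$axis), con)
  for (i in seq_len(n)) {
    px <- to_px(shapes[[i]])
    writeLines(sprintf('<polyline fill="none" stroke="%s" stroke-width="1.5" points="%s"/>',
                       ramp[i],
                       paste(sprintf("%.3f,%.3f", px[, 1L], px[, 2L]), collapse = " ")),
               con)
  }
  writeLines("</svg>", con)
  invisible(path)
}
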