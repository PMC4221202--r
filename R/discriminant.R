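#' Two-group canonical variates analysis of shape scores
#'
#' Fits the single discriminant axis separating two a-priori groups in a
#' k-dimensional score space. With W the pooled within-group SSCP and B the
#' between-group SSCP, the discriminant vector is the leading eigenvector
#' of \eqn{W^{-1}B}, scaled so the pooled within-group variance of the
#' projected scores is 1 (so distances along the axis are Mahalanobis
#' distances). Group distinctiveness is summarised by Wilks'
#' \eqn{\Lambda = \det W / \det(W + B)} and the log-likelihood-ratio index
#' \eqn{\varphi = -(n - 1 - (k + g)/2)\,\ln\Lambda} (Bartlett's form,
#' g = 2 groups), referred to a chi-squared distribution with k degrees of
#' freedom. The unscaled variant \eqn{-n \ln\Lambda} is available via
#' `phi_form`.
#'
#' @param scores An n x k numeric matrix of ordination scores.
#' @param groups Length-n vector with exactly two distinct labels, each
#'   occurring at least twice.
#' @param phi_form `"bartlett"` (default) or `"unscaled"`.
#' @return An object of class `cva_model`: `discriminant_vector` (length
#'   k), `cv_scores` (length n, grand-mean centred), `centroids` (named
#'   length-2), `group_ranges` (2 x 2, observed cv range per group),
#'   `wilks_lambda`, `phi`, `p_chi2`, `grand_mean`, `groups`, `n`, `k`.
#' @export
cva_fit <- function(scores, groups, phi_form = c("bartlett", "unscaled")) {
  phi_form <- match.arg(phi_form)
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups are required")
  n <- nrow(scores); k <- ncol(scores); g <- 2L
  if (any(table(groups) < 2L)) stop("each group needs >= 2 members")
  if (n < k + 2L) stop("too few specimens for ", k, " score axes")
  grand <- colMeans(scores)
  W <- matrix(0, k, k); B <- matrix(0, k, k)
  for (lv in lev) {
    xs <- scores[groups == lv, , drop = FALSE]
    mu <- colMeans(xs)
    W <- W + crossprod(sweep(xs, 2L, mu))
    B <- B + nrow(xs) * tcrossprod(mu - grand)
  }
  detW <- det(W)
  if (!is.finite(detW) || detW <= 0) {
    stop("singular within-group SSCP; retain fewer score axes")
  }
  lambda <- detW / det(W + B)
  phi <- if (phi_form == "bartlett") {
    -(n - 1 - (k + g) / 2) * log(lambda)
  } else {
    -n * log(lambda)
  }
  p_chi2 <- stats::pchisq(phi, df = k * (g - 1L), lower.tail = FALSE)
  v <- solve(W, colMeans(scores[groups == lev[1L], , drop = FALSE]) -
                  colMeans(scores[groups == lev[2L], , drop = FALSE]))
  # unit pooled within-group variance along the axis
  v <- v / sqrt(as.numeric(t(v) %*% W %*% v) / (n - g))
  cv <- as.numeric(sweep(scores, 2L, grand) %*% v)
  names(cv) <- rownames(scores)
  centroids <- vapply(lev, function(lv) mean(cv[groups == lv]), 1.0)
  ranges <- t(vapply(lev, function(lv) range(cv[groups == lv]), numeric(2L)))
  colnames(ranges) <- c("min", "max")
  structure(list(discriminant_vector = v, cv_scores = cv,
                 centroids = centroids, group_ranges = ranges,
                 wilks_lambda = lambda, phi = phi, p_chi2 = p_chi2,
                 grand_mean = grand, groups = groups, levels = lev,
                 n = n, k = k, phi_form = phi_form),
            class = "cva_model")
}

cva_transform <- function(model, scores) {
  scores <- rbind(scores)
  if (ncol(scores) != model$k) stop("dimension mismatch")
  as.numeric(sweep(scores, 2L, model$grand_mean) %*% model$discriminant_vector)
}

#' Nearest-centroid classification in the canonical variates space
#'
#' Projects score rows onto the fitted discriminant axis and assigns each
#' to the group whose centroid is nearer (1-D Euclidean distance, equal to
#' Mahalanobis distance under the model's unit-within-variance scaling).
#' Exact ties go to the alphabetically first group and are flagged.
#'
#' @param model A `cva_model`.
#' @param scores An n x k score matrix.
#' @param groups Optional true labels; when given, a confusion matrix and
#'   percent-correct summary are attached.
#' @return A list with `assignments` (data.frame: id, cv_score, distances
#'   to each centroid, assigned, tie flag) and, when `groups` is supplied,
#'   `confusion` (a `confusion_matrix`).
#' @export
cva_classify <- function(model, scores, groups = NULL) {
  scores <- rbind(scores)
  cv <- cva_transform(model, scores)
  d <- abs(outer(cv, model$centroids, `-`))
  tie <- abs(d[, 1L] - d[, 2L]) < 1e-12
  assigned <- model$levels[max.col(-d, ties.method = "first")]
  out <- data.frame(id = rownames(scores) %||% seq_along(cv),
                    cv_score = cv,
                    stringsAsFactors = FALSE)
  out[[paste0("dist_", model$levels[1L])]] <- d[, 1L]
  out[[paste0("dist_", model$levels[2L])]] <- d[, 2L]
  out$assigned <- assigned
  out$tie <- tie
  res <- list(assignments = out)
  if (!is.null(groups)) {
    res$confusion <- confusion_matrix(as.character(groups), assigned, model$levels)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

confusion_matrix <- function(truth, assigned, levels) {
  tab <- table(factor(truth, levels = levels), factor(assigned, levels = levels),
               dnn = c("true", "assigned"))
  n <- sum(tab)
  correct <- sum(diag(tab))
  structure(list(counts = tab, n = n, n_correct = correct,
                 percent_correct = 100 * correct / n),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  cat(sprintf("correct: %d / %d (%.2f%%)\n", x$n_correct, x$n, x$percent_correct))
  invisible(x)
}

#' Jackknifed (leave-one-out) cross-validation of the CVA
#'
#' For each specimen, refits the CVA on the remaining n - 1 specimens and
#' classifies the holdout by nearest centroid; aggregates into a confusion
#' matrix. Reports both the rate and its exact fraction.
#'
#' @inheritParams cva_fit
#' @return A `confusion_matrix` with an extra element `assignments`.
#' @export
cva_jackknife <- function(scores, groups, phi_form = c("bartlett", "unscaled")) {
  phi_form <- match.arg(phi_form)
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  if (any(table(groups) < 3L)) stop("each group needs >= 3 members for the jackknife")
  n <- nrow(scores)
  assigned <- character(n)
  for (i in seq_len(n)) {
    fit <- cva_fit(scores[-i, , drop = FALSE], groups[-i], phi_form = phi_form)
    assigned[i] <- cva_classify(fit, scores[i, , drop = FALSE])$assignments$assigned
  }
  cm <- confusion_matrix(groups, assigned, sort(unique(groups)))
  cm$assignments <- data.frame(id = rownames(scores) %||% seq_len(n),
                               true = groups, assigned = assigned,
                               stringsAsFactors = FALSE)
  cm
}

null_summary <- function(phi_null, phi_obs, R, mode) {
  count <- sum(phi_null >= phi_obs)
  structure(list(phi_values = phi_null, phi_observed = phi_obs,
                 p_value = count / R,
                 p_conservative = (count + 1) / (R + 1),
                 R = R, mode = mode),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("%s null: R = %d, observed phi = %.4f, p = %.4g (conservative %.4g)\n",
              x$mode, x$R, x$phi_observed, x$p_value, x$p_conservative))
  invisible(x)
}

#' Monte Carlo null distribution for the phi statistic
#'
#' Builds R pseudo-replicate datasets in which every score column is drawn
#' iid from a normal distribution with the pooled (group-blind) mean and
#' variance of that column, keeps the observed group sizes as labels, fits
#' the CVA and records phi. The resulting distribution is the expectation
#' of phi under no group difference beyond sampling error, guarding
#' against hyper-dimensionality artefacts.
#'
#' @inheritParams cva_fit
#' @param R Number of pseudo-replicates (default 1000).
#' @param seed Integer seed for reproducibility (optional).
#' @return A `null_distribution`: `phi_values`, `phi_observed`, `p_value`
#'   (= count of null phi >= observed, / R), `p_conservative`
#'   (= (count + 1)/(R + 1)), `R`, `mode`.
#' @export
null_montecarlo <- function(scores, groups, R = 1000L, seed = NULL,
                            phi_form = c("bartlett", "unscaled")) {
  phi_form <- match.arg(phi_form)
  scores <- as.matrix(scores)
  if (R < 1L) stop("R must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- cva_fit(scores, groups, phi_form = phi_form)$phi
  n <- nrow(scores); k <- ncol(scores)
  mu <- colMeans(scores)
  sd_ <- apply(scores, 2L, stats::sd)
  g_null <- rep(sort(unique(as.character(groups))),
                times = table(as.character(groups)))
  phi_null <- vapply(seq_len(R), function(r) {
    x <- sweep(sweep(matrix(stats::rnorm(n * k), n, k), 2L, sd_, `*`), 2L, mu, `+`)
    cva_fit(x, g_null, phi_form = phi_form)$phi
  }, 1.0)
  null_summary(phi_null, obs, R, "montecarlo")
}

#' Bootstrap null distribution for the phi statistic
#'
#' Destroys the observed group structure by resampling n score rows with
#' replacement from the pooled observed rows and assigning the first n1 to
#' group 1 and the rest to group 2 (a random agglomeration with the
#' observed group sample sizes and variables), then fits the CVA and
#' records phi for each of R pseudo-replicates. `permute = TRUE` gives the
#' without-replacement label-permutation variant.
#'
#' @inheritParams null_montecarlo
#' @param permute Resample without replacement (label permutation).
#' @return A `null_distribution` (mode `"bootstrap"`).
#' @export
null_bootstrap <- function(scores, groups, R = 1000L, seed = NULL,
                           permute = FALSE,
                           phi_form = c("bartlett", "unscaled")) {
  phi_form <- match.arg(phi_form)
  scores <- as.matrix(scores)
  if (R < 1L) stop("R must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- cva_fit(scores, groups, phi_form = phi_form)$phi
  n <- nrow(scores)
  g_null <- rep(sort(unique(as.character(groups))),
                times = table(as.character(groups)))
  phi_null <- vapply(seq_len(R), function(r) {
    idx <- if (permute) sample.int(n) else sample.int(n, replace = TRUE)
    cva_fit(scores[idx, , drop = FALSE], g_null, phi_form = phi_form)$phi
  }, 1.0)
  null_summary(phi_null, obs, R, "bootstrap")
}

#' Project unknown specimens into a fitted discriminant space
#'
#' Routes aligned configurations of specimens of unknown group through the
#' PCA (`pca_project`) and the CVA axis, assigns each to the nearer group
#' centroid, reports the distance to both centroids, and flags specimens
#' whose cv score falls outside the observed cv range of both training
#' groups (assignments that cannot be justified by proximity to either
#' occupied region).
#'
#' @param model A `cva_model` fitted on the training scores.
#' @param pca The `pca_model` those scores came from.
#' @param aligned_unknowns Named list of p x 2 configurations already
#'   aligned into the training consensus frame (see [gpa_align_to()]).
#' @return A data.frame: id, cv_score, distances, assigned, outside_range.
#' @export
project_unknowns <- function(model, pca, aligned_unknowns) {
  scores <- pca_project(pca, aligned_unknowns)[, seq_len(model$k), drop = FALSE]
  res <- cva_classify(model, scores)$assignments
  res$outside_range <- res$cv_score < min(model$group_ranges[, "min"]) |
                       res$cv_score > max(model$group_ranges[, "max"])
  res
}
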