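# Analytic end-member templates for a ventral snout (premaxilla) profile.
# Both are open curves running from the left maxilla-premaxilla suture
# point, up the left lateral margin, across the distal (anterior) end, and
# down the right margin; x is mediolateral (midline at 0), y axial with
# anterior up. The blunt end member is slightly wider than long with a
# distal medial concavity and posteriorly diverging margins; the pointed
# end member is elongate (about twice as long as wide) with a convex
# distal end and a medial compression of the lateral margins.
template_dense <- function(s, m = 400L) {
  t <- seq(0, 1, length.out = m)
  margin <- function(w, h) cbind(x = w, y = h * t)
  cap <- function(wtip, h, d, m2 = 160L) {
    xx <- seq(-wtip, wtip, length.out = m2)
    cbind(x = xx, y = h + d * cos(pi * xx / (2 * wtip)))
  }
  build <- function(w, h, d) {
    left <- margin(-rev(w), h)[m:1, , drop = FALSE]   # ascend from posterior
    left <- margin(-w, h)
    right <- margin(w, h)[m:1, , drop = FALSE]
    rbind(left, cap(w[m], h, d)[-c(1L, 160L), , drop = FALSE], right)
  }
  # blunt: wide, short, margins diverge posteriorly, concave distal end
  w_blunt <- 0.55 - 0.12 * t
  blunt <- build(w_blunt, 0.9, -0.10)
  # pointed: narrow, elongate, mid-margin compression, convex distal end
  w_point <- (0.34 - 0.07 * sin(pi * t)) * (1 - 0.55 * t)
  pointed <- build(w_point, 2.0, 0.22)
  (1 - s) * blunt + s * pointed
}

#' Synthetic snout-profile template on a blunt-to-pointed continuum
#'
#' Deterministic bilaterally symmetric open outline interpolating between
#' a blunt, wide end member (s = 0) and a pointed, elongate end member
#' (s = 1), resampled to p equally spaced semilandmarks. The two end
#' members emulate the grazer-like and browser-like extremes of the snout
#' shape continuum.
#'
#' @param s Shape-blend parameter in [0, 1].
#' @param p Number of semilandmarks (default 100).
#' @return A p x 2 semilandmark matrix.
#' @export
template_outline <- function(s, p = 100L) {
  if (!is.finite(s) || s < 0 || s > 1) stop("s must be in [0, 1]")
  resample_outline(template_dense(s), p = p, closed = FALSE)
}

# deterministic per-purpose sub-seeds derived from one master seed
derive_seed <- function(seed, stream) {
  (seed * 48271 + stream * 1009) %% 2147483647
}

#' Default configuration for the synthetic two-guild study
#'
#' The defaults define the simulated study conditions: 30 browsers and 30
#' grazers on the s-continuum (group means 0.8 and 0.2, within-group sd
#' 0.1, partially overlapping), 20 unknowns drawn from a uniform mixture
#' of the two guilds, coordinate noise of 1 percent of the outline scale,
#' nuisance rotation/scale/translation on every specimen, 100
#' semilandmarks, and an allometric log-mass slope along the continuum.
#'
#' @param n_browser,n_grazer,n_unknown Group sizes.
#' @param s_browser_mean,s_grazer_mean Group means of the blend parameter.
#' @param s_sd Within-group sd of the blend parameter.
#' @param noise_sd Coordinate noise sd as a fraction of outline scale.
#' @param p Semilandmarks per outline.
#' @param allometry_slope Slope of log mass on s (browsers being more
#'   pointed and typically smaller, the default is negative).
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `outline_gen_config`.
#' @export
study_config <- function(n_browser = 30L, n_grazer = 30L, n_unknown = 20L,
                         s_browser_mean = 0.8, s_grazer_mean = 0.2,
                         s_sd = 0.1, noise_sd = 0.01, p = 100L,
                         allometry_slope = -1.5, seed = 1L) {
  cfg <- list(n_browser = n_browser, n_grazer = n_grazer,
              n_unknown = n_unknown,
              s_browser_mean = s_browser_mean, s_grazer_mean = s_grazer_mean,
              s_sd = s_sd, noise_sd = noise_sd, p = p,
              allometry_slope = allometry_slope, seed = seed)
  stopifnot(n_browser >= 0, n_grazer >= 0, n_unknown >= 0,
            s_browser_mean >= 0, s_browser_mean <= 1,
            s_grazer_mean >= 0, s_grazer_mean <= 1,
            s_sd >= 0, noise_sd >= 0, p >= 3)
  structure(cfg, class = "outline_gen_config")
}

rtrunc_norm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  pmin(1, pmax(0, stats::rnorm(n, mean, sd)))
}

#' Generate a complete synthetic study
#'
#' Produces outline coordinates, a trait table and an ultrametric Yule
#' phylogeny for a two-guild study. Per specimen: the blend parameter s is
#' drawn from the guild's truncated normal; the template outline receives
#' iid Gaussian coordinate noise scaled by the outline size, then a random
#' rotation (uniform on the circle), log-normal scaling and translation —
#' nuisance transforms the Procrustes stage must remove. Body mass (grams)
#' is log-linear in s with noise. Unknowns draw their guild uniformly. All
#' true parameters are recorded for recovery tests.
#'
#' @param config An `outline_gen_config` from [study_config()].
#' @return A list of class `simulated_study`: `dataset` (`coord_dataset`),
#'   `traits` (data.frame), `tree` (`phylo`), `true_parameters`
#'   (config plus per-specimen true s and true guild).
#' @export
generate_study <- function(config = study_config()) {
  set.seed(derive_seed(config$seed, 1L))
  n_b <- config$n_browser; n_g <- config$n_grazer; n_u <- config$n_unknown
  n <- n_b + n_g + n_u
  ids <- sprintf("sp_%03d", seq_len(n))
  cls <- c(rep("browser", n_b), rep("grazer", n_g), rep("unknown", n_u))
  true_guild <- cls
  if (n_u > 0L) {
    true_guild[cls == "unknown"] <- sample(c("browser", "grazer"), n_u, replace = TRUE)
  }
  mean_of <- c(browser = config$s_browser_mean, grazer = config$s_grazer_mean)
  s <- rtrunc_norm01(n, mean_of[true_guild], config$s_sd)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    shp <- template_outline(s[i], p = config$p)
    scale0 <- max(apply(shp, 2L, function(z) diff(range(z))))
    shp <- shp + matrix(stats::rnorm(2L * config$p, 0, config$noise_sd * scale0),
                        ncol = 2L)
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    shp <- shp %*% R * stats::rlnorm(1, 0, 0.2)
    shp <- sweep(shp, 2L, stats::rnorm(2L, 0, 5), `+`)
    colnames(shp) <- c("x", "y")
    specs[[i]] <- shp
  }
  names(specs) <- ids
  # grams: ~1e5 g baseline, log-linear in s
  mass <- exp(log(1e5) + config$allometry_slope * s + stats::rnorm(n, 0, 0.3))
  traits <- data.frame(species = ids, feeding_class = cls,
                       body_mass_g = mass, stringsAsFactors = FALSE)
  set.seed(derive_seed(config$seed, 2L))
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- ids
  structure(list(dataset = validate_coord_dataset(specs),
                 traits = traits, tree = tree,
                 true_parameters = c(unclass(config),
                                     list(s = stats::setNames(s, ids),
                                          true_guild = stats::setNames(true_guild, ids)))),
            class = "simulated_study")
}

#' Simulate a Yule tree with a Brownian-motion trait
#'
#' Pure-birth (Yule) tree with exactly `n_tips` tips, ultrametric, with a
#' continuous trait evolved along its branches under Brownian motion with
#' rate `sigma2` from `root_value`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (default 1; affects branch scale only).
#' @param sigma2 Brownian variance rate.
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed.
#' @return List with `tree` (`phylo`) and `trait` (named vector over tips).
#' @export
simulate_tree_bm <- function(n_tips, birth_rate = 1, sigma2 = 1,
                             root_value = 0, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  trait <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2),
                           root.value = root_value)
  list(tree = tree, trait = trait)
}

#' Write a simulated study to the three standard input files
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed). Writes
#'   `coordinates.txt` (block-text), `traits.csv`, `tree.nwk`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_coordinates(study$dataset, file.path(dir, "coordinates.txt"))
  utils::write.csv(study$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
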