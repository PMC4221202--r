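#' Run the complete snout-shape analysis pipeline
#'
#' Orchestrates the full workflow on a coordinate dataset, trait table and
#' optional tree: equal arc-length resampling, generalized Procrustes
#' superimposition of all specimens, covariance-based (or phylogenetic)
#' PCA fitted on the browser/grazer training specimens, two-group
#' canonical variates analysis with Monte Carlo and bootstrap phi nulls,
#' resubstitution and jackknifed classification, projection of unknown
#' specimens, back-projected shape model series, and — when a tree and
#' body mass are available — the phylogenetic-signal suite (Blomberg's K
#' and Pagel's lambda on the mass-residualised PC scores, independent
#' contrasts of the PC scores against log mass).
#'
#' The raw and phylogenetically controlled runs share every stage except
#' the ordination step (`phylo = TRUE` swaps [pca_fit()] for
#' [phylo_pca_fit()] on the tree pruned to the training specimens).
#'
#' @param dataset A `coord_dataset` (or a `simulated_study`, in which case
#'   `traits`/`tree` default to its members).
#' @param traits Trait table with `species`, `feeding_class`, optionally
#'   `body_mass_g`.
#' @param tree Optional `phylo` tree.
#' @param p Semilandmarks per outline (default 100).
#' @param gpa_tol GPA convergence tolerance (default 1e-4).
#' @param k Retained PC axes for the CVA (default 3).
#' @param R Null-distribution pseudo-replicates (default 1000).
#' @param seed Master seed for the stochastic stages.
#' @param phylo Use the phylogenetically controlled ordination.
#' @param signal_permutations Permutations for the K test (default 999).
#' @param out_dir Optional directory: writes scores, assignments,
#'   confusion matrices, a JSON-like summary and SVG strobe plots.
#' @return A list of class `snout_run` with elements `gpa`, `pca`, `cva`,
#'   `null_mc`, `null_boot`, `confusion`, `jackknife`, `unknowns`,
#'   `pc_models`, `cv_model`, `signal`, `summary`.
#' @export
run_pipeline <- function(dataset, traits = NULL, tree = NULL, p = 100L,
                         gpa_tol = 1e-4, k = 3L, R = 1000L, seed = 1L,
                         phylo = FALSE, signal_permutations = 999L,
                         out_dir = NULL) {
  if (inherits(dataset, "simulated_study")) {
    if (is.null(traits)) traits <- dataset$traits
    if (is.null(tree)) tree <- dataset$tree
    dataset <- dataset$dataset
  }
  if (is.null(traits)) stop("a trait table is required")
  if (phylo && is.null(tree)) stop("phylo = TRUE requires a tree")
  rec <- reconcile(dataset, traits, tree)
  dataset <- rec$dataset; traits <- rec$traits; tree <- rec$tree

  dataset <- resample_dataset(dataset, p = p)
  fit <- gpa(dataset, tolerance = gpa_tol)

  known <- traits$species[traits$feeding_class %in% c("browser", "grazer")]
  unknown <- setdiff(traits$species, known)
  groups <- stats::setNames(traits$feeding_class, traits$species)[known]
  if (length(unique(groups)) != 2L) stop("need both browser and grazer specimens")

  known_cfgs <- fit$configs[known]
  pca <- if (phylo) {
    phylo_pca_fit(known_cfgs, ape::keep.tip(tree, known))
  } else {
    pca_fit(known_cfgs)
  }
  kk <- min(k, ncol(pca$scores))
  scores <- pca$scores[, seq_len(kk), drop = FALSE]

  cva <- cva_fit(scores, groups)
  null_mc <- null_montecarlo(scores, groups, R = R, seed = derive_seed(seed, 11L))
  null_boot <- null_bootstrap(scores, groups, R = R, seed = derive_seed(seed, 12L))
  cls <- cva_classify(cva, scores, groups)
  jk <- cva_jackknife(scores, groups)

  unknowns <- NULL
  if (length(unknown) > 0L) {
    unknowns <- project_unknowns(cva, pca, fit$configs[unknown])
  }

  pc_models <- lapply(seq_len(kk), function(a) model_pc_axis(pca, a, scores))
  cv_model <- model_cv_axis(cva, pca)

  signal <- NULL
  if (!is.null(tree) && "body_mass_g" %in% names(traits)) {
    signal <- signal_suite(pca, traits, tree, known,
                           permutations = signal_permutations,
                           seed = derive_seed(seed, 13L))
  }

  summary <- list(
    n = length(dataset), n_known = length(known), n_unknown = length(unknown),
    p = p, k = kk, phylo = phylo,
    gpa_iterations = fit$iterations,
    variance_fraction = pca$variance_fraction[seq_len(kk)],
    variance_pct_retained = 100 * sum(pca$variance_fraction[seq_len(kk)]),
    wilks_lambda = cva$wilks_lambda, phi = cva$phi, p_chi2 = cva$p_chi2,
    p_mc = null_mc$p_value, p_boot = null_boot$p_value,
    pct_correct = cls$confusion$percent_correct,
    pct_correct_jackknife = jk$percent_correct,
    unknown_assignments = if (is.null(unknowns)) NULL else table(unknowns$assigned)
  )

  run <- structure(list(gpa = fit, pca = pca, cva = cva,
                        null_mc = null_mc, null_boot = null_boot,
                        confusion = cls$confusion, jackknife = jk,
                        unknowns = unknowns, pc_models = pc_models,
                        cv_model = cv_model, signal = signal,
                        traits = traits, summary = summary),
                   class = "snout_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# K / lambda on mass-residualised PC scores + contrasts vs log mass
signal_suite <- function(pca, traits, tree, known, permutations = 999L,
                         seed = NULL) {
  mass <- stats::setNames(traits$body_mass_g, traits$species)
  mass <- mass[known]
  tr_known <- ape::keep.tip(tree, known)
  out <- list()
  for (axis in 1:2) {
    if (axis > ncol(pca$scores)) break
    sc <- stats::setNames(pca$scores[known, axis], known)
    res <- mass_residuals(sc, mass)
    kb <- blomberg_k(res, tr_known, permutations = permutations, seed = seed)
    pl <- pagel_lambda(res, tr_known)
    c_sc <- independent_contrasts(sc, tr_known)
    c_m <- independent_contrasts(log10(mass[tr_known$tip.label]), tr_known)
    out[[paste0("PC", axis)]] <- list(
      K = kb$K, p_K = kb$p_K,
      lambda = pl$lambda, logL = pl$logL, p_lambda = pl$p_lambda,
      spearman = contrast_correlation(c_m, c_sc, "spearman"),
      kendall = contrast_correlation(c_m, c_sc, "kendall"))
  }
  out
}

fmt12 <- function(x) formatC(x, digits = 12, format = "g")

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- run$pca$scores
  utils::write.csv(data.frame(species = rownames(sc),
                              apply(sc, 2L, fmt12),
                              check.names = FALSE),
                   file.path(dir, "pc_scores.csv"), row.names = FALSE, quote = FALSE)
  cvdf <- data.frame(species = names(run$cva$cv_scores),
                     cv1 = fmt12(run$cva$cv_scores),
                     group = run$cva$groups)
  utils::write.csv(cvdf, file.path(dir, "cv_scores.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(run$unknowns)) {
    utils::write.csv(run$unknowns, file.path(dir, "unknown_assignments.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  for (i in seq_along(run$pc_models)) {
    strobe_plot(run$pc_models[[i]], file.path(dir, sprintf("strobe_pc%d.svg", i)))
  }
  strobe_plot(run$cv_model, file.path(dir, "strobe_cv1.svg"))
  s <- run$summary
  s$unknown_assignments <- as.list(s$unknown_assignments)
  txt <- vapply(names(s), function(nm) {
    val <- s[[nm]]
    paste0(nm, ": ", paste(unlist(val), collapse = " "))
  }, "")
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}
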