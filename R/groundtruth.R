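#' Generate category signal templates
#'
#' One unit-norm voxel vector per category, with pairwise absolute cosine
#' similarity below \code{max_abs_cos}. With \code{max_abs_cos = 0} the
#' templates are signed canonical basis vectors (exact orthogonality).
#'
#' @param n_voxels voxels per template (at least the number of categories).
#' @param categories category labels.
#' @param seed integer seed.
#' @param max_abs_cos upper bound on pairwise |cosine| (default 0.2).
#' @param max_tries retry budget for the rejection draw.
#' @return matrix (categories x voxels) with category row names.
#' @export
make_templates <- function(n_voxels, categories, seed = 1L,
                           max_abs_cos = 0.2, max_tries = 1000L) {
  k <- length(categories)
  if (n_voxels < k) stop("n_voxels must be >= number of categories")
  set.seed(seed)
  if (max_abs_cos == 0) {
    tm <- matrix(0, k, n_voxels)
    tm[cbind(seq_len(k), seq_len(k))] <- sample(c(-1, 1), k, replace = TRUE)
    rownames(tm) <- categories
    return(tm)
  }
  for (i in seq_len(max_tries)) {
    tm <- matrix(stats::rnorm(k * n_voxels), k, n_voxels)
    tm <- tm / sqrt(rowSums(tm^2))
    g <- tcrossprod(tm)
    if (max(abs(g[upper.tri(g)])) < max_abs_cos) {
      rownames(tm) <- categories
      return(tm)
    }
  }
  stop(sprintf(
    "template generation failed: |cos| < %.3g unattainable in %d tries for %d voxels",
    max_abs_cos, max_tries, n_voxels))
}

#' Default generative plasticity curve
#'
#' A theory-consistent (U-shaped) curve mapping normalized updating-phase
#' competitor reactivation to the change in competitor signal at final test:
#' mild reactivation leaves memory near baseline, moderate reactivation
#' weakens it, strong reactivation strengthens it.
#'
#' @return a \code{\link{pcit_curve}}.
#' @export
default_plasticity_curve <- function() {
  pcit_curve(c(0, 0.3, 0.7, 1), c(0.2, -0.5, -0.2, 0.6))
}

#' Default behavioral response model
#'
#' Per-condition multinomial response probabilities over
#' \{target, competitor, other, dontknow\} for each updating repetition, and a
#' single multinomial per condition for the final test. RetPrac retrieval
#' starts near the 1/3 chance level and improves steeply across repetitions;
#' Restudy category judgments are correct with probability 0.99. Final-test
#' probabilities favor targets under RetPrac and show more competitor
#' intrusions under Restudy.
#'
#' @return nested list: \code{updating$RetPrac} / \code{updating$Restudy}
#'   (repetition x outcome matrices) and \code{test$RetPrac} /
#'   \code{test$Restudy} (named probability vectors).
#' @export
default_behavior_params <- function() {
  outc <- c("target", "competitor", "other", "dontknow")
  rp <- rbind(c(0.35, 0.25, 0.25, 0.15),
              c(0.65, 0.15, 0.12, 0.08),
              c(0.85, 0.06, 0.05, 0.04))
  rs <- matrix(rep(c(0.99, 0.004, 0.003, 0.003), 3), 3, byrow = TRUE)
  colnames(rp) <- colnames(rs) <- outc
  list(
    updating = list(RetPrac = rp, Restudy = rs),
    test = list(
      RetPrac = stats::setNames(c(0.55, 0.20, 0.15, 0.10), outc),
      Restudy = stats::setNames(c(0.45, 0.28, 0.17, 0.10), outc)
    )
  )
}

#' Assemble the generative ground truth for one synthetic subject
#'
#' Bundles the category templates, the generative plasticity curve, the
#' trial-level reactivation mixing coefficients, and per-pair ROI activation
#' values with a known activation-outcome coupling.
#'
#' Coefficients: each pair draws a base competitor coefficient from its
#' condition's Gaussian (RetPrac mean above Restudy's), clipped at zero, used
#' for all updating repetitions. Updating target coefficients are drawn per
#' trial; when \code{behavior} is supplied and
#' \code{params$subsequent_memory_boost > 0}, pairs answered correctly at the
#' final test get a higher updating target mean (the generative
#' subsequent-memory effect). Test-phase competitor coefficients equal the
#' updating coefficient plus the plasticity curve evaluated at the coefficient
#' min-max-normalized over pairs, clipped at zero.
#'
#' Activations: one scalar per pair and repetition, standing in for per-item
#' GLM betas: \code{act = intercept + coupling * (test target coefficient -
#' test competitor coefficient) + noise}.
#'
#' @param config a \code{\link{experiment_config}}.
#' @param pairs output of \code{\link{make_pairs}}.
#' @param behavior optional output of \code{\link{simulate_behavior}} (used
#'   for the subsequent-memory coupling).
#' @param seed integer seed.
#' @param params list of generative parameters; see
#'   \code{default_coefficient_params}.
#' @param plasticity_curve generative curve (default
#'   \code{\link{default_plasticity_curve}}); pass a constant-zero curve to
#'   switch the updating-to-test coupling off.
#' @return list of class \code{memupdate_ground_truth}.
#' @export
make_ground_truth <- function(config, pairs, behavior = NULL, seed = 1L,
                              params = default_coefficient_params(),
                              plasticity_curve = default_plasticity_curve()) {
  seeds <- child_seeds(seed, c("templates", "coef", "act"))
  templates <- make_templates(config$n_voxels, config$categories,
                              seed = seeds[["templates"]])
  set.seed(seeds[["coef"]])
  n <- nrow(pairs)
  comp_base <- pmax(0, stats::rnorm(
    n,
    mean = ifelse(pairs$condition == "RetPrac",
                  params$comp_upd_mean["RetPrac"],
                  params$comp_upd_mean["Restudy"]),
    sd = params$comp_upd_sd))
  correct_final <- rep(FALSE, n)
  if (!is.null(behavior) && params$subsequent_memory_boost != 0) {
    tst <- behavior[behavior$phase == "test", ]
    correct_final <- pairs$pair_id %in% tst$pair_id[tst$outcome == "target"]
  }
  reps <- config$n_repetitions
  upd_target <- matrix(pmax(0, stats::rnorm(
    n * reps,
    mean = params$target_upd_mean +
      params$subsequent_memory_boost * rep(correct_final, reps),
    sd = params$target_upd_sd)), n, reps)
  test_target <- pmax(0, stats::rnorm(n, params$target_test_mean,
                                      params$target_test_sd))
  x_norm <- if (max(comp_base) > min(comp_base)) {
    normalize_x(comp_base)
  } else rep(0.5, n)
  test_comp <- pmax(0, comp_base + curve_value(plasticity_curve, x_norm))
  coefficients <- data.frame(
    pair_id = pairs$pair_id, condition = pairs$condition,
    comp_upd = comp_base, comp_upd_norm = x_norm,
    test_target = test_target, test_comp = test_comp,
    correct_final = correct_final, stringsAsFactors = FALSE
  )
  for (r in seq_len(reps))
    coefficients[[paste0("target_upd_rep", r)]] <- upd_target[, r]

  set.seed(seeds[["act"]])
  act <- data.frame(
    pair_id = rep(pairs$pair_id, reps),
    repetition = rep(seq_len(reps), each = n),
    activation = params$act_intercept +
      params$act_coupling * rep(test_target - test_comp, reps) +
      stats::rnorm(n * reps, 0, params$act_sd),
    stringsAsFactors = FALSE
  )
  structure(list(
    templates = templates, plasticity_curve = plasticity_curve,
    coefficients = coefficients, activations = act, params = params
  ), class = "memupdate_ground_truth")
}

#' Default generative coefficient parameters
#'
#' Means and spreads of the reactivation mixing coefficients and of the
#' synthetic ROI activations. Competitor reactivation during updating is
#' stronger under RetPrac (mean 0.6) than Restudy (mean 0.15), matching the
#' direction of the observed condition difference; the subsequent-memory
#' boost raises updating target signal for pairs later answered correctly.
#'
#' @return named list of parameters.
#' @export
default_coefficient_params <- function() {
  list(
    target_upd_mean = 1.0, target_upd_sd = 0.2,
    comp_upd_mean = c(RetPrac = 0.6, Restudy = 0.15), comp_upd_sd = 0.15,
    target_test_mean = 1.0, target_test_sd = 0.2,
    subsequent_memory_boost = 0.3,
    act_intercept = 0.5, act_coupling = 0.5, act_sd = 0.3
  )
}
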