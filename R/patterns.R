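# TR pooling windows, as volume offsets from the first volume at/after trial
# onset (1-based volume "k TRs after onset" = onset volume + k - 1):
# updating & localizer pool volumes 3-4 after onset (unweighted mean), the
# final test pools volumes 3-6 with weights 0.35/0.35/0.15/0.15.
pooling_offsets <- function(phase) {
  switch(phase,
         test = 2:5,
         updating = ,
         localizer = 2:3,
         stop("unknown phase: ", phase))
}

pooling_weights <- function(phase) {
  if (phase == "test") c(0.35, 0.35, 0.15, 0.15) else c(0.5, 0.5)
}

# 1-based index of the first volume whose acquisition starts at or after onset
onset_to_tr <- function(onset, tr_seconds) {
  as.integer(ceiling(onset / tr_seconds)) + 1L
}

#' Simulate TR-by-voxel pattern matrices for a whole experiment
#'
#' For every run of every phase, builds a TR x voxel matrix of i.i.d.
#' Gaussian noise (\code{sd = config$noise_sd}) and adds, to the volumes
#' inside each trial's pooling window, that trial's signal: for updating
#' trials \code{target_coef * template_C + competitor_coef * template_B}; for
#' final-test trials the test-phase coefficients (competitor coefficient
#' shifted by the generative plasticity curve); for localizer trials the
#' presented category's template with unit coefficient. Volumes outside
#' pooling windows carry pure noise (no hemodynamic model is simulated).
#'
#' @param schedule output of \code{\link{make_schedule}}.
#' @param pairs output of \code{\link{make_pairs}}.
#' @param ground_truth output of \code{\link{make_ground_truth}}.
#' @param config the \code{\link{experiment_config}}.
#' @param seed integer seed for the noise draw.
#' @return list with \code{runs}: named list (\code{"<phase>_run<k>"}) of
#'   TR x voxel matrices, and \code{trials}: the schedule augmented with
#'   \code{onset_tr} (first volume of each trial).
#' @export
simulate_patterns <- function(schedule, pairs, ground_truth, config, seed = 1L) {
  tm <- ground_truth$templates
  if (!setequal(rownames(tm), config$categories))
    stop("ground-truth templates do not match config categories")
  coefs <- ground_truth$coefficients
  ci <- match(schedule$pair_id, coefs$pair_id)
  pi <- match(schedule$pair_id, pairs$pair_id)
  schedule$onset_tr <- onset_to_tr(schedule$onset, config$tr_seconds)

  set.seed(seed)
  keys <- unique(schedule[c("phase", "run")])
  keys <- keys[order(match(keys$phase, c("localizer", "updating", "test")),
                     keys$run), ]
  runs <- list()
  for (j in seq_len(nrow(keys))) {
    ph <- keys$phase[j]; rn <- keys$run[j]
    sel <- which(schedule$phase == ph & schedule$run == rn)
    offs <- pooling_offsets(ph)
    n_tr <- max(schedule$onset_tr[sel]) + max(offs) + 2L
    mat <- matrix(stats::rnorm(n_tr * config$n_voxels, 0, config$noise_sd),
                  n_tr, config$n_voxels)
    for (i in sel) {
      sig <- if (ph == "localizer") {
        tm[schedule$category[i], ]
      } else if (ph == "updating") {
        coefs[[paste0("target_upd_rep", schedule$repetition[i])]][ci[i]] *
          tm[pairs$category_C[pi[i]], ] +
          coefs$comp_upd[ci[i]] * tm[pairs$category_B[pi[i]], ]
      } else {
        coefs$test_target[ci[i]] * tm[pairs$category_C[pi[i]], ] +
          coefs$test_comp[ci[i]] * tm[pairs$category_B[pi[i]], ]
      }
      rows <- schedule$onset_tr[i] + offs
      mat[rows, ] <- mat[rows, ] + rep(sig, each = length(rows))
    }
    runs[[paste0(ph, "_run", rn)]] <- mat
  }
  list(runs = runs, trials = schedule)
}

#' Generate one complete synthetic subject
#'
#' Convenience wrapper running the full generation chain: pair specs, trial
#' schedule, behavioral responses, ground truth (templates, coefficients,
#' plasticity curve, activations) and voxel patterns, all from one seed fanned
#' out to per-stage child seeds.
#'
#' @param config a \code{\link{experiment_config}}.
#' @param seed integer seed.
#' @param ... passed to \code{\link{make_ground_truth}} (e.g. \code{params},
#'   \code{plasticity_curve}).
#' @return list of class \code{memupdate_experiment} with elements
#'   \code{config}, \code{pairs}, \code{schedule}, \code{behavior},
#'   \code{ground_truth}, \code{patterns}, \code{seed}.
#' @export
simulate_experiment <- function(config = experiment_config(), seed = 1L, ...) {
  seeds <- child_seeds(seed, c("pairs", "schedule", "behavior",
                               "ground_truth", "patterns"))
  pairs <- make_pairs(config, seed = seeds[["pairs"]])
  schedule <- make_schedule(config, pairs, seed = seeds[["schedule"]])
  behavior <- simulate_behavior(schedule, pairs, seed = seeds[["behavior"]],
                                categories = config$categories)
  gt <- make_ground_truth(config, pairs, behavior = behavior,
                          seed = seeds[["ground_truth"]], ...)
  patterns <- simulate_patterns(schedule, pairs, gt, config,
                                seed = seeds[["patterns"]])
  structure(list(config = config, pairs = pairs, schedule = schedule,
                 behavior = behavior, ground_truth = gt, patterns = patterns,
                 seed = seed),
            class = "memupdate_experiment")
}
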