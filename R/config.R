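#' Configuration of a synthetic memory-updating experiment
#'
#' Describes the three-day A-B/A-C retrieval-practice paradigm at the level
#' needed to generate synthetic data: pair counts, run structure, repetition
#' spacing, localizer design, and the voxel-pattern noise model. The defaults
#' reproduce the study design: 144 A-C pairs split evenly between retrieval
#' practice (RetPrac) and Restudy; 6 updating runs each containing 12 unique
#' pairs per condition, every pair repeated 3 times with inter-repetition
#' intervals of 10-36 trial positions; a 3-run final test of 48 pairs each;
#' and a 4-run localizer with 9 six-trial miniblocks per run (72 trials per
#' category in total).
#'
#' @param n_pairs number of A-B/A-C triads (even; default 144).
#' @param categories ordered picture-category labels (default face, object,
#'   scene); the order fixes deterministic tie-breaking downstream.
#' @param n_updating_runs number of updating runs (default 6).
#' @param pairs_per_condition_per_run unique pairs of each condition per
#'   updating run (default 12).
#' @param n_repetitions repetitions of each pair during updating (default 3).
#' @param iri_min,iri_max inter-repetition interval bounds, in trial
#'   positions (defaults 10 and 36).
#' @param n_test_runs,pairs_per_test_run final-test structure (3 runs x 48).
#' @param n_localizer_runs,miniblocks_per_run,trials_per_miniblock localizer
#'   structure (4 runs x 9 miniblocks x 6 trials; miniblocks split evenly
#'   over categories within each run).
#' @param n_voxels voxels per simulated ROI (default 120).
#' @param noise_sd standard deviation of the i.i.d. Gaussian voxel noise
#'   (default 0.12; see the methods vignette for the rationale).
#' @param tr_seconds repetition time of the simulated acquisition (2 s).
#' @param updating_trial_spacing,test_trial_spacing,localizer_trial_spacing
#'   onset-to-onset spacing in seconds (6, 12, 4).
#' @param localizer_gap_seconds gap after each localizer miniblock (12 s).
#' @param max_schedule_retries bounded retries for the IRI-constrained
#'   scheduler before it errors (default 1000).
#' @return list of class \code{memupdate_config}.
#' @export
experiment_config <- function(n_pairs = 144L,
                              categories = c("face", "object", "scene"),
                              n_updating_runs = 6L,
                              pairs_per_condition_per_run = 12L,
                              n_repetitions = 3L,
                              iri_min = 10L, iri_max = 36L,
                              n_test_runs = 3L, pairs_per_test_run = 48L,
                              n_localizer_runs = 4L,
                              miniblocks_per_run = 9L,
                              trials_per_miniblock = 6L,
                              n_voxels = 120L,
                              noise_sd = 0.12,
                              tr_seconds = 2,
                              updating_trial_spacing = 6,
                              test_trial_spacing = 12,
                              localizer_trial_spacing = 4,
                              localizer_gap_seconds = 12,
                              max_schedule_retries = 1000L) {
  if (n_pairs %% 2L != 0L) stop("invalid config: n_pairs must be even")
  if (length(categories) < 2L) stop("invalid config: need at least 2 categories")
  if (anyDuplicated(categories)) stop("invalid config: duplicate categories")
  if (noise_sd < 0) stop("invalid config: noise_sd must be nonnegative")
  if (iri_min > iri_max || iri_min < 1) stop("invalid config: bad IRI bounds")
  if (n_voxels < length(categories))
    stop("invalid config: n_voxels must be >= number of categories")
  structure(list(
    n_pairs = as.integer(n_pairs), categories = categories,
    n_updating_runs = as.integer(n_updating_runs),
    pairs_per_condition_per_run = as.integer(pairs_per_condition_per_run),
    n_repetitions = as.integer(n_repetitions),
    iri_min = as.integer(iri_min), iri_max = as.integer(iri_max),
    n_test_runs = as.integer(n_test_runs),
    pairs_per_test_run = as.integer(pairs_per_test_run),
    n_localizer_runs = as.integer(n_localizer_runs),
    miniblocks_per_run = as.integer(miniblocks_per_run),
    trials_per_miniblock = as.integer(trials_per_miniblock),
    n_voxels = as.integer(n_voxels), noise_sd = noise_sd,
    tr_seconds = tr_seconds,
    updating_trial_spacing = updating_trial_spacing,
    test_trial_spacing = test_trial_spacing,
    localizer_trial_spacing = localizer_trial_spacing,
    localizer_gap_seconds = localizer_gap_seconds,
    max_schedule_retries = as.integer(max_schedule_retries)
  ), class = "memupdate_config")
}

# Checks the run-structure invariants needed to build a full schedule.
# Kept separate from the constructor so that reduced configs (e.g. a handful
# of pairs for pair-assignment unit tests) remain constructible.
check_schedule_config <- function(config) {
  with(config, {
    if (n_pairs != 2L * n_updating_runs * pairs_per_condition_per_run)
      stop("invalid config: n_pairs != 2 * n_updating_runs * pairs_per_condition_per_run")
    if (n_test_runs * pairs_per_test_run != n_pairs)
      stop("invalid config: n_test_runs * pairs_per_test_run != n_pairs")
    if (miniblocks_per_run %% length(categories) != 0L)
      stop("invalid config: miniblocks_per_run must divide evenly over categories")
  })
  invisible(config)
}

# Fan a single seed out to named child seeds by a fixed counter scheme, so
# each generation stage is individually reproducible.
child_seeds <- function(seed, names) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  stats::setNames(s, names)
}
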