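# IRI-constrained ordering of one updating run.
#
# m unique pairs, n_rep repetitions, run length m * n_rep. Trial positions are
# partitioned into n_rep consecutive blocks of m; each pair occupies exactly
# one position per block, so every pair appears once per repetition "sweep"
# (conditions stay intermixed because pairs are randomly placed within
# blocks). The gap between a pair's consecutive positions is m + delta with
# delta the within-block offset, and positions are drawn by randomized
# tightest-first matching so every gap lands inside [iri_min, iri_max].
# Returns an m x n_rep matrix of trial positions (rows = pairs) or NULL if a
# feasible matching was not found in this attempt.
.schedule_run_once <- function(m, n_rep, iri_min, iri_max) {
  pos <- matrix(NA_integer_, m, n_rep)
  pos[, 1] <- sample.int(m)
  if (n_rep == 1L) return(pos)
  for (r in 2L:n_rep) {
    block <- (r - 1L) * m + seq_len(m)
    prev <- pos[, r - 1L] + (r - 2L) * m
    free <- rep(TRUE, m)           # availability of block positions 1..m
    assigned <- rep(NA_integer_, m)
    feas <- lapply(seq_len(m), function(i) {
      lo <- max(block[1], prev[i] + iri_min)
      hi <- min(block[m], prev[i] + iri_max)
      if (lo > hi) integer(0) else (lo:hi) - (r - 1L) * m
    })
    # tightest-first with random tie-breaking
    ord <- order(vapply(feas, length, integer(1)) + stats::runif(m))
    for (i in ord) {
      opts <- feas[[i]][free[feas[[i]]]]
      if (!length(opts)) return(NULL)
      pick <- if (length(opts) == 1L) opts else sample(opts, 1L)
      assigned[i] <- pick
      free[pick] <- FALSE
    }
    pos[, r] <- assigned
  }
  pos
}

.schedule_run <- function(pair_ids, n_rep, iri_min, iri_max, max_retries) {
  m <- length(pair_ids)
  if (n_rep > 1L && (iri_max < 1L || iri_min > (n_rep * m - 1L)))
    stop("infeasible IRI constraints for run length ", n_rep * m)
  for (attempt in seq_len(max_retries)) {
    pos <- .schedule_run_once(m, n_rep, iri_min, iri_max)
    if (!is.null(pos)) {
      abs_pos <- sweep(pos, 2L, (seq_len(n_rep) - 1L) * m, `+`)
      out <- data.frame(
        trial = as.vector(abs_pos),
        pair_id = rep(pair_ids, n_rep),
        repetition = rep(seq_len(n_rep), each = m),
        stringsAsFactors = FALSE
      )
      return(out[order(out$trial), ])
    }
  }
  stop(sprintf(
    "scheduling failed: no IRI-feasible ordering found after %d attempts",
    max_retries))
}

#' Generate the full trial schedule
#'
#' Builds the trial-by-trial schedule of all three phases: the updating phase
#' (pairs assigned to runs so that each run holds
#' \code{pairs_per_condition_per_run} unique pairs of each condition, each
#' repeated \code{n_repetitions} times with inter-repetition gaps inside the
#' IRI bounds), the final test (every pair probed exactly once, split across
#' test runs), and the category localizer (miniblocks of one category each,
#' evenly covering categories within every run). Trial onsets are in seconds
#' from run start. Regeneration with the same seed is bit-identical.
#'
#' @param config a \code{\link{experiment_config}} (full-design invariants are
#'   checked here).
#' @param pairs output of \code{\link{make_pairs}} consistent with the config.
#' @param seed integer seed.
#' @return data.frame with columns \code{phase} (localizer/updating/test),
#'   \code{run}, \code{trial}, \code{pair_id} (NA for localizer),
#'   \code{condition}, \code{repetition}, \code{category} (localizer only:
#'   presented category), \code{onset}.
#' @export
make_schedule <- function(config, pairs, seed = 1L) {
  check_schedule_config(config)
  if (nrow(pairs) != config$n_pairs)
    stop("pairs table does not match config: wrong number of pairs")
  set.seed(seed)
  ppc <- config$pairs_per_condition_per_run

  # --- updating: assign unique pairs to runs, balanced by condition
  rp <- sample(pairs$pair_id[pairs$condition == "RetPrac"])
  rs <- sample(pairs$pair_id[pairs$condition == "Restudy"])
  upd <- do.call(rbind, lapply(seq_len(config$n_updating_runs), function(k) {
    ids <- c(rp[(k - 1L) * ppc + seq_len(ppc)], rs[(k - 1L) * ppc + seq_len(ppc)])
    run <- .schedule_run(ids, config$n_repetitions, config$iri_min,
                         config$iri_max, config$max_schedule_retries)
    data.frame(phase = "updating", run = k, trial = run$trial,
               pair_id = run$pair_id, repetition = run$repetition,
               onset = (run$trial - 1) * config$updating_trial_spacing,
               stringsAsFactors = FALSE)
  }))

  # --- final test: all pairs once, shuffled across runs
  tst_ids <- sample(pairs$pair_id)
  tst <- do.call(rbind, lapply(seq_len(config$n_test_runs), function(k) {
    ids <- tst_ids[(k - 1L) * config$pairs_per_test_run +
                     seq_len(config$pairs_per_test_run)]
    data.frame(phase = "test", run = k, trial = seq_along(ids), pair_id = ids,
               repetition = 1L,
               onset = (seq_along(ids) - 1) * config$test_trial_spacing,
               stringsAsFactors = FALSE)
  }))

  # --- localizer: category miniblocks
  n_cat <- length(config$categories)
  mb_per_cat <- config$miniblocks_per_run %/% n_cat
  loc <- do.call(rbind, lapply(seq_len(config$n_localizer_runs), function(k) {
    mb_cats <- sample(rep(config$categories, mb_per_cat))
    mb_len <- config$trials_per_miniblock * config$localizer_trial_spacing +
      config$localizer_gap_seconds
    do.call(rbind, lapply(seq_along(mb_cats), function(mb) {
      j <- seq_len(config$trials_per_miniblock)
      data.frame(phase = "localizer", run = k,
                 trial = (mb - 1L) * config$trials_per_miniblock + j,
                 pair_id = NA_character_, repetition = 1L,
                 category = mb_cats[mb],
                 onset = (mb - 1) * mb_len +
                   (j - 1) * config$localizer_trial_spacing,
                 stringsAsFactors = FALSE)
    }))
  }))

  upd$category <- NA_character_
  tst$category <- NA_character_
  cond <- stats::setNames(pairs$condition, pairs$pair_id)
  upd$condition <- unname(cond[upd$pair_id])
  tst$condition <- unname(cond[tst$pair_id])
  loc$condition <- NA_character_
  cols <- c("phase", "run", "trial", "pair_id", "condition", "repetition",
            "category", "onset")
  out <- rbind(upd[cols], tst[cols], loc[cols])
  rownames(out) <- NULL
  out
}

#' Inter-repetition intervals of an updating schedule
#'
#' Gap, in trial positions, between consecutive repetitions of each pair
#' within its updating run.
#'
#' @param schedule output of \code{\link{make_schedule}}.
#' @return data.frame with \code{pair_id}, \code{from_rep}, \code{gap}.
#' @export
schedule_iris <- function(schedule) {
  upd <- schedule[schedule$phase == "updating", ]
  upd <- upd[order(upd$pair_id, upd$repetition), ]
  do.call(rbind, lapply(split(upd, upd$pair_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    data.frame(pair_id = d$pair_id[1],
               from_rep = d$repetition[-nrow(d)],
               gap = diff(d$trial), stringsAsFactors = FALSE)
  }))
}
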