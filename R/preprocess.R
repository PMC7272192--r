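#' Z-score each voxel's time series within a run
#'
#' First stage of the normalization cascade: every voxel (column) of the
#' TR x voxel matrix is standardized to mean 0, sd 1 across the run's volumes
#' (sample sd, denominator n-1).
#'
#' @param mat TR x voxel matrix.
#' @return matrix of the same shape.
#' @export
zscore_within_run <- function(mat) {
  if (any(!is.finite(mat))) stop("non-finite values in run data")
  mu <- colMeans(mat)
  sdv <- apply(mat, 2L, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop("zero temporal variance in voxel(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  sweep(sweep(mat, 2L, mu), 2L, sdv, `/`)
}

#' Z-score each volume across voxels
#'
#' Second stage of the cascade: every volume (row) is standardized to mean 0,
#' sd 1 across voxels.
#'
#' @param mat TR x voxel matrix.
#' @return matrix of the same shape.
#' @export
zscore_across_voxels <- function(mat) {
  if (any(!is.finite(mat))) stop("non-finite values in run data")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop("zero across-voxel variance in volume(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  sweep(sweep(mat, 1L, mu), 1L, sdv, `/`)
}

#' Pool the volumes of one trial into a single pattern vector
#'
#' Final-test trials: weighted average of volumes 3-6 after onset with weights
#' (0.35, 0.35, 0.15, 0.15). Updating and localizer trials: unweighted mean of
#' volumes 3-4 after onset. "Volume k after onset" is the k-th volume whose
#' acquisition starts at or after the onset, counted 1-based. Volumes listed
#' in \code{tr_exclude} (e.g. motion-scrubbed) are dropped from the window and
#' the remaining weights renormalized; an emptied window is an error.
#'
#' @param mat TR x voxel run matrix.
#' @param onset_tr 1-based index of the trial's first volume.
#' @param phase one of \code{"updating"}, \code{"test"}, \code{"localizer"}.
#' @param tr_exclude optional integer vector of excluded volume indices.
#' @return voxel-length pattern vector.
#' @export
pool_trial <- function(mat, onset_tr, phase, tr_exclude = NULL) {
  idx <- onset_tr + pooling_offsets(phase)
  w <- pooling_weights(phase)
  if (max(idx) > nrow(mat))
    stop(sprintf("pooling window of trial at volume %d extends past run end (%d > %d)",
                 onset_tr, max(idx), nrow(mat)))
  keep <- !(idx %in% tr_exclude)
  if (!any(keep))
    stop(sprintf("all volumes of trial at volume %d are excluded", onset_tr))
  idx <- idx[keep]; w <- w[keep] / sum(w[keep])
  as.vector(w %*% mat[idx, , drop = FALSE])
}

#' Pool every trial of a run
#'
#' @param mat TR x voxel run matrix.
#' @param onset_trs integer vector of trial onset volumes.
#' @inheritParams pool_trial
#' @return trials x voxel matrix.
#' @export
pool_run <- function(mat, onset_trs, phase, tr_exclude = NULL) {
  t(vapply(onset_trs, function(o) pool_trial(mat, o, phase, tr_exclude),
           numeric(ncol(mat))))
}

#' Z-score pooled trial patterns across a selected trial set
#'
#' Third stage of the cascade: each voxel is standardized to mean 0, sd 1
#' across all trials of the selected set (one phase, runs combined).
#'
#' @param patterns trials x voxel matrix (at least 2 rows).
#' @return matrix of the same shape.
#' @export
zscore_across_selected <- function(patterns) {
  if (nrow(patterns) < 2L) stop("need at least 2 patterns")
  zscore_within_run(patterns)
}

#' Run the full normalization cascade for one phase
#'
#' Applies, in fixed order: z-scoring within each run (per voxel over time),
#' z-scoring across voxels (per volume), trial pooling, and a final z-scoring
#' across all of the phase's pooled trials (per voxel). With
#' \code{third_zscore = "before_pooling"} the final z-scoring is instead
#' applied to the selected in-window volumes before pooling (the alternative
#' reading of the cascade; see the methods vignette).
#'
#' @param patterns output of \code{\link{simulate_patterns}} (or a list with
#'   the same structure built from real ROI data).
#' @param phase phase to extract.
#' @param third_zscore \code{"after_pooling"} (default) or
#'   \code{"before_pooling"}.
#' @param tr_exclude optional named list (run key -> excluded volume indices).
#' @return list with \code{patterns} (trials x voxel matrix) and
#'   \code{trials} (the phase's schedule rows, in matching order).
#' @export
preprocess_phase <- function(patterns, phase,
                             third_zscore = c("after_pooling", "before_pooling"),
                             tr_exclude = NULL) {
  third_zscore <- match.arg(third_zscore)
  trials <- patterns$trials[patterns$trials$phase == phase, ]
  if (!nrow(trials)) stop("no trials for phase ", phase)
  runs <- sort(unique(trials$run))
  pooled <- vector("list", length(runs))
  selected <- vector("list", length(runs))
  for (j in seq_along(runs)) {
    key <- paste0(phase, "_run", runs[j])
    mat <- patterns$runs[[key]]
    if (is.null(mat)) stop("missing run matrix: ", key)
    excl <- tr_exclude[[key]]
    z <- zscore_across_voxels(zscore_within_run(mat))
    tr <- trials[trials$run == runs[j], ]
    tr <- tr[order(tr$trial), ]
    if (third_zscore == "after_pooling") {
      pooled[[j]] <- pool_run(z, tr$onset_tr, phase, excl)
    } else {
      selected[[j]] <- list(z = z, onsets = tr$onset_tr, excl = excl)
    }
  }
  trials <- trials[order(trials$run, trials$trial), ]
  if (third_zscore == "after_pooling") {
    out <- zscore_across_selected(do.call(rbind, pooled))
  } else {
    # z-score the pooling-window volumes across the whole phase, then pool
    win <- lapply(selected, function(s) {
      idx <- unique(sort(as.vector(outer(pooling_offsets(phase), s$onsets, `+`))))
      idx <- setdiff(idx, s$excl)
      list(idx = idx, n = length(idx))
    })
    vol <- do.call(rbind, lapply(seq_along(selected), function(j)
      selected[[j]]$z[win[[j]]$idx, , drop = FALSE]))
    vol <- zscore_within_run(vol)   # per-voxel over all selected volumes
    off <- cumsum(c(0L, vapply(win, `[[`, integer(1), "n")))
    out <- do.call(rbind, lapply(seq_along(selected), function(j) {
      zmat <- selected[[j]]$z
      zmat[win[[j]]$idx, ] <- vol[off[j] + seq_len(win[[j]]$n), ]
      pool_run(zmat, selected[[j]]$onsets, phase, selected[[j]]$excl)
    }))
  }
  list(patterns = out, trials = trials)
}
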