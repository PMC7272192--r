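#' Write a BIDS-style events table
#'
#' One TSV per call: schedule rows (optionally merged with behavioral
#' responses) with onset/duration first, as in BIDS events.tsv files.
#'
#' @param schedule output of \code{\link{make_schedule}}, or a merged
#'   schedule-plus-behavior table.
#' @param path output file path.
#' @param duration trial duration in seconds written to the duration column.
#' @return the path, invisibly.
#' @export
write_events_tsv <- function(schedule, path, duration = 4) {
  df <- schedule
  df$duration <- duration
  front <- c("onset", "duration")
  df <- df[c(front, setdiff(names(df), front))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' Read an events table written by \code{\link{write_events_tsv}}
#'
#' @param path TSV file path.
#' @return data.frame with the original schedule columns restored.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", na.strings = "n/a",
                          stringsAsFactors = FALSE)
  df$duration <- NULL
  pref <- c("phase", "run", "trial", "pair_id", "condition", "repetition",
            "category", "onset")
  df[c(intersect(pref, names(df)), setdiff(names(df), pref))]
}

#' Write pair metadata as TSV
#' @param pairs the pair table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth sidecar JSON
#'
#' Stores the generative plasticity curve, coefficient parameters, and
#' trial-level coefficients of a synthetic subject.
#'
#' @param ground_truth output of \code{\link{make_ground_truth}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  obj <- list(
    plasticity_curve = ground_truth$plasticity_curve[c("x", "y")],
    params = ground_truth$params,
    coefficients = ground_truth$coefficients
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
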