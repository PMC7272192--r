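#' Simulate categorical responses for updating and test trials
#'
#' Draws one response per updating and test trial from the per-condition
#' (and, for updating, per-repetition) multinomial over
#' \{target, competitor, other, dontknow\}; any residual probability mass is
#' assigned to \code{noresponse}. The sampled outcome is translated into a
#' concrete category response: \code{target} maps to the pair's category C,
#' \code{competitor} to category B, \code{other} to the remaining category.
#'
#' @param schedule output of \code{\link{make_schedule}}.
#' @param pairs output of \code{\link{make_pairs}}.
#' @param behavior_params see \code{\link{default_behavior_params}}.
#' @param seed integer seed.
#' @param categories full category set (defaults to the categories present in
#'   \code{pairs}).
#' @return data.frame: schedule keys plus \code{outcome} (sampled outcome
#'   label) and \code{response} (category label, \code{dontknow} or
#'   \code{noresponse}).
#' @export
simulate_behavior <- function(schedule, pairs,
                              behavior_params = default_behavior_params(),
                              seed = 1L,
                              categories = sort(unique(c(pairs$category_B,
                                                         pairs$category_C)))) {
  .check_probs <- function(p) {
    if (any(p < 0) || sum(p) > 1 + 1e-12)
      stop("invalid behavior_params: probabilities must be nonnegative and sum to <= 1")
  }
  for (cnd in names(behavior_params$updating))
    apply(behavior_params$updating[[cnd]], 1L, .check_probs)
  for (cnd in names(behavior_params$test))
    .check_probs(behavior_params$test[[cnd]])

  trials <- schedule[schedule$phase %in% c("updating", "test"), ]
  pi <- match(trials$pair_id, pairs$pair_id)
  other_cat <- vapply(seq_len(nrow(pairs)), function(i) {
    rest <- setdiff(categories, c(pairs$category_B[i], pairs$category_C[i]))
    if (length(rest)) rest[1] else NA_character_
  }, character(1))

  set.seed(seed)
  outc <- c("target", "competitor", "other", "dontknow", "noresponse")
  outcome <- character(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    cnd <- trials$condition[i]
    p <- if (trials$phase[i] == "updating") {
      behavior_params$updating[[cnd]][trials$repetition[i], ]
    } else behavior_params$test[[cnd]]
    p <- c(p, noresponse = max(0, 1 - sum(p)))
    if (p["other"] > 0 && is.na(other_cat[pi[i]]))
      stop("'other' outcome has positive probability but no third category exists")
    outcome[i] <- sample(outc, 1L, prob = p)
  }
  response <- ifelse(
    outcome == "target", pairs$category_C[pi],
    ifelse(outcome == "competitor", pairs$category_B[pi],
           ifelse(outcome == "other", other_cat[pi], outcome)))
  out <- trials[c("phase", "run", "trial", "pair_id", "condition", "repetition")]
  out$outcome <- outcome
  out$response <- response
  rownames(out) <- NULL
  out
}
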