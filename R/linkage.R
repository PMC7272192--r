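#' Build the short-term suppression linkage table
#'
#' One row per eligible pair and repetition r < R: the predictor is the ROI
#' activation at repetition r, the outcome is the drop in competitor evidence
#' from repetition r to r + 1
#' (\code{competitor_norm(r) - competitor_norm(r+1)}). Pairs are filtered by
#' updating history (\code{FC} only, or \code{FC} plus \code{IC}).
#'
#' @param evidence updating-phase evidence with \code{subject},
#'   \code{pair_id}, \code{repetition}, \code{competitor_norm}.
#' @param activations data.frame with \code{subject}, \code{pair_id},
#'   \code{repetition}, \code{activation}.
#' @param history data.frame with \code{subject}, \code{pair_id},
#'   \code{history} (see \code{\link{label_update_history}}).
#' @param trial_filter \code{"FC"} or \code{"FC_IC"}.
#' @return data.frame with \code{subject}, \code{pair_id}, \code{repetition},
#'   \code{predictor}, \code{outcome}.
#' @export
build_suppression_table <- function(evidence, activations, history,
                                    trial_filter = c("FC", "FC_IC")) {
  trial_filter <- match.arg(trial_filter)
  keep_labels <- if (trial_filter == "FC") "FC" else c("FC", "IC")
  hkey <- paste(history$subject, history$pair_id)
  keep_pairs <- hkey[history$history %in% keep_labels]
  ev <- evidence[paste(evidence$subject, evidence$pair_id) %in% keep_pairs, ]
  if (!nrow(ev)) stop("trial filter '", trial_filter, "' left no pairs")
  ev <- ev[order(ev$subject, ev$pair_id, ev$repetition), ]
  akey <- paste(activations$subject, activations$pair_id,
                activations$repetition)
  out <- do.call(rbind, lapply(
    split(ev, paste(ev$subject, ev$pair_id)), function(d) {
      if (nrow(d) < 2L) return(NULL)
      r <- seq_len(nrow(d) - 1L)
      data.frame(subject = d$subject[1], pair_id = d$pair_id[1],
                 repetition = d$repetition[r],
                 predictor = activations$activation[
                   match(paste(d$subject[1], d$pair_id[1], d$repetition[r]),
                         akey)],
                 outcome = d$competitor_norm[r] - d$competitor_norm[r + 1L],
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  if (any(is.na(out$predictor))) stop("activations missing for some trials")
  out
}

#' Build the long-term memory-updating linkage table
#'
#' One row per pair: the predictor is the pair's mean ROI activation across
#' the updating repetitions, the outcome is final-test target minus competitor
#' evidence. Pairs without final-test evidence are excluded with a message.
#'
#' @param activations data.frame with \code{subject}, \code{pair_id},
#'   \code{repetition}, \code{activation}.
#' @param test_evidence final-test evidence with \code{subject},
#'   \code{pair_id}, \code{target_norm}, \code{competitor_norm}.
#' @return data.frame with \code{subject}, \code{pair_id}, \code{predictor},
#'   \code{outcome}.
#' @export
build_longterm_table <- function(activations, test_evidence) {
  mean_act <- stats::aggregate(activation ~ subject + pair_id,
                               data = activations, FUN = mean)
  key <- paste(test_evidence$subject, test_evidence$pair_id)
  idx <- match(paste(mean_act$subject, mean_act$pair_id), key)
  missing <- sum(is.na(idx))
  if (missing)
    message(missing, " pair(s) without final-test evidence excluded")
  keep <- !is.na(idx)
  out <- data.frame(
    subject = mean_act$subject[keep], pair_id = mean_act$pair_id[keep],
    predictor = mean_act$activation[keep],
    outcome = test_evidence$target_norm[idx[keep]] -
      test_evidence$competitor_norm[idx[keep]],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mixed-effects likelihood-ratio test for an activation-evidence link
#'
#' Fits \code{outcome ~ predictor + (1 | subject)} (full) against
#' \code{outcome ~ 1 + (1 | subject)} (null), both by maximum likelihood (not
#' REML, so the fixed-effect likelihood-ratio comparison is valid), and
#' reports \code{chi^2 = 2 * (llik_full - llik_null)} on 1 df (clipped at 0
#' against numerical noise). Boundary (singular) random-effect fits are kept
#' and reported. With a single subject the model degrades to ordinary linear
#' regression, with a warning.
#'
#' @param table a linkage table with \code{subject}, \code{predictor},
#'   \code{outcome}.
#' @return list with \code{chisq}, \code{df}, \code{p}, \code{estimate}
#'   (fixed slope), \code{se}, \code{singular}, \code{n}, \code{n_subjects}.
#' @export
lmm_lrt <- function(table) {
  stopifnot(all(c("subject", "predictor", "outcome") %in% names(table)))
  if (any(!is.finite(table$predictor)) || any(!is.finite(table$outcome)))
    stop("non-finite values in linkage table")
  n_sub <- length(unique(table$subject))
  if (n_sub < 2L) {
    warning("single subject: falling back to ordinary linear regression")
    full <- stats::lm(outcome ~ predictor, data = table)
    null <- stats::lm(outcome ~ 1, data = table)
    chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                           as.numeric(stats::logLik(null))))
    est <- stats::coef(summary(full))["predictor", ]
    return(list(chisq = chisq, df = 1L,
                p = stats::pchisq(chisq, 1L, lower.tail = FALSE),
                estimate = est[["Estimate"]], se = est[["Std. Error"]],
                singular = NA, n = nrow(table), n_subjects = n_sub))
  }
  if (min(table(table$subject)) < 2L)
    stop("each subject needs at least 2 rows")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- suppressMessages(lme4::lmer(
    outcome ~ predictor + (1 | subject), data = table, REML = FALSE,
    control = ctrl))
  null <- suppressMessages(lme4::lmer(
    outcome ~ 1 + (1 | subject), data = table, REML = FALSE, control = ctrl))
  chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                         as.numeric(stats::logLik(null))))
  cf <- lme4::fixef(full)["predictor"]
  se <- sqrt(diag(as.matrix(stats::vcov(full))))[2L]
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1L, lower.tail = FALSE),
       estimate = unname(cf), se = unname(se),
       singular = lme4::isSingular(full), n = nrow(table),
       n_subjects = n_sub)
}
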