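#' Score a categorical response against a pair's association roles
#'
#' In the A-C test, choosing the pair's category C is a \code{target} response
#' and category B a \code{competitor} (intrusion); in the A-B test the roles
#' reverse (B is the probed target, C the intrusion). Any remaining category
#' is \code{other}; \code{dontknow}/\code{noresponse} pass through.
#'
#' @param response response label(s): a category, \code{dontknow}, or
#'   \code{noresponse}.
#' @param category_B,category_C the pair's picture categories (recycled).
#' @param test_kind \code{"AC"} (default) or \code{"AB"}.
#' @param categories valid category labels.
#' @return character vector of outcome labels
#'   \{target, competitor, other, dontknow, noresponse\}.
#' @export
score_response <- function(response, category_B, category_C,
                           test_kind = c("AC", "AB"),
                           categories = NULL) {
  test_kind <- match.arg(test_kind)
  if (is.null(categories))
    categories <- sort(unique(c(category_B, category_C,
                                response[!response %in% c("dontknow", "noresponse")])))
  ok <- response %in% c(categories, "dontknow", "noresponse")
  if (any(!ok))
    stop("unknown response code: ", paste(unique(response[!ok]), collapse = ", "))
  tgt <- if (test_kind == "AC") category_C else category_B
  cmp <- if (test_kind == "AC") category_B else category_C
  ifelse(response %in% c("dontknow", "noresponse"), response,
         ifelse(response == tgt, "target",
                ifelse(response == cmp, "competitor", "other")))
}

#' Joint outcome of the A-B and A-C memory tests
#'
#' Classifies each pair by its pattern of responses across both tests:
#' \code{correct_both} (B chosen in the A-B test and C in the A-C test),
#' \code{B_both} (old memory given in both tests), \code{C_both} (new memory
#' given in both tests), or \code{other}; reports proportions over pairs per
#' condition.
#'
#' @param ab_responses,ac_responses data.frames with \code{pair_id} and
#'   \code{response} (category / dontknow / noresponse), one row per pair.
#' @param pairs the pair specification table.
#' @return list with \code{cells} (per-pair joint label) and
#'   \code{proportions} (condition x joint-cell proportion table).
#' @export
joint_outcome_table <- function(ab_responses, ac_responses, pairs) {
  ids <- pairs$pair_id
  if (!setequal(ab_responses$pair_id, ids) || !setequal(ac_responses$pair_id, ids))
    stop("both tests must cover exactly the configured pair set")
  ab <- ab_responses$response[match(ids, ab_responses$pair_id)]
  ac <- ac_responses$response[match(ids, ac_responses$pair_id)]
  B <- pairs$category_B; C <- pairs$category_C
  cell <- ifelse(ab == B & ac == C, "correct_both",
                 ifelse(ab == B & ac == B, "B_both",
                        ifelse(ab == C & ac == C, "C_both", "other")))
  cells <- data.frame(pair_id = ids, condition = pairs$condition,
                      joint = cell, stringsAsFactors = FALSE)
  lv <- c("correct_both", "B_both", "C_both", "other")
  props <- do.call(rbind, lapply(split(cells, cells$condition), function(d) {
    p <- table(factor(d$joint, levels = lv)) / nrow(d)
    data.frame(condition = d$condition[1], t(as.numeric(p)))
  }))
  names(props)[-1] <- lv
  rownames(props) <- NULL
  list(cells = cells, proportions = props)
}

#' Label each pair's updating history (FC / LC / IC)
#'
#' \code{FC} (first correct): target response at repetition 1; \code{LC}
#' (later correct): first target response at repetition 2 or 3; \code{IC}:
#' never correct. Pairs correct at repetition 1 but incorrect at a later
#' repetition keep a separate \code{FC_lapse} label (excluded from FC/LC/IC
#' analyses, mirroring regressors of no interest).
#'
#' @param updating_behavior data.frame of updating-phase rows with
#'   \code{pair_id}, \code{repetition}, \code{outcome}.
#' @param n_repetitions expected repetitions per pair.
#' @return data.frame with \code{pair_id} and \code{history} in
#'   \{FC, LC, IC, FC_lapse\}.
#' @export
label_update_history <- function(updating_behavior, n_repetitions = 3L) {
  sp <- split(updating_behavior, updating_behavior$pair_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$repetition), ]
    if (!identical(as.integer(d$repetition), seq_len(n_repetitions)))
      stop("missing repetition(s) for pair ", d$pair_id[1])
    correct <- d$outcome == "target"
    lab <- if (correct[1]) {
      if (all(correct[-1])) "FC" else "FC_lapse"
    } else if (any(correct)) "LC" else "IC"
    data.frame(pair_id = d$pair_id[1], history = lab, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Subject-by-cell means with within-subject standard errors
#'
#' Aggregates trial-level evidence into per-subject cell means for a fully
#' crossed within-subject design, then computes within-subject standard
#' errors by subject-mean centering (Cousineau) with the cell-count bias
#' correction (Morey): each subject's cell means are centered on the
#' subject's grand mean, the per-cell SE of the centered values is multiplied
#' by \code{sqrt(C / (C - 1))} for C cells. Subjects with an empty cell are
#' excluded (with a warning) rather than imputed.
#'
#' @param data trial-level data.frame with a \code{subject} column, the factor
#'   columns, and the measure column.
#' @param measure name of the evidence column.
#' @param factors character vector of factor column names.
#' @return list with \code{subject_cells} (subject x cell means),
#'   \code{cells} (cell-level mean, within-subject SE, n subjects, counts),
#'   \code{excluded_subjects}.
#' @export
evidence_cells <- function(data, measure, factors) {
  stopifnot(all(c("subject", factors, measure) %in% names(data)))
  key <- interaction(data[factors], drop = FALSE, sep = ":")
  lv <- levels(key)
  agg <- stats::aggregate(data[[measure]],
                          by = c(list(subject = data$subject), data[factors]),
                          FUN = mean)
  names(agg)[ncol(agg)] <- "mean"
  cnt <- stats::aggregate(data[[measure]],
                          by = c(list(subject = data$subject), data[factors]),
                          FUN = length)
  names(cnt)[ncol(cnt)] <- "n_trials"
  agg$n_trials <- cnt$n_trials
  wide_key <- interaction(agg[factors], drop = FALSE, sep = ":")
  subjects <- unique(agg$subject)
  full <- length(lv)
  complete <- vapply(subjects, function(s)
    length(unique(wide_key[agg$subject == s])) == full, logical(1))
  excluded <- subjects[!complete]
  if (length(excluded))
    warning("excluding subject(s) with empty cells: ",
            paste(excluded, collapse = ", "))
  agg <- agg[agg$subject %in% subjects[complete], ]
  wide_key <- interaction(agg[factors], drop = FALSE, sep = ":")
  # Cousineau centering + Morey correction
  gm <- tapply(agg$mean, agg$subject, mean)
  centered <- agg$mean - gm[as.character(agg$subject)] + mean(agg$mean)
  n_sub <- sum(complete)
  cells <- do.call(rbind, lapply(lv, function(l) {
    sel <- wide_key == l
    # with one subject there is no between-subject spread: SE is 0
    se <- if (n_sub < 2L) 0 else
      stats::sd(centered[sel]) / sqrt(n_sub) * sqrt(full / (full - 1))
    data.frame(cell = l, mean = mean(agg$mean[sel]),
               se_within = se,
               n_subjects = n_sub,
               mean_trials = mean(agg$n_trials[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  list(subject_cells = agg, cells = cells, excluded_subjects = excluded)
}

#' Paired contrast (t test with Cohen's d)
#'
#' Paired t statistic with df = n - 1, two-sided p, and Cohen's d computed
#' from the standard deviation of the paired differences.
#'
#' @param a,b paired per-subject values.
#' @return list with \code{t}, \code{df}, \code{p}, \code{cohens_d},
#'   \code{mean_diff}.
#' @export
paired_contrast <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need paired vectors of equal length >= 2")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of paired differences")
  n <- length(d)
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L),
       cohens_d = mean(d) / sdd, mean_diff = mean(d))
}

#' Repeated-measures ANOVA for fully crossed 2-level within-subject designs
#'
#' F ratios for all main effects and interactions. For 2-level factors every
#' effect reduces exactly to a one-sample t test on per-subject contrast
#' scores, so each F has df (1, n - 1); no sphericity correction is needed at
#' 2 levels. Trial-level input is first aggregated to subject-by-cell means.
#'
#' @param data data.frame with \code{subject}, the factor columns, and the
#'   dependent-variable column.
#' @param dv dependent-variable column name.
#' @param factors character vector of 1-3 factor column names, each with
#'   exactly 2 levels.
#' @return data.frame with \code{effect}, \code{F}, \code{df1}, \code{df2},
#'   \code{p}.
#' @export
rm_anova <- function(data, dv, factors) {
  stopifnot(all(c("subject", factors, dv) %in% names(data)),
            length(factors) >= 1L, length(factors) <= 3L)
  agg <- stats::aggregate(data[[dv]],
                          by = c(list(subject = data$subject), data[factors]),
                          FUN = mean)
  names(agg)[ncol(agg)] <- "y"
  lvls <- lapply(factors, function(f) sort(unique(as.character(agg[[f]]))))
  if (any(vapply(lvls, length, integer(1)) != 2L))
    stop("rm_anova requires exactly 2 levels per factor")
  subjects <- unique(agg$subject)
  per_sub <- table(agg$subject)
  if (any(per_sub != 2L^length(factors)))
    stop("missing cells: design must be fully crossed within every subject")
  codes <- lapply(seq_along(factors), function(i)
    ifelse(as.character(agg[[factors[i]]]) == lvls[[i]][2L], 1, -1))
  effects <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(seq_along(factors), k, simplify = FALSE)), recursive = FALSE)
  n <- length(subjects)
  out <- do.call(rbind, lapply(effects, function(ef) {
    code <- Reduce(`*`, codes[ef])
    sc <- tapply(agg$y * code, agg$subject, mean)
    tval <- mean(sc) / (stats::sd(sc) / sqrt(n))
    data.frame(effect = paste(factors[ef], collapse = ":"),
               F = tval^2, df1 = 1L, df2 = n - 1L,
               p = 2 * stats::pt(-abs(tval), n - 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-subject evidence trend across updating repetitions
#'
#' Least-squares slope of each subject's per-repetition mean evidence over
#' the repetition index, with a one-sample t test of the slopes against zero.
#'
#' @param data data.frame with \code{subject}, \code{repetition}, and the
#'   measure column.
#' @param measure evidence column name.
#' @param n_repetitions required repetitions (default 3).
#' @return list with \code{slopes} (named per subject), \code{t}, \code{df},
#'   \code{p}.
#' @export
repetition_trend <- function(data, measure, n_repetitions = 3L) {
  stopifnot(all(c("subject", "repetition", measure) %in% names(data)))
  if (length(unique(data$repetition)) < n_repetitions)
    stop("need ", n_repetitions, " repetitions")
  slopes <- vapply(split(data, data$subject), function(d) {
    m <- tapply(d[[measure]], d$repetition, mean)
    r <- as.numeric(names(m))
    sum((r - mean(r)) * (m - mean(m))) / sum((r - mean(r))^2)
  }, numeric(1))
  n <- length(slopes)
  sds <- stats::sd(slopes)
  t <- if (sds == 0 && mean(slopes) == 0) 0 else mean(slopes) / (sds / sqrt(n))
  list(slopes = slopes, t = t, df = n - 1L,
       p = if (is.nan(t)) NA_real_ else 2 * stats::pt(-abs(t), n - 1L))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values and the rejection set at the given level.
#'
#' @param p vector of p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with \code{adjusted} and logical \code{reject}.
#' @export
fdr_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj <= alpha)
}
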