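#' Run the full synthetic memory-updating analysis pipeline
#'
#' End-to-end orchestration: for each synthetic subject, generate the
#' experiment, run the normalization cascade, train the localizer classifiers
#' (with leave-one-run-out cross-validation), decode the updating and test
#' phases, and assign target/competitor/other evidence. At the group level it
#' then computes the updating-phase condition contrast on competitor
#' evidence, the subsequent-memory contrast on target evidence, the
#' final-test 2x2x2 cell table and repeated-measures ANOVA, the
#' nonmonotonic-plasticity fit on RetPrac pairs, and the activation-evidence
#' mixed-model linkage tests.
#'
#' @param config a \code{\link{experiment_config}}.
#' @param n_subjects number of synthetic subjects (default 19).
#' @param seed master seed, fanned out to per-subject and per-stage child
#'   seeds.
#' @param n_curve_samples curve samples for the plasticity fit.
#' @param n_perm permutations for the plasticity permutation test (0 skips
#'   the permutation stage; it is then reported as "skipped").
#' @param stages subset of \code{c("decode", "aggregate", "pcit", "linkage")}
#'   to run; earlier stages required by later ones are always run.
#' @return list of class \code{memupdate_report}; see the methods vignette
#'   for the report layout. Every number in the report is traceable to a
#'   stage and the master seed.
#' @export
run_pipeline <- function(config = experiment_config(), n_subjects = 19L,
                         seed = 1L, n_curve_samples = 10000L, n_perm = 0L,
                         stages = c("decode", "aggregate", "pcit", "linkage")) {
  t_start <- Sys.time()
  seeds <- child_seeds(seed, c(paste0("subject", seq_len(n_subjects)),
                               "pcit", "perm"))
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

  t0 <- tic()
  subjects <- lapply(seq_len(n_subjects), function(s) {
    sid <- sprintf("sub%02d", s)
    exp <- simulate_experiment(config, seed = seeds[[paste0("subject", s)]])
    loc <- preprocess_phase(exp$patterns, "localizer")
    upd <- preprocess_phase(exp$patterns, "updating")
    tst <- preprocess_phase(exp$patterns, "test")
    cv <- crossvalidate(loc$patterns, loc$trials$category, loc$trials$run)
    model <- train_classifier(loc$patterns, loc$trials$category,
                              categories = config$categories)
    ev_upd <- assign_evidence(predict_probs(model, upd$patterns),
                              upd$trials, exp$pairs)
    ev_tst <- assign_evidence(predict_probs(model, tst$patterns),
                              tst$trials, exp$pairs)
    ev_upd$subject <- sid
    ev_tst$subject <- sid
    beh_upd <- exp$behavior[exp$behavior$phase == "updating", ]
    beh_tst <- exp$behavior[exp$behavior$phase == "test", ]
    hist <- label_update_history(beh_upd, config$n_repetitions)
    hist$subject <- sid
    act <- exp$ground_truth$activations
    act$subject <- sid
    # final-test outcome per pair
    ev_tst$outcome <- beh_tst$outcome[match(ev_tst$pair_id, beh_tst$pair_id)]
    ev_upd$final_outcome <- beh_tst$outcome[match(ev_upd$pair_id,
                                                  beh_tst$pair_id)]
    list(subject = sid, cv = cv, evidence_updating = ev_upd,
         evidence_test = ev_tst, history = hist, activations = act,
         behavior = exp$behavior,
         judgment_accuracy = judgment_prediction_accuracy(
           ev_tst$predicted_category, beh_tst$response,
           categories = config$categories))
  })
  timings["decode"] <- toc(t0)

  ev_upd <- do.call(rbind, lapply(subjects, `[[`, "evidence_updating"))
  ev_tst <- do.call(rbind, lapply(subjects, `[[`, "evidence_test"))
  report <- list(
    seed = seed, n_subjects = n_subjects, config = config,
    cv_accuracy = vapply(subjects, function(s) s$cv$mean_accuracy, numeric(1)),
    judgment_accuracy = vapply(subjects, `[[`, numeric(1), "judgment_accuracy"),
    stage_status = c(decode = "ok")
  )

  if ("aggregate" %in% stages) {
    t0 <- tic()
    # updating-phase competitor evidence by condition (per subject)
    upd_cond <- stats::aggregate(competitor_norm ~ subject + condition,
                                 data = ev_upd, FUN = mean)
    wide <- stats::reshape(upd_cond, idvar = "subject",
                           timevar = "condition", direction = "wide")
    report$updating_competitor <- list(
      subject_means = upd_cond,
      contrast = paired_contrast(wide$competitor_norm.RetPrac,
                                 wide$competitor_norm.Restudy))
    # subsequent-memory effect on updating target evidence
    sm <- ev_upd[ev_upd$final_outcome %in% c("target", "competitor"), ]
    sm$outcome_bin <- ifelse(sm$final_outcome == "target",
                             "correct", "incorrect")
    sm_cells <- stats::aggregate(target_norm ~ subject + outcome_bin,
                                 data = sm, FUN = mean)
    sm_wide <- stats::reshape(sm_cells, idvar = "subject",
                              timevar = "outcome_bin", direction = "wide")
    sm_wide <- sm_wide[stats::complete.cases(sm_wide), ]
    report$subsequent_memory <- list(
      subject_means = sm_cells,
      contrast = paired_contrast(sm_wide$target_norm.correct,
                                 sm_wide$target_norm.incorrect))
    # final-test 2 (method) x 2 (outcome) x 2 (evidence) cells + ANOVA
    tt <- ev_tst[ev_tst$outcome %in% c("target", "competitor"), ]
    tt$outcome_bin <- ifelse(tt$outcome == "target", "correct", "incorrect")
    long <- rbind(
      data.frame(subject = tt$subject, method = tt$condition,
                 outcome = tt$outcome_bin, evidence = "target",
                 value = tt$target_norm, stringsAsFactors = FALSE),
      data.frame(subject = tt$subject, method = tt$condition,
                 outcome = tt$outcome_bin, evidence = "competitor",
                 value = tt$competitor_norm, stringsAsFactors = FALSE))
    report$test_cells <- suppressWarnings(
      evidence_cells(long, "value", c("method", "outcome", "evidence")))
    anova_data <- report$test_cells$subject_cells
    names(anova_data)[names(anova_data) == "mean"] <- "value"
    report$test_anova <- tryCatch(
      rm_anova(anova_data, "value", c("method", "outcome", "evidence")),
      error = function(e) e$message)
    # target-evidence trend across updating repetitions
    report$repetition_trend <- repetition_trend(ev_upd, "target_norm",
                                                config$n_repetitions)
    report$stage_status["aggregate"] <- "ok"
    timings["aggregate"] <- toc(t0)
  } else report$stage_status["aggregate"] <- "skipped"

  if ("pcit" %in% stages) {
    t0 <- tic()
    pc <- .pcit_inputs(ev_upd, ev_tst, condition = "RetPrac")
    fit <- tryCatch(
      suppressWarnings(pcit_fit(pc$x, pc$y, n_samples = n_curve_samples,
                                seed = seeds[["pcit"]])),
      error = function(e) e)
    if (inherits(fit, "error")) {
      report$pcit <- list(status = "failed", message = conditionMessage(fit))
      report$stage_status["pcit"] <- "failed"
    } else {
      report$pcit <- list(status = if (fit$fit_ok) "ok" else "fit_failed",
                          fit = fit, n_pairs = length(pc$x))
      report$stage_status["pcit"] <- "ok"
      if (n_perm > 0L) {
        report$pcit$permutation <- pcit_permutation_test(
          pc$x, pc$y, n_perm = n_perm, n_samples = n_curve_samples,
          seed = seeds[["perm"]])
        report$stage_status["pcit_permutation"] <- "ok"
      } else report$stage_status["pcit_permutation"] <- "skipped"
    }
    timings["pcit"] <- toc(t0)
  } else report$stage_status["pcit"] <- "skipped"

  if ("linkage" %in% stages) {
    t0 <- tic()
    hist <- do.call(rbind, lapply(subjects, `[[`, "history"))
    act <- do.call(rbind, lapply(subjects, `[[`, "activations"))
    longterm <- build_longterm_table(act, ev_tst)
    report$linkage <- list(longterm = lmm_lrt(longterm))
    supp <- tryCatch(
      build_suppression_table(ev_upd, act, hist, "FC"),
      error = function(e) e)
    report$linkage$suppression <- if (inherits(supp, "error")) {
      list(status = "failed", message = conditionMessage(supp))
    } else lmm_lrt(supp)
    report$stage_status["linkage"] <- "ok"
    timings["linkage"] <- toc(t0)
  } else report$stage_status["linkage"] <- "skipped"

  report$timings <- timings
  report$wall_clock = as.numeric(Sys.time() - t_start, units = "secs")
  class(report) <- "memupdate_report"
  report
}

# x = per-pair mean updating competitor evidence (min-max normalized over the
# included set), y = final-test competitor evidence minus the pair's mean
# updating competitor evidence (relative change).
.pcit_inputs <- function(ev_upd, ev_tst, condition = "RetPrac") {
  u <- ev_upd[ev_upd$condition == condition, ]
  mu <- stats::aggregate(competitor_norm ~ subject + pair_id, data = u,
                         FUN = mean)
  key <- paste(ev_tst$subject, ev_tst$pair_id)
  idx <- match(paste(mu$subject, mu$pair_id), key)
  keep <- !is.na(idx)
  x_raw <- mu$competitor_norm[keep]
  y <- ev_tst$competitor_norm[idx[keep]] - x_raw
  list(x = normalize_x(x_raw), y = y, x_raw = x_raw)
}

#' @export
print.memupdate_report <- function(x, ...) {
  cat(sprintf("memupdate pipeline report (seed %d, %d subjects)\n",
              x$seed, x$n_subjects))
  cat(sprintf("  decoder CV accuracy: mean %.3f (range %.3f-%.3f)\n",
              mean(x$cv_accuracy), min(x$cv_accuracy), max(x$cv_accuracy)))
  if (!is.null(x$updating_competitor))
    cat(sprintf("  updating competitor evidence RetPrac-Restudy: t(%d) = %.2f, p = %.2g\n",
                x$updating_competitor$contrast$df,
                x$updating_competitor$contrast$t,
                x$updating_competitor$contrast$p))
  if (!is.null(x$pcit) && !is.null(x$pcit$fit))
    cat(sprintf("  P(theory consistent) = %.3f (%s)\n",
                x$pcit$fit$p_theory_consistent, x$pcit$status))
  if (!is.null(x$linkage))
    cat(sprintf("  long-term linkage: chi2(1) = %.2f, p = %.3g\n",
                x$linkage$longterm$chisq, x$linkage$longterm$p))
  cat("  stages:", paste(names(x$stage_status), x$stage_status,
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Save a pipeline report as JSON plus TSV tables
#'
#' @param report a \code{\link{run_pipeline}} report.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  core <- list(
    seed = report$seed, n_subjects = report$n_subjects,
    cv_accuracy = report$cv_accuracy,
    judgment_accuracy = report$judgment_accuracy,
    stage_status = as.list(report$stage_status),
    updating_competitor_contrast = report$updating_competitor$contrast,
    subsequent_memory_contrast = report$subsequent_memory$contrast,
    pcit = if (!is.null(report$pcit$fit)) list(
      p_theory_consistent = report$pcit$fit$p_theory_consistent,
      ess = report$pcit$fit$ess, status = report$pcit$status,
      permutation_p = report$pcit$permutation$p_value),
    linkage = report$linkage, timings = as.list(report$timings))
  jsonlite::write_json(core, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  if (!is.null(report$test_cells))
    utils::write.table(report$test_cells$cells,
                       file.path(dir, "test_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$test_anova) && is.data.frame(report$test_anova))
    utils::write.table(report$test_anova, file.path(dir, "test_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$pcit$fit))
    utils::write.table(report$pcit$fit$mean_curve,
                       file.path(dir, "pcit_mean_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
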