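test_that("response scoring follows association roles in both test kinds", {
  expect_equal(score_response("face", category_B = "scene",
                              category_C = "face"), "target")
  # same response is a competitor in the A-C test but the target in A-B
  expect_equal(score_response("scene", "scene", "face", "AC"), "competitor")
  expect_equal(score_response("scene", "scene", "face", "AB"), "target")
  expect_equal(score_response("object", "scene", "face", "AC",
                              categories = c("face", "object", "scene")),
               "other")
  expect_equal(score_response("dontknow", "scene", "face"), "dontknow")
  expect_error(score_response("banana", "scene", "face",
                              categories = c("face", "object", "scene")),
               "unknown response")
})

test_that("joint A-B/A-C outcome table classifies pairs by enumeration", {
  pairs <- data.frame(
    pair_id = paste0("p", 1:4), cue_id = paste0("c", 1:4),
    category_B = c("face", "face", "scene", "object"),
    category_C = c("scene", "object", "face", "face"),
    condition = c("RetPrac", "RetPrac", "Restudy", "Restudy"))
  ab <- data.frame(pair_id = paste0("p", 1:4),
                   response = c("face", "object", "scene", "face"))
  ac <- data.frame(pair_id = paste0("p", 1:4),
                   response = c("scene", "object", "scene", "face"))
  jt <- joint_outcome_table(ab, ac, pairs)
  # p1: B then C -> correct_both; p2: C in both -> C_both;
  # p3: B in both -> B_both; p4: C in both -> C_both
  expect_equal(jt$cells$joint, c("correct_both", "C_both", "B_both", "C_both"))
  rp <- jt$proportions[jt$proportions$condition == "RetPrac", ]
  expect_equal(rp$correct_both, 0.5)
  expect_equal(rp$C_both, 0.5)
  # all-correct case
  ab2 <- data.frame(pair_id = pairs$pair_id, response = pairs$category_B)
  ac2 <- data.frame(pair_id = pairs$pair_id, response = pairs$category_C)
  jt2 <- joint_outcome_table(ab2, ac2, pairs)
  expect_true(all(jt2$proportions$correct_both == 1))
  expect_error(joint_outcome_table(ab[1:3, ], ac, pairs), "pair set")
})

test_that("independent responses factorize the joint proportions", {
  cfg <- experiment_config(n_pairs = 1000L)
  pairs <- make_pairs(cfg, seed = 2)
  set.seed(3)
  cats <- c("face", "object", "scene")
  ab <- data.frame(pair_id = pairs$pair_id,
                   response = sample(cats, 1000, replace = TRUE))
  ac <- data.frame(pair_id = pairs$pair_id,
                   response = sample(cats, 1000, replace = TRUE))
  jt <- joint_outcome_table(ab, ac, pairs)
  # marginal p(B response) in each test is ~1/3, so joint B_both ~ 1/9
  pooled <- table(factor(jt$cells$joint,
                         c("correct_both", "B_both", "C_both", "other"))) / 1000
  expect_lt(abs(pooled[["B_both"]] - 1 / 9), 3 * sqrt(1 / 9 * 8 / 9 / 1000))
  expect_lt(abs(pooled[["correct_both"]] - 1 / 9),
            3 * sqrt(1 / 9 * 8 / 9 / 1000))
})

test_that("updating history labels encode when a pair first became correct", {
  beh <- data.frame(
    pair_id = rep(c("p1", "p2", "p3", "p4"), each = 3),
    repetition = rep(1:3, 4),
    outcome = c("target", "target", "target",      # FC
                "competitor", "target", "other",   # LC (first correct at 2)
                "other", "other", "competitor",    # IC
                "target", "competitor", "target")) # FC but later lapse
  h <- label_update_history(beh)
  expect_equal(h$history[match(paste0("p", 1:4), h$pair_id)],
               c("FC", "LC", "IC", "FC_lapse"))
  expect_error(label_update_history(beh[-2, ]), "missing repetition")
})

test_that("evidence cells compute subject means and within-subject errors", {
  d <- expand.grid(subject = c("s1", "s2"), method = c("RetPrac", "Restudy"),
                   outcome = c("correct", "incorrect"),
                   stringsAsFactors = FALSE)
  d <- d[rep(seq_len(nrow(d)), each = 2), ]
  set.seed(5)
  d$value <- c(1, 3, 2, 2, 5, 5, 4, 6, 0, 2, 3, 1, 4, 4, 5, 5)
  cells <- evidence_cells(d, "value", c("method", "outcome"))
  # hand check one cell: s1 RetPrac correct trials are the first two values
  sc <- cells$subject_cells
  expect_equal(sc$mean[sc$subject == "s1" & sc$method == "RetPrac" &
                         sc$outcome == "correct"], mean(c(1, 3)))
  # constant shift invariance: means shift, within-subject SEs unchanged
  d2 <- d; d2$value <- d$value + 10
  cells2 <- evidence_cells(d2, "value", c("method", "outcome"))
  expect_equal(cells2$cells$mean, cells$cells$mean + 10)
  expect_equal(cells2$cells$se_within, cells$cells$se_within)
  # a single subject with equal evidence everywhere: SE 0, equal means
  d3 <- d[d$subject == "s1", ]; d3$value <- 2
  cells3 <- evidence_cells(d3, "value", c("method", "outcome"))
  expect_true(all(cells3$cells$mean == 2))
  expect_true(all(cells3$cells$se_within == 0))
  # subjects with empty cells are excluded with a warning
  d4 <- rbind(d, data.frame(subject = "s3", method = "RetPrac",
                            outcome = "correct", value = 1))
  expect_warning(c4 <- evidence_cells(d4, "value", c("method", "outcome")),
                 "s3")
  expect_equal(c4$excluded_subjects, "s3")
})

test_that("paired contrasts match hand-computed t statistics", {
  a <- c(2, 3, 4); b <- c(1, 1, 1)   # differences (1, 2, 3)
  ct <- paired_contrast(a, b)
  expect_equal(ct$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(ct$df, 2L)
  expect_equal(ct$cohens_d, 2)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(ct$t, unname(tt$statistic))
  expect_equal(ct$p, tt$p.value)
  # sign flip negates t, keeps p
  ct2 <- paired_contrast(b, a)
  expect_equal(ct2$t, -ct$t)
  expect_equal(ct2$p, ct$p)
  expect_error(paired_contrast(a, a), "zero variance")
})

test_that("two-level repeated-measures ANOVA matches the aov decomposition", {
  set.seed(7)
  d <- expand.grid(subject = paste0("s", 1:8),
                   A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + ifelse(d$A == "a2", 0.8, 0)
  res <- rm_anova(d, "y", c("A", "B", "C"))
  oracle <- summary(aov(y ~ A * B * C + Error(subject / (A * B * C)),
                        data = transform(d, subject = factor(subject))))
  for (ef in c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")) {
    stratum <- oracle[[paste0("Error: subject:", ef)]][[1]]
    expect_equal(res$F[res$effect == ef], stratum[["F value"]][1],
                 tolerance = 1e-10)
    expect_equal(res$p[res$effect == ef], stratum[["Pr(>F)"]][1],
                 tolerance = 1e-10)
  }
  # injected main effect is detected; a null factor stays null-calibrated
  expect_lt(res$p[res$effect == "A"], 0.05)
  expect_error(rm_anova(d[-1, ], "y", c("A", "B", "C")), "missing cells")
})

test_that("repetition trends recover injected slopes", {
  d <- data.frame(subject = "s1", repetition = 1:3, v = c(0.1, 0.2, 0.3))
  tr <- repetition_trend(d, "v")
  expect_equal(unname(tr$slopes), 0.1, tolerance = 1e-12)
  # constant evidence: slope 0, t 0
  d2 <- expand.grid(subject = c("s1", "s2"), repetition = 1:3)
  d2$v <- 1
  tr2 <- repetition_trend(d2, "v")
  expect_equal(unname(tr2$slopes), c(0, 0))
  expect_equal(tr2$t, 0)
  # injected linear increase of 0.05/repetition recovered within its CI
  set.seed(8)
  d3 <- expand.grid(subject = paste0("s", 1:12), repetition = 1:3,
                    trial = 1:24)
  d3$v <- 0.05 * d3$repetition + rnorm(nrow(d3), 0, 0.2)
  tr3 <- repetition_trend(d3, "v")
  ci <- mean(tr3$slopes) + c(-1, 1) * qt(0.975, tr3$df) *
    sd(tr3$slopes) / sqrt(length(tr3$slopes))
  expect_true(ci[1] < 0.05 && 0.05 < ci[2])
  expect_error(repetition_trend(d, "v", n_repetitions = 4L), "repetitions")
})

test_that("FDR adjustment reproduces the step-up rule", {
  # step-up by hand at alpha = .05, m = 4: thresholds .0125/.025/.0375/.05;
  # 0.04 > 0.0375, so exactly the first two are rejected
  p <- c(0.01, 0.02, 0.04, 0.5)
  f <- fdr_adjust(p)
  expect_equal(f$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(f$adjusted, p.adjust(p, "BH"))
  expect_true(all(fdr_adjust(rep(0, 5))$reject))
  expect_equal(fdr_adjust(0.03)$adjusted, 0.03)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
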