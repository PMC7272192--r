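test_that("pair generation balances conditions and category combinations", {
  cfg <- experiment_config()
  pairs <- make_pairs(cfg, seed = 3)
  expect_equal(nrow(pairs), 144L)
  expect_equal(sum(pairs$condition == "RetPrac"), 72L)
  expect_true(all(pairs$category_B != pairs$category_C))
  combos <- table(paste(pairs$category_B, pairs$category_C))
  expect_equal(length(combos), 6L)
  expect_true(all(combos == 24L))

  # 12 pairs over 3 categories: each ordered combination exactly twice
  p12 <- make_pairs(experiment_config(n_pairs = 12L), seed = 1)
  expect_true(all(table(paste(p12$category_B, p12$category_C)) == 2L))
  expect_equal(sum(p12$condition == "RetPrac"), 6L)

  # two categories leave a single unordered combination
  p2 <- make_pairs(experiment_config(n_pairs = 2L,
                                     categories = c("face", "scene")),
                   seed = 1)
  expect_setequal(paste(p2$category_B, p2$category_C),
                  c("face scene", "scene face"))
  expect_equal(sum(p2$condition == "RetPrac"), 1L)

  expect_error(experiment_config(n_pairs = 143L), "even")
  expect_identical(make_pairs(cfg, seed = 5), make_pairs(cfg, seed = 5))
})

test_that("updating schedules respect run composition and IRI bounds", {
  cfg <- experiment_config()
  pairs <- make_pairs(cfg, seed = 2)
  sch <- make_schedule(cfg, pairs, seed = 4)

  upd <- sch[sch$phase == "updating", ]
  expect_equal(nrow(upd), 6L * 72L)
  for (r in 1:6) {
    run <- upd[upd$run == r, ]
    expect_equal(sort(run$trial), 1:72)
    per_pair <- table(run$pair_id)
    expect_true(all(per_pair == 3L))
    uniq <- run[!duplicated(run$pair_id), ]
    expect_equal(sum(uniq$condition == "RetPrac"), 12L)
    expect_equal(sum(uniq$condition == "Restudy"), 12L)
  }
  gaps <- schedule_iris(sch)
  expect_true(all(gaps$gap >= 10 & gaps$gap <= 36))

  tst <- sch[sch$phase == "test", ]
  expect_equal(as.vector(table(tst$run)), rep(48L, 3L))
  expect_setequal(tst$pair_id, pairs$pair_id)
  expect_equal(anyDuplicated(tst$pair_id), 0L)

  loc <- sch[sch$phase == "localizer", ]
  expect_equal(as.vector(table(loc$category)), rep(72L, 3L))

  expect_identical(make_schedule(cfg, pairs, seed = 9),
                   make_schedule(cfg, pairs, seed = 9))
})

test_that("single-repetition schedules make the IRI constraint vacuous", {
  cfg <- experiment_config(n_pairs = 24L, n_updating_runs = 2L,
                           pairs_per_condition_per_run = 6L,
                           n_repetitions = 1L, n_test_runs = 2L,
                           pairs_per_test_run = 12L, n_localizer_runs = 2L,
                           miniblocks_per_run = 3L)
  sch <- make_schedule(cfg, make_pairs(cfg, seed = 1), seed = 1)
  upd <- sch[sch$phase == "updating", ]
  expect_true(all(table(upd$pair_id) == 1L))
})

test_that("infeasible IRI constraints raise a scheduling error with attempts", {
  cfg <- experiment_config(n_pairs = 8L, n_updating_runs = 2L,
                           pairs_per_condition_per_run = 2L,
                           n_test_runs = 2L, pairs_per_test_run = 4L,
                           n_localizer_runs = 2L, miniblocks_per_run = 3L,
                           iri_min = 11L, iri_max = 12L,
                           max_schedule_retries = 20L)
  # 4 pairs x 3 reps = 12 trials; consecutive-repetition gaps of 11-12 cannot
  # be satisfied for all four pairs simultaneously
  expect_error(make_schedule(cfg, make_pairs(cfg, seed = 1), seed = 1),
               "after 20 attempts")
})

test_that("templates are unit norm, nearly orthogonal, and reproducible", {
  tm <- make_templates(100L, c("face", "object", "scene"), seed = 1)
  expect_equal(unname(sqrt(rowSums(tm^2))), rep(1, 3), tolerance = 1e-12)
  g <- tcrossprod(tm)
  expect_true(max(abs(g[upper.tri(g)])) < 0.2)
  expect_identical(tm, make_templates(100L, c("face", "object", "scene"),
                                      seed = 1))
  tm0 <- make_templates(3L, c("a", "b", "c"), seed = 2, max_abs_cos = 0)
  expect_equal(abs(tm0), diag(3), ignore_attr = TRUE)
  expect_error(make_templates(2L, c("a", "b", "c")), "n_voxels")
})

test_that("noise-free patterns recover generative mixing coefficients", {
  cfg <- small_config(noise_sd = 0)
  exp <- simulate_experiment(cfg, seed = 11)
  tm <- exp$ground_truth$templates
  coefs <- exp$ground_truth$coefficients
  upd <- exp$patterns$trials[exp$patterns$trials$phase == "updating", ]
  for (i in sample(nrow(upd), 10L)) {
    run <- exp$patterns$runs[[paste0("updating_run", upd$run[i])]]
    pat <- pool_trial(run, upd$onset_tr[i], "updating")
    beta <- qr.solve(t(tm), pat)   # least-squares projection onto templates
    pr <- exp$pairs[exp$pairs$pair_id == upd$pair_id[i], ]
    ci <- which(coefs$pair_id == upd$pair_id[i])
    expect_equal(beta[[pr$category_C]],
                 coefs[[paste0("target_upd_rep", upd$repetition[i])]][ci],
                 tolerance = 1e-8)
    expect_equal(beta[[pr$category_B]], coefs$comp_upd[ci], tolerance = 1e-8)
  }
  # localizer trial: pooled pattern exactly the presented category template
  loc <- exp$patterns$trials[exp$patterns$trials$phase == "localizer", ][1, ]
  run <- exp$patterns$runs[[paste0("localizer_run", loc$run)]]
  expect_equal(pool_trial(run, loc$onset_tr, "localizer"),
               unname(tm[loc$category, ]), tolerance = 1e-12)
})

test_that("a null plasticity curve leaves test coefficients at updating levels", {
  cfg <- small_config(noise_sd = 0)
  flat <- pcit_curve(c(0, 1/3, 2/3, 1), c(0, 0, 0, 0))
  pairs <- make_pairs(cfg, seed = 1)
  gt <- make_ground_truth(cfg, pairs, seed = 2, plasticity_curve = flat)
  expect_equal(gt$coefficients$test_comp, gt$coefficients$comp_upd)
})

test_that("a U-shaped generative curve depresses mid-range test coefficients", {
  cfg <- experiment_config()
  pairs <- make_pairs(cfg, seed = 1)
  gt <- make_ground_truth(cfg, pairs, seed = 3)
  co <- gt$coefficients
  change <- co$test_comp - co$comp_upd
  mid <- co$comp_upd_norm > 0.2 & co$comp_upd_norm < 0.5
  hi <- co$comp_upd_norm > 0.9
  expect_true(mean(change[mid]) < mean(change[hi]))
  # direct evaluation of the generative curve matches the applied change
  # wherever clipping at zero does not bind
  unclipped <- co$test_comp > 0
  expect_equal(change[unclipped],
               curve_value(gt$plasticity_curve, co$comp_upd_norm[unclipped]),
               tolerance = 1e-12)
})

test_that("behavioral simulation tracks the configured multinomials", {
  cfg <- experiment_config()
  pairs <- make_pairs(cfg, seed = 5)
  sch <- make_schedule(cfg, pairs, seed = 5)
  beh <- simulate_behavior(sch, pairs, seed = 6)
  upd <- beh[beh$phase == "updating" & beh$condition == "RetPrac", ]
  rate <- tapply(upd$outcome == "target", upd$repetition, mean)
  # repetition 1 near 1/3 chance, repetition 3 markedly higher (n = 72 each)
  expect_lt(abs(rate[["1"]] - 0.35), 3 * sqrt(0.35 * 0.65 / 72))
  expect_lt(abs(rate[["3"]] - 0.85), 3 * sqrt(0.85 * 0.15 / 72))
  expect_gt(rate[["3"]], rate[["1"]] + 0.2)
  rs <- beh[beh$phase == "updating" & beh$condition == "Restudy", ]
  expect_gt(mean(rs$outcome == "target"), 0.95)
  expect_identical(beh, simulate_behavior(sch, pairs, seed = 6))

  # degenerate multinomial: all mass on target
  bp <- default_behavior_params()
  bp$updating$RetPrac[] <- rep(c(1, 0, 0, 0), each = 3)
  bp$updating$Restudy[] <- rep(c(1, 0, 0, 0), each = 3)
  bp$test$RetPrac[] <- c(1, 0, 0, 0)
  bp$test$Restudy[] <- c(1, 0, 0, 0)
  all_t <- simulate_behavior(sch, pairs, behavior_params = bp, seed = 1)
  expect_true(all(all_t$outcome == "target"))

  bad <- default_behavior_params()
  bad$test$RetPrac[1] <- 1.2
  expect_error(simulate_behavior(sch, pairs, behavior_params = bad),
               "probabilities")
})

test_that("events tables round-trip through TSV", {
  cfg <- small_config()
  pairs <- make_pairs(cfg, seed = 1)
  sch <- make_schedule(cfg, pairs, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(sch, path)
  back <- read_events_tsv(path)
  expect_equal(back, sch, ignore_attr = TRUE)
})

test_that("experiment generation is bit-reproducible under a fixed seed", {
  cfg <- small_config()
  e1 <- simulate_experiment(cfg, seed = 123)
  e2 <- simulate_experiment(cfg, seed = 123)
  expect_identical(e1$pairs, e2$pairs)
  expect_identical(e1$schedule, e2$schedule)
  expect_identical(e1$behavior, e2$behavior)
  expect_identical(e1$ground_truth$coefficients, e2$ground_truth$coefficients)
  expect_identical(e1$patterns$runs, e2$patterns$runs)
})
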