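# a compact synthetic condition reused across the protocol tests
small_spec <- function(seed = 1, amp0 = 2, amp1 = 1) {
  synth_spec(C = 8, informative = 1:2, n_per_class = 20, M = 150,
             amp0 = amp0, amp1 = amp1, seed = seed)
}
small_cfg <- function(ranker = "RFS", ...) {
  fccr_config(feature = "TDP", K = 8, ranker = ranker, n_channels = 2,
              seed = 1, ...)
}

test_that("fold assignment is stratified, seeded and reproducible", {
  set.seed(99)               # must not influence the fold function
  labels <- rep(c(0, 1), each = 25)
  f1 <- make_cv_folds(50, labels, 5, 5, seed = 7)
  set.seed(1234)
  f2 <- make_cv_folds(50, labels, 5, 5, seed = 7)
  expect_identical(f1, f2)                       # pure function of inputs
  expect_length(f1, 5)
  for (r in 1:5) {
    expect_setequal(unique(f1[[r]]), 1:5)
    for (f in 1:5) {
      sel <- labels[f1[[r]] == f]
      expect_equal(sum(sel == 0), 5)             # stratified: 5 + 5 per fold
      expect_equal(sum(sel == 1), 5)
    }
  }
  f3 <- make_cv_folds(50, labels, 5, 5, seed = 8)
  expect_false(identical(f1, f3))
})

test_that("the 5x5 protocol yields 25 fold results with coherent aggregates", {
  ts <- generate_synthetic(small_spec(seed = 3))
  cv <- cross_validate(ts, small_cfg(), cv_plan(5, 5, seed = 2))
  expect_equal(nrow(cv$per_fold), 25)
  expect_gte(cv$mean["accuracy"], min(cv$per_fold$accuracy))
  expect_lte(cv$mean["accuracy"], max(cv$per_fold$accuracy))
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 100))
  expect_true(all(cv$sd >= 0))
})

test_that("identical configuration and seed reproduce the report exactly", {
  ts <- generate_synthetic(small_spec(seed = 4))
  cv1 <- cross_validate(ts, small_cfg(), cv_plan(5, 2, seed = 5))
  cv2 <- cross_validate(ts, small_cfg(), cv_plan(5, 2, seed = 5))
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$fits, cv2$fits)
})

test_that("fold splits are shared across methods under one seed", {
  ts <- generate_synthetic(small_spec(seed = 6))
  plan <- cv_plan(5, 1, seed = 11)
  cvA <- cross_validate(ts, small_cfg("RFS"), plan)
  cvB <- cross_validate(ts, small_cfg("SSLSR"), plan)
  expect_identical(cvA$folds, cvB$folds)
  expect_error(compare_rankers(ts, list(
    fccr_config(K = 6, ranker = "RFS", seed = 1),
    fccr_config(K = 6, ranker = "SSLSR", seed = 2)), plan),
    class = "fccr_protocol_error")
})

test_that("null data classifies at chance level over 25 folds", {
  ts <- generate_synthetic(synth_spec(C = 8, informative = 1:2,
                                      n_per_class = 40, M = 150,
                                      amp0 = 1.5, amp1 = 1.5, seed = 8))
  cv <- cross_validate(ts, small_cfg(), cv_plan(5, 5, seed = 3))
  expect_gte(cv$mean["accuracy"], 43)
  expect_lte(cv$mean["accuracy"], 57)
})

test_that("training-stage fits never touch held-out trials", {
  ts <- generate_synthetic(small_spec(seed = 9))
  plan <- cv_plan(5, 1, seed = 13)
  cv1 <- cross_validate(ts, small_cfg(), plan)
  # canary: corrupt the *signals* of the first repeat's fold-1 test trials;
  # folds depend only on (N, labels, seed), so the split is unchanged and
  # every fitted quantity for that fold must be bit-identical
  folds <- make_cv_folds(n_trials(ts), ts$labels, 5, 1, 13)
  te <- which(folds[[1]] == 1)
  ts2 <- ts
  ts2$trials[te, , ] <- 100 * matrix(rnorm(length(te) * 150 * 8),
                                     nrow = length(te))
  cv2 <- cross_validate(ts2, small_cfg(), plan)
  f1 <- cv1$fits[[1]]; f2 <- cv2$fits[[1]]
  expect_identical(f1$ranking, f2$ranking)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$lda_means, f2$lda_means)
  # corrupting held-out labels after the split likewise leaves the fitted
  # stage untouched
  tr <- which(folds[[1]] != 1)
  ft <- extract_features(ts, "TDP")
  lab2 <- ts$labels; lab2[te] <- 1 - lab2[te]
  s1 <- fccr:::fit_fccr_stage(ft, ts$labels, tr, K = 8, ranker = "RFS",
                              n_select = 2, seed = 21)
  s2 <- fccr:::fit_fccr_stage(ft, lab2, tr, K = 8, ranker = "RFS",
                              n_select = 2, seed = 21)
  expect_identical(s1$weights$W, s2$weights$W)
  expect_identical(s1$lda$means, s2$lda$means)
})

test_that("the channel sweep at n = C reproduces the all-channels result", {
  ts <- generate_synthetic(small_spec(seed = 10))
  plan <- cv_plan(5, 1, seed = 17)
  cfg <- small_cfg()
  sw <- channel_sweep(ts, cfg, plan, n_range = c(1, 2, 4, 8))
  expect_equal(nrow(sw$curve), 4)
  cfg_all <- cfg; cfg_all$n_channels <- "all"
  cv_all <- cross_validate(ts, cfg_all, plan)
  expect_equal(sw$curve$accuracy_mean[sw$curve$n == 8],
               unname(cv_all$mean["accuracy"]))
  expect_error(channel_sweep(ts, cfg, plan, n_range = 0:3),
               class = "fccr_bounds_error")
})

test_that("few informative channels carry most of the attainable accuracy", {
  wins <- 0L
  for (s in 1:5) {
    ts <- generate_synthetic(synth_spec(C = 16, informative = 1:3,
                                        n_per_class = 30, M = 200, seed = 60 + s))
    sw <- channel_sweep(ts, fccr_config(K = 20, ranker = "RFS", seed = 1),
                        cv_plan(5, 1, seed = s), n_range = c(1:6, 16))
    peak <- max(sw$curve$accuracy_mean)
    wins <- wins + (max(sw$curve$accuracy_mean[sw$curve$n <= 6]) >= 0.95 * peak)
  }
  expect_gte(wins, 3L)
})

test_that("auto channel selection picks a small subset on informative data", {
  ts <- generate_synthetic(synth_spec(C = 10, informative = 1:2,
                                      n_per_class = 25, M = 150, seed = 70))
  fit <- fccr(ts, config = fccr_config(feature = "TDP", K = 10,
                                       ranker = "RFS", n_channels = "auto",
                                       seed = 2))
  expect_gte(length(fit$selected), 1)
  expect_lte(length(fit$selected), 10)
  p <- predict(fit, ts)
  expect_gte(accuracy(ts$labels, p), 60)
})

test_that("end-to-end runner writes a coherent artifact set", {
  ts <- generate_synthetic(small_spec(seed = 12))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ts.bin")
  save_trialset(ts, p)
  cv <- run_fccr(p, small_cfg(), cv_plan(5, 1, seed = 19),
                 out_dir = file.path(dir, "out"))
  expect_s3_class(cv, "fccr_cv")
  expect_true(file.exists(file.path(dir, "out", "report.json")))
  expect_true(file.exists(file.path(dir, "out", "folds.csv")))
  expect_true(file.exists(file.path(dir, "out", "rankings.csv")))
  expect_true(file.exists(file.path(dir, "out", "run_log.json")))
  rep <- jsonlite::read_json(file.path(dir, "out", "report.json"))
  expect_equal(rep$n_folds, 5)
  expect_equal(rep$mean$accuracy, unname(cv$mean["accuracy"]))
  # determinism of the full runner
  cv2 <- run_fccr(p, small_cfg(), cv_plan(5, 1, seed = 19))
  expect_identical(cv$per_fold, cv2$per_fold)
})

test_that("comparing rankers tabulates all methods on identical folds", {
  ts <- generate_synthetic(small_spec(seed = 14))
  plan <- cv_plan(5, 1, seed = 23)
  cfgs <- list(RFS = small_cfg("RFS"), SSLSR = small_cfg("SSLSR"))
  cmp <- compare_rankers(ts, cfgs, plan)
  expect_equal(nrow(cmp$table), 2)
  expect_identical(cmp$reports$RFS$folds, cmp$reports$SSLSR$folds)
  solo <- cross_validate(ts, cfgs$RFS, plan)
  expect_equal(cmp$reports$RFS$mean, solo$mean)
})
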