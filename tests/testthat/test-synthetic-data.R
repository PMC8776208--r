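test_that("the same seed reproduces the cohort bit-for-bit", {
  cfg <- sim_config(seed = 101)
  a <- suppressMessages(simulate_cohort(cfg))
  b <- suppressMessages(simulate_cohort(cfg))
  expect_identical(a$nightly, b$nightly)
  expect_identical(a$ema, b$ema)
  expect_identical(a$responses, b$responses)
  expect_identical(a$truth, b$truth)
})

test_that("the default design yields the study-scale cohort", {
  co <- suppressMessages(simulate_cohort(sim_config(seed = 102)))
  expect_identical(length(unique(co$nightly$participant_id)), 9L)
  # windows = questionnaires - 1, summed over participants
  nq <- table(co$scores$participant_id)
  expect_identical(nrow(co$truth), sum(nq - 1L))
  expect_identical(nrow(co$truth), 47L)
  expect_identical(nrow(co$scores), 56L)
})

test_that("degenerate noise gives a near-constant nightly series", {
  set.seed(103)
  s <- simulate_nightly(35, 4, 0, 0, noise_sd = 0.001, sigma_min = 1e-4)
  expect_lt(sd(s$ln_rmssd), 0.002)
  d <- as.Date("2020-07-01") + s$day
  expect_lt(max(rolling_sd(d, s$ln_rmssd), na.rm = TRUE), 0.003)
})

test_that("nightly missingness concentrates at the configured rate", {
  set.seed(104)
  s <- simulate_nightly(20000, 4, 0, 0, missing_rate = 0.057)
  expect_lt(abs(mean(is.na(s$ln_rmssd)) - 0.057), 0.01)
})

test_that("a positive dispersion slope induces an HRVsd uptrend", {
  set.seed(105)
  pos <- 0L
  reps <- 100
  d <- as.Date("2020-07-01") + 0:34
  for (r in seq_len(reps)) {
    s <- simulate_nightly(35, 4, 0, 0.004, noise_sd = 0.08)
    hs <- rolling_sd(d, s$ln_rmssd)
    if (trend_beta(d, hs)$beta > 0) pos <- pos + 1L
  }
  expect_gte(pos / reps, 0.95)
})

test_that("null effects leave latent slopes uncorrelated with changes", {
  cfg0 <- sim_config(gamma = c(hrv = 0, hrvsd = 0, int = 0, tst = 0,
                               mvpa = 0, alcohol = 0), seed = 106)
  # direct window-level route at n = 1000 for a tight bound
  w <- simulate_windows(1000, gamma = c(hrv = 0, hrvsd = 0, int = 0,
                                        tst = 0, mvpa = 0, alcohol = 0),
                        outcome_noise_sd = 1, seed = 106)
  for (v in c("hrv_uptrend", "hrvsd_uptrend", "tst_uptrend"))
    expect_lt(abs(cor(w[[v]], w$stress_increase)), 0.07)
  # and through the cohort's discretized questionnaire layer
  co <- suppressMessages(simulate_cohort(cfg0))
  expect_lt(abs(cor(co$truth$z_hrvsd, co$truth$delta_stress)), 0.3)
})

test_that("a total floor yields all-zero scores that get flagged", {
  cfg <- sim_config(floor_zero_prob = 1, seed = 107)
  co <- suppressMessages(simulate_cohort(cfg))
  expect_true(all(co$scores$depression == 0))
  expect_true(all(co$scores$anxiety == 0))
  expect_true(floor_effect_check(co$scores$depression)$flagged)
})

test_that("generated scores respect 4DSQ bounds and round-trip through
           item responses", {
  co <- suppressMessages(simulate_cohort(sim_config(seed = 108)))
  expect_true(all(co$scores$stress >= 0 & co$scores$stress <= 32))
  expect_true(all(co$scores$depression >= 0 & co$scores$depression <= 10))
  expect_true(all(co$scores$anxiety >= 0 & co$scores$anxiety <= 24))
  expect_true(all(co$scores$somatisation >= 0 &
                    co$scores$somatisation <= 32))
  rescored <- score_4dsq_table(co$responses)
  expect_equal(rescored$stress, co$scores$stress)
  expect_equal(rescored$depression, co$scores$depression)
  expect_equal(rescored$anxiety, co$scores$anxiety)
  expect_equal(rescored$somatisation, co$scores$somatisation)
})

test_that("synthetic IBI nights hit their target RMSSD and carry
           detectable ectopics", {
  set.seed(109)
  night <- simulate_ibi_night(40, duration_minutes = 60, ectopic_rate = 0.03)
  lab <- flag_artifacts(night$ibi_ms)
  expect_gt(mean(lab == "abnormal"), 0.005)
  res <- process_night(night$t_seconds, night$ibi_ms)
  expect_lt(abs(res$rmssd_ms - 40) / 40, 0.25)
})

test_that("the end-to-end pipeline recovers configured effects from a
           large cohort", {
  # scale the design up (many participants) so estimation noise in the
  # trends averages out; effects on hrvsd and the buffering interaction
  cfg <- sim_config(n_participants = 40,
                    weeks_per_participant = rep(25, 40),
                    gamma = c(hrv = 0, hrvsd = 0.5, int = -0.4, tst = 0,
                              mvpa = 0, alcohol = 0),
                    seed = 110)
  co <- suppressMessages(simulate_cohort(cfg))
  daily <- build_daily_table(co$nightly, co$ema, co$activity)
  scores <- score_4dsq_table(co$responses)
  win <- suppressWarnings(assemble_windows(daily, scores))
  fit <- suppressMessages(
    fit_hierarchical(win, "stress_increase"))
  b <- coef(fit, step = 3)
  expect_gt(b[["hrvsd_uptrend"]], 0.1) # attenuated but clearly positive
  expect_lt(b[[".interaction"]], 0)
  expect_gt(fit$steps[[2]]$r.squared, fit$steps[[1]]$r.squared)
})
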