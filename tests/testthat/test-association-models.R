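std_vars <- c("stress_increase", "tst_uptrend", "mvpa_uptrend",
              "alcohol_uptrend", "hrv_uptrend", "hrvsd_uptrend")

test_that("grand-mean standardization yields mean-0 SD-1 columns", {
  set.seed(51)
  w <- simulate_windows(40, seed = 51)
  s <- standardize(w, std_vars)
  for (v in std_vars) {
    expect_equal(mean(s$data[[v]]), 0, tolerance = 1e-9)
    expect_equal(sd(s$data[[v]]), 1, tolerance = 1e-9)
  }
  # {1,2,3} -> {-1,0,1} with sample SD 1
  tiny <- data.frame(x = c(1, 2, 3))
  expect_equal(standardize(tiny, "x")$data$x, c(-1, 0, 1))
  expect_error(standardize(data.frame(x = rep(2, 5)), "x"), "x")
})

test_that("incomplete windows are excluded listwise with a report", {
  w <- simulate_windows(20, seed = 52)
  w$hrvsd_uptrend[c(3, 11)] <- NA
  expect_message(s <- standardize(w, std_vars), "2 incomplete")
  expect_identical(s$n, 18L)
  expect_identical(s$dropped, c(3L, 11L))
})

test_that("hierarchical fit reproduces the normal-equations oracle", {
  set.seed(53)
  for (rep in 1:10) {
    w <- simulate_windows(50)
    fit <- fit_hierarchical(w, "stress_increase")
    z <- scale(as.matrix(w[std_vars]))
    y <- z[, "stress_increase"]
    X3 <- cbind(1, z[, c("tst_uptrend", "mvpa_uptrend", "alcohol_uptrend",
                         "hrv_uptrend", "hrvsd_uptrend")],
                z[, "hrv_uptrend"] * z[, "hrvsd_uptrend"])
    expect_equal(unname(coef(fit, step = 3)),
                 unname(oracle_lm_coefs(X3, y)), tolerance = 1e-8)
    X1 <- X3[, 1:4]
    expect_equal(unname(coef(fit, step = 1)),
                 unname(oracle_lm_coefs(X1, y)), tolerance = 1e-8)
    r2 <- vapply(fit$steps, `[[`, numeric(1), "r.squared")
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("a dominant HRVsd effect is recovered on synthetic windows", {
  w <- simulate_windows(500, gamma = c(hrv = 0, hrvsd = 0.6, int = 0,
                                       tst = 0, mvpa = 0, alcohol = 0),
                        outcome_noise_sd = 0.8, seed = 54)
  fit <- fit_hierarchical(w, "stress_increase")
  b2 <- coef(fit, step = 2)
  expect_lt(abs(b2[["hrvsd_uptrend"]] - 0.6), 0.1)
})

test_that("a pure-noise outcome shows near-zero R-squared at large n", {
  w <- simulate_windows(500, gamma = c(hrv = 0, hrvsd = 0, int = 0,
                                       tst = 0, mvpa = 0, alcohol = 0),
                        outcome_noise_sd = 1, seed = 55)
  fit <- fit_hierarchical(w, "stress_increase")
  expect_lt(fit$steps[[3]]$r.squared, 0.05)
})

test_that("floor-flagged outcomes are refused unless forced", {
  w <- simulate_windows(47, seed = 56)
  fc <- floor_effect_check(rep(0, 56))
  expect_error(fit_hierarchical(w, "stress_increase", floor_check = fc),
               "no models could be formed")
  expect_s3_class(fit_hierarchical(w, "stress_increase", floor_check = fc,
                                   force = TRUE), "hrv_hfit")
})

test_that("simple slopes follow the covariance identity and the
           re-centred refit oracle", {
  w <- simulate_windows(200, seed = 57)
  fit <- fit_hierarchical(w, "stress_increase")
  ss <- simple_slopes(fit, moderator_values = c(-1, 0, 0.7, 1))
  b3 <- coef(fit, step = 3)

  # at moderator 0 the conditional slope is the step-3 focal coefficient
  expect_equal(ss$slope[ss$moderator == 0],
               unname(b3["hrvsd_uptrend"]), tolerance = 1e-12)

  # beta_focal + h * beta_int identity
  expect_equal(ss$slope,
               unname(b3["hrvsd_uptrend"] + ss$moderator * b3[".interaction"]),
               tolerance = 1e-12)

  # re-centring oracle: shift the moderator by h and refit; the focal
  # main effect and its SE must match the conditional slope at h
  h <- 0.7
  dat <- fit$fits[[3]]$model
  dat$hrv_c <- dat$hrv_uptrend - h
  ref <- lm(stress_increase ~ tst_uptrend + mvpa_uptrend + alcohol_uptrend +
              hrv_c + hrvsd_uptrend + hrv_c:hrvsd_uptrend, data = dat)
  sm <- summary(ref)$coefficients
  expect_equal(ss$slope[ss$moderator == h],
               sm["hrvsd_uptrend", "Estimate"], tolerance = 1e-10)
  expect_equal(ss$se[ss$moderator == h],
               sm["hrvsd_uptrend", "Std. Error"], tolerance = 1e-10)
})

test_that("cluster-robust variant changes SEs, not coefficients", {
  w <- simulate_windows(60, seed = 58)
  w$participant_id <- rep(sprintf("P%02d", 1:6), each = 10)
  plain <- fit_hierarchical(w, "stress_increase")
  cl <- fit_hierarchical(w, "stress_increase", cluster = "participant_id")
  expect_equal(coef(cl), coef(plain), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    cl$steps[[3]]$coefficients[, "Std. Error"],
    plain$steps[[3]]$coefficients[, "Std. Error"])))
})

test_that("correlation table gives Pearson r with sensible extremes", {
  set.seed(59)
  d <- data.frame(a = rnorm(1000))
  d$b <- -d$a
  d$c <- rnorm(1000)
  ct <- correlation_table(d, c("a", "b", "c"))
  expect_equal(ct$r["a", "a"], 1)
  expect_equal(ct$r["a", "b"], -1, tolerance = 1e-12)
  expect_lt(abs(ct$r["a", "c"]), 0.1) # independent columns
  expect_identical(ct$stars["a", "b"], "***")
})

test_that("model comparison reports both delta-F flavours", {
  w <- simulate_windows(100, seed = 60)
  fit <- fit_hierarchical(w, "stress_increase")
  cmp <- fit$comparisons[[2]]
  f2 <- fit$steps[[2]]$fstatistic; f3 <- fit$steps[[3]]$fstatistic
  expect_equal(cmp$dF_diff, f3 - f2, tolerance = 1e-12)
  an <- anova(fit$fits[[2]], fit$fits[[3]])
  expect_equal(cmp$partial_F, an$F[2], tolerance = 1e-12)
  expect_equal(cmp$p, an$`Pr(>F)`[2], tolerance = 1e-12)
  # print/summary render without error
  expect_output(print(fit), "Hierarchical regression")
  expect_output(print(summary(fit)), "Step 3")
})

test_that("predictions back-transform to outcome units", {
  w <- simulate_windows(120, seed = 61)
  fit <- fit_hierarchical(w, "stress_increase")
  pr <- predict(fit)
  expect_length(pr, fit$n)
  # training predictions = fitted values mapped back to original units
  z <- (w$stress_increase - fit$center[["stress_increase"]]) /
    fit$scale[["stress_increase"]]
  expect_equal(cor(pr, w$stress_increase) > 0, TRUE)
  new1 <- w[3, c("tst_uptrend", "mvpa_uptrend", "alcohol_uptrend",
                 "hrv_uptrend", "hrvsd_uptrend")]
  expect_equal(unname(predict(fit, new1)), unname(pr[3]),
               tolerance = 1e-10)
})
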