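test_that("artifact labelling follows the neighbour-median deviation rule", {
  # constant series: zero deviation everywhere
  expect_true(all(flag_artifacts(rep(1000, 100)) == "normal"))

  # a single gross outlier among steady beats is the only abnormal label
  x <- rep(800, 40); x[17] <- 2000
  lab <- flag_artifacts(x)
  expect_identical(which(lab == "abnormal"), 17L)

  # small physiological jitter stays normal (max rel. deviation ~0.006)
  expect_true(all(flag_artifacts(c(900, 905, 910)) == "normal"))

  expect_error(flag_artifacts(numeric(0)), "no intervals")
  expect_error(flag_artifacts(c(800, -5, 900)), "positive")
})

test_that("artifact labelling matches the brute-force oracle, edges included", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(3:60, 1)
    x <- rnorm(n, 900, 60)
    sp <- runif(n) < 0.1 # irregular spikes
    x[sp] <- x[sp] * 1.8
    x <- pmax(x, 300)
    expect_identical(flag_artifacts(x), oracle_flag(x))
  }
})

test_that("relabelling the normal subset flags nothing new", {
  set.seed(42)
  x <- rnorm(300, 950, 25)
  x[c(50, 180)] <- 2400 # lone outliers are the only violations
  lab <- flag_artifacts(x)
  kept <- x[lab == "normal"]
  expect_true(all(flag_artifacts(kept) == "normal"))
})

test_that("night segmentation tiles the night half-open by timestamp", {
  t10 <- seq(0, 599, by = 1); ib <- rep(1000, length(t10))
  segs <- segment_night(t10, ib, rep("normal", length(t10)))
  expect_length(segs, 2L)

  t12 <- seq(0, 719, by = 1)
  segs <- segment_night(t12, rep(1000, length(t12)),
                        rep("normal", length(t12)))
  expect_length(segs, 3L) # last one partial

  # all-abnormal labels zero every validity fraction
  segs <- segment_night(t10, ib, rep("abnormal", length(t10)))
  expect_true(all(vapply(segs, `[[`, numeric(1),
                         "validity_fraction") == 0))
})

test_that("nightly RMSSD averages valid segments and handles degeneracy", {
  # hand example: sqrt((10^2 + (-20)^2)/2) = sqrt(250)
  expect_equal(rmssd(c(1000, 1010, 990)), sqrt(250))

  mk_seg <- function(x) list(normal_ibis = x, n_ibis = length(x),
                             n_normal = length(x), validity_fraction = 1)
  # two valid segments with RMSSD 20 and 40 average to 30
  s1 <- mk_seg(c(1000, 1020, 1000, 1020)) # diffs 20 -> RMSSD 20
  s2 <- mk_seg(c(1000, 1040, 1000, 1040)) # diffs 40 -> RMSSD 40
  res <- nightly_rmssd(list(s1, s2), min_normal_ibis = 2)
  expect_equal(res$rmssd_ms, 30)
  expect_equal(res$ln_rmssd, log(30))
  expect_identical(res$n_valid_segments, 2L)

  # constant segment: zero RMSSD is a missing night, not a log of zero
  expect_warning(
    res0 <- nightly_rmssd(list(mk_seg(rep(1000, 40))), min_normal_ibis = 2),
    "missing")
  expect_true(is.na(res0$ln_rmssd))

  # no valid segment: missing night without an exception
  low <- list(normal_ibis = c(1000, 1010), n_ibis = 40, n_normal = 2,
              validity_fraction = 0.05)
  resna <- nightly_rmssd(list(low))
  expect_true(is.na(resna$rmssd_ms))
  expect_identical(resna$n_valid_segments, 0L)
})

test_that("segment RMSSD is translation-invariant and scale-equivariant", {
  set.seed(7)
  x <- rnorm(200, 1000, 35)
  expect_equal(rmssd(x + 250), rmssd(x))
  expect_equal(rmssd(3.5 * x), 3.5 * rmssd(x))
})

test_that("full-night processing equals the explicit-loop oracle", {
  set.seed(99)
  for (rep in 1:20) {
    night <- random_ibi_night(runif(1, 10, 25))
    lab <- flag_artifacts(night$ibi)
    segs <- segment_night(night$t, night$ibi, lab)
    got <- nightly_rmssd(segs, 0.5, 30)
    want <- oracle_night_rmssd(night$t, night$ibi, lab, 5, 0.5, 30)
    if (is.na(want)) expect_true(is.na(got$rmssd_ms))
    else expect_equal(got$rmssd_ms, want, tolerance = 1e-12)
  }
})

test_that("multi-night table processes each (participant, night) once", {
  set.seed(5)
  nights <- do.call(rbind, lapply(1:3, function(k) {
    nt <- random_ibi_night(12)
    data.frame(participant_id = "P01",
               night_date = as.Date("2020-07-01") + k,
               t_seconds = nt$t, ibi_ms = nt$ibi)
  }))
  tab <- nightly_hrv_table(nights)
  expect_identical(nrow(tab), 3L)
  expect_true(all(is.finite(tab$rmssd_ms)))
  expect_equal(tab$ln_rmssd, log(tab$rmssd_ms))
  expect_true(all(tab$n_valid_segments <= tab$n_total_segments))
})
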