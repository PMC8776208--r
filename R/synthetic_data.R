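# Synthetic cohort generator: drifting nightly lnRMSSD level and
# dispersion, wearable/EMA missingness, and five-weekly 4DSQ outcomes
# driven by the latent trends.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: 9 participants
#' observed 15-55 weeks with questionnaires every 35 days (yielding 47
#' five-week windows and 56 questionnaires under full adherence), ~94.3%
#' nightly HRV completeness and ~89% EMA completeness, latent per-window
#' linear trends in the level and dispersion of nightly lnRMSSD, and
#' questionnaire change scores generated on the standardized scale from
#' those trends with configurable effect sizes `gamma`. Depression and
#' anxiety are zero-inflated to reproduce floor effects.
#'
#' @param n_participants number of participants (default 9).
#' @param weeks_per_participant weeks of data per participant (multiples
#'   of 5).
#' @param questionnaire_interval_days days between questionnaires
#'   (default 35).
#' @param baseline_ln_rmssd_mean,baseline_ln_rmssd_sd between-participant
#'   baseline lnRMSSD distribution (ln ms; default 4.0 / 0.3, i.e. RMSSD
#'   around 55 ms).
#' @param level_slope_sd SD of the per-window lnRMSSD level trend
#'   (ln ms per day, default 0.004).
#' @param disp_slope_sd SD of the per-window nightly-noise-SD trend
#'   (per day, default 0.002).
#' @param nightly_noise_sd baseline SD of nightly lnRMSSD around its
#'   trend line (default 0.12).
#' @param sigma_min lower truncation for the nightly noise SD
#'   (default 0.01).
#' @param hrv_missing_rate iid nightly HRV missingness (default 0.057).
#' @param ema_missing_rate iid daily EMA missingness (default 0.11).
#' @param gamma named standardized effect sizes on the outcome change:
#'   `hrv`, `hrvsd`, `int` (their product), `tst`, `mvpa`, `alcohol`.
#' @param outcome_noise_sd residual SD of the standardized outcome change
#'   (default 0.8).
#' @param change_points_per_sd questionnaire points per standardized
#'   change unit when discretizing (default 3).
#' @param stress_baseline,somatisation_baseline first-questionnaire scores.
#' @param floor_zero_prob zero-inflation probability for depression and
#'   anxiety scores (default 0.9).
#' @param tst_mean,tst_noise_sd,tst_slope_sd total-sleep-time process
#'   (minutes).
#' @param mvpa_mean,mvpa_noise_sd,mvpa_slope_sd activity process
#'   (minutes/day at >= 3 MET).
#' @param alcohol_lambda,alcohol_slope_sd daily drink-count Poisson
#'   process.
#' @param seed integer seed; fully determines the cohort.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 9L,
                       weeks_per_participant = c(15, 20, 20, 20, 25, 25, 25, 30, 55),
                       questionnaire_interval_days = 35L,
                       baseline_ln_rmssd_mean = 4.0,
                       baseline_ln_rmssd_sd = 0.3,
                       level_slope_sd = 0.004,
                       disp_slope_sd = 0.002,
                       nightly_noise_sd = 0.12,
                       sigma_min = 0.01,
                       hrv_missing_rate = 0.057,
                       ema_missing_rate = 0.11,
                       gamma = c(hrv = -0.1, hrvsd = 0.5, int = -0.4,
                                 tst = 0, mvpa = -0.2, alcohol = 0),
                       outcome_noise_sd = 0.8,
                       change_points_per_sd = 3,
                       stress_baseline = 8L,
                       somatisation_baseline = 6L,
                       floor_zero_prob = 0.9,
                       tst_mean = 420, tst_noise_sd = 25, tst_slope_sd = 0.3,
                       mvpa_mean = 40, mvpa_noise_sd = 12, mvpa_slope_sd = 0.2,
                       alcohol_lambda = 0.8, alcohol_slope_sd = 0.01,
                       seed = 20260101L) {
  cfg <- as.list(environment())
  if (length(cfg$weeks_per_participant) != cfg$n_participants)
    stop("weeks_per_participant must have n_participants entries")
  rates <- c(cfg$hrv_missing_rate, cfg$ema_missing_rate, cfg$floor_zero_prob)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (cfg$questionnaire_interval_days < 7L)
    stop("questionnaire interval must be at least 7 days")
  need <- c("hrv", "hrvsd", "int", "tst", "mvpa", "alcohol")
  if (!all(need %in% names(cfg$gamma)))
    stop("gamma must name: ", paste(need, collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_participants, "participants,",
      paste(range(x$weeks_per_participant), collapse = "-"), "weeks,",
      "questionnaires every", x$questionnaire_interval_days, "days\n")
  cat("gamma:", paste(names(x$gamma), formatC(x$gamma), sep = "=",
                      collapse = ", "), "\n")
  invisible(x)
}

#' Simulate one window of nightly lnRMSSD
#'
#' `ln_rmssd(t) = baseline + level_slope * t + eps(t)` with
#' `eps(t) ~ Normal(0, sigma(t))` and
#' `sigma(t) = noise_sd + disp_slope * t`, truncated below at `sigma_min`
#' (with a warning when truncation bites). Nights are then removed iid at
#' `missing_rate`. Uses the current RNG state.
#'
#' @param n_days number of nights.
#' @param baseline lnRMSSD at day 0 (ln ms).
#' @param level_slope level trend, ln ms per day.
#' @param disp_slope dispersion trend, SD units per day.
#' @param noise_sd baseline nightly noise SD.
#' @param sigma_min noise-SD floor.
#' @param missing_rate iid missingness.
#' @return data frame: `day` (0-based), `ln_rmssd` (`NA` when missing).
#' @export
simulate_nightly <- function(n_days, baseline, level_slope, disp_slope,
                             noise_sd = 0.12, sigma_min = 0.01,
                             missing_rate = 0) {
  t <- seq_len(n_days) - 1
  sigma <- noise_sd + disp_slope * t
  if (any(sigma < sigma_min)) {
    warning("nightly noise SD truncated at sigma_min for ",
            sum(sigma < sigma_min), " night(s)")
    sigma <- pmax(sigma, sigma_min)
  }
  y <- baseline + level_slope * t + stats::rnorm(n_days, 0, sigma)
  y[stats::runif(n_days) < missing_rate] <- NA_real_
  data.frame(day = t, ln_rmssd = y)
}

# distribute an integer scale score over its items: full-score items first
.items_from_score <- function(score, n_items) {
  items <- rep("no", n_items)
  q <- score %/% 2L
  r <- score %% 2L
  if (q > 0) items[seq_len(q)] <- "regularly"
  if (r > 0) items[q + 1L] <- "sometimes"
  items
}

# map one scores row to 50 item responses under the default layout
.responses_from_scores <- function(scores, scale_map = fdsq_default_map()) {
  items <- rep("no", 50L)
  for (sc in .fdsq_scale_names) {
    idx <- which(!is.na(scale_map) & scale_map == sc)
    items[idx] <- .items_from_score(scores[[sc]], length(idx))
  }
  items
}

#' Simulate questionnaire scores from latent window trends
#'
#' The standardized outcome change for each window is
#' `delta = gamma . (z_hrv, z_hrvsd, z_hrv*z_hrvsd, z_tst, z_mvpa, z_alc)
#' + Normal(0, outcome_noise_sd)`; stress and somatisation scores follow a
#' cumulative path, `score[k+1] = clip(round(score[k] +
#' delta * change_points_per_sd))` within scale bounds (clipping is
#' logged via a message). Depression and anxiety are zero-inflated: zero
#' with probability `floor_zero_prob`, else a small positive count —
#' reproducing the floor effects that preclude modelling those scales.
#' Uses the current RNG state.
#'
#' @param config a [sim_config()].
#' @param latent_slopes data frame with one row per window per
#'   participant, ordered, with columns `participant_id` and standardized
#'   slopes `z_hrv`, `z_hrvsd`, `z_tst`, `z_mvpa`, `z_alcohol`.
#' @param q_dates list of questionnaire `Date` vectors, one per
#'   participant (names = participant ids).
#' @return list: `scores` (data frame per questionnaire), `deltas` (the
#'   realized standardized changes per window, for recovery tests).
#' @export
simulate_outcomes <- function(config, latent_slopes, q_dates) {
  g <- config$gamma
  rows <- list(); drows <- list()
  for (id in names(q_dates)) {
    ls <- latent_slopes[latent_slopes$participant_id == id, , drop = FALSE]
    nq <- length(q_dates[[id]])
    stopifnot(nrow(ls) == nq - 1L)
    stress <- config$stress_baseline
    soma <- config$somatisation_baseline
    clipped <- 0L
    sc <- data.frame(participant_id = id, date = q_dates[[id]],
                     stress = NA_real_, depression = NA_real_,
                     anxiety = NA_real_, somatisation = NA_real_,
                     stringsAsFactors = FALSE)
    dl <- data.frame(participant_id = id, window = seq_len(nq - 1L),
                     delta_stress = NA_real_, delta_somatisation = NA_real_)
    for (k in seq_len(nq)) {
      sc$stress[k] <- stress
      sc$somatisation[k] <- soma
      sc$depression[k] <- if (stats::runif(1) < config$floor_zero_prob) 0 else
        min(1 + stats::rpois(1, 0.7), .fdsq_max[["depression"]])
      sc$anxiety[k] <- if (stats::runif(1) < config$floor_zero_prob) 0 else
        min(1 + stats::rpois(1, 0.7), .fdsq_max[["anxiety"]])
      if (k == nq) break
      lin <- g[["hrv"]] * ls$z_hrv[k] + g[["hrvsd"]] * ls$z_hrvsd[k] +
        g[["int"]] * ls$z_hrv[k] * ls$z_hrvsd[k] +
        g[["tst"]] * ls$z_tst[k] + g[["mvpa"]] * ls$z_mvpa[k] +
        g[["alcohol"]] * ls$z_alcohol[k]
      d_st <- lin + stats::rnorm(1, 0, config$outcome_noise_sd)
      d_so <- lin + stats::rnorm(1, 0, config$outcome_noise_sd)
      dl$delta_stress[k] <- d_st
      dl$delta_somatisation[k] <- d_so
      new_st <- round(stress + d_st * config$change_points_per_sd)
      new_so <- round(soma + d_so * config$change_points_per_sd)
      if (new_st < 0 || new_st > .fdsq_max[["stress"]] ||
          new_so < 0 || new_so > .fdsq_max[["somatisation"]])
        clipped <- clipped + 1L
      stress <- min(max(new_st, 0), .fdsq_max[["stress"]])
      soma <- min(max(new_so, 0), .fdsq_max[["somatisation"]])
    }
    if (clipped > 0L)
      message("participant ", id, ": ", clipped,
              " score step(s) clipped to scale bounds")
    rows[[id]] <- sc
    drows[[id]] <- dl
  }
  list(scores = do.call(rbind, c(rows, make.row.names = FALSE)),
       deltas = do.call(rbind, c(drows, make.row.names = FALSE)))
}

#' Simulate window-level samples directly
#'
#' Direct generator at the unit of analysis: standardized trend vectors
#' are drawn iid standard normal and the continuous standardized outcome
#' change is formed from `gamma` plus noise. This bypasses the daily
#' measurement layer (no estimation error in the trends), which is the
#' right fixture for calibrating the regression engine's parameter
#' recovery.
#'
#' @param n number of windows.
#' @param gamma named effects as in [sim_config()].
#' @param outcome_noise_sd residual SD (default 0.8).
#' @param outcome_name outcome column name (default `"stress_increase"`).
#' @param seed optional seed.
#' @return data frame with `hrv_uptrend`, `hrvsd_uptrend`, `tst_uptrend`,
#'   `mvpa_uptrend`, `alcohol_uptrend` and the outcome column.
#' @export
simulate_windows <- function(n, gamma = c(hrv = -0.1, hrvsd = 0.5,
                                          int = -0.4, tst = 0, mvpa = -0.2,
                                          alcohol = 0),
                             outcome_noise_sd = 0.8,
                             outcome_name = "stress_increase",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- replicate(5, stats::rnorm(n))
  colnames(z) <- c("hrv", "hrvsd", "tst", "mvpa", "alcohol")
  y <- gamma[["hrv"]] * z[, "hrv"] + gamma[["hrvsd"]] * z[, "hrvsd"] +
    gamma[["int"]] * z[, "hrv"] * z[, "hrvsd"] +
    gamma[["tst"]] * z[, "tst"] + gamma[["mvpa"]] * z[, "mvpa"] +
    gamma[["alcohol"]] * z[, "alcohol"] +
    stats::rnorm(n, 0, outcome_noise_sd)
  out <- data.frame(hrv_uptrend = z[, "hrv"], hrvsd_uptrend = z[, "hrvsd"],
                    tst_uptrend = z[, "tst"], mvpa_uptrend = z[, "mvpa"],
                    alcohol_uptrend = z[, "alcohol"])
  out[[outcome_name]] <- y
  out
}

#' Simulate one night of inter-beat intervals
#'
#' Gaussian inter-beat-interval series calibrated to a target RMSSD
#' (intervals iid around `mean_ibi_ms` with SD `target_rmssd_ms/sqrt(2)`,
#' so the expected RMSSD equals the target), with a fraction of injected
#' ectopic-like beats (interval multiplied by `ectopic_factor`) to
#' exercise the artifact screen. Uses the current RNG state.
#'
#' @param target_rmssd_ms target RMSSD (ms).
#' @param duration_minutes night length (default 480).
#' @param mean_ibi_ms mean interval (default 1000 ms).
#' @param ectopic_rate fraction of beats made ectopic (default 0.02).
#' @param ectopic_factor multiplier for ectopic intervals (default 1.8).
#' @return data frame: `t_seconds` (first beat at 0), `ibi_ms`.
#' @export
simulate_ibi_night <- function(target_rmssd_ms, duration_minutes = 480,
                               mean_ibi_ms = 1000, ectopic_rate = 0.02,
                               ectopic_factor = 1.8) {
  n <- ceiling(duration_minutes * 60 * 1000 / mean_ibi_ms) + 10L
  ibi <- stats::rnorm(n, mean_ibi_ms, target_rmssd_ms / sqrt(2))
  ibi <- pmax(ibi, mean_ibi_ms * 0.4)
  ect <- stats::runif(n) < ectopic_rate
  ibi[ect] <- ibi[ect] * ectopic_factor
  t <- cumsum(c(0, ibi[-n])) / 1000
  keep <- t < duration_minutes * 60
  data.frame(t_seconds = t[keep], ibi_ms = ibi[keep])
}

#' Simulate a full synthetic cohort
#'
#' Assembles participants, five-week windows, nightly lnRMSSD with latent
#' level and dispersion trends, daily TST/MVPA with their own mild trends,
#' alcohol EMA with missingness, 4DSQ item responses, and the latent truth
#' for recovery tests. The configuration seed fully determines the output.
#'
#' Bases (lnRMSSD level, TST, MVPA, alcohol rate) evolve continuously
#' across windows: each window starts where the previous trend line ended.
#'
#' @param config a [sim_config()].
#' @return object of class `hrv_cohort`: list with `nightly`
#'   (participant_id, night_date, ln_rmssd), `activity`, `ema`,
#'   `responses` (50-item 4DSQ responses per questionnaire), `scores`,
#'   `truth` (per-window latent slopes, standardized slopes, realized
#'   standardized changes, and `gamma`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  interval <- config$questionnaire_interval_days
  start <- as.Date("2020-07-06")
  ids <- sprintf("P%02d", seq_len(config$n_participants))

  nightly <- list(); activity <- list(); ema <- list()
  truth <- list(); q_dates <- list(); latent <- list()

  for (p in seq_along(ids)) {
    id <- ids[p]
    n_win <- as.integer(config$weeks_per_participant[p] * 7 / interval)
    q_dates[[id]] <- start + (0:n_win) * interval

    base_ln <- stats::rnorm(1, config$baseline_ln_rmssd_mean,
                            config$baseline_ln_rmssd_sd)
    base_tst <- stats::rnorm(1, config$tst_mean, 20)
    base_mvpa <- max(stats::rnorm(1, config$mvpa_mean, 10), 5)
    base_alc <- max(stats::rnorm(1, config$alcohol_lambda, 0.3), 0.05)

    for (k in seq_len(n_win)) {
      a <- stats::rnorm(1, 0, config$level_slope_sd)
      b <- stats::rnorm(1, 0, config$disp_slope_sd)
      s_tst <- stats::rnorm(1, 0, config$tst_slope_sd)
      s_mvpa <- stats::rnorm(1, 0, config$mvpa_slope_sd)
      s_alc <- stats::rnorm(1, 0, config$alcohol_slope_sd)
      dates <- q_dates[[id]][k] + 0:(interval - 1L)
      t <- 0:(interval - 1L)

      night <- suppressWarnings(
        simulate_nightly(interval, base_ln, a, b, config$nightly_noise_sd,
                         config$sigma_min, config$hrv_missing_rate))
      nightly[[length(nightly) + 1L]] <- data.frame(
        participant_id = id, night_date = dates,
        ln_rmssd = night$ln_rmssd, stringsAsFactors = FALSE)

      activity[[length(activity) + 1L]] <- data.frame(
        participant_id = id, date = dates,
        tst_min = pmax(base_tst + s_tst * t +
                         stats::rnorm(interval, 0, config$tst_noise_sd), 0),
        mvpa_min = pmax(base_mvpa + s_mvpa * t +
                          stats::rnorm(interval, 0, config$mvpa_noise_sd), 0),
        stringsAsFactors = FALSE)

      lam <- pmax(base_alc + s_alc * t, 0)
      drinks <- stats::rpois(interval, lam)
      answered <- stats::runif(interval) >= config$ema_missing_rate
      if (any(answered))
        ema[[length(ema) + 1L]] <- data.frame(
          participant_id = id,
          timestamp = paste(dates[answered], "21:30:00"),
          drinks = drinks[answered], stringsAsFactors = FALSE)

      truth[[length(truth) + 1L]] <- data.frame(
        participant_id = id, window = k,
        start_date = q_dates[[id]][k], end_date = q_dates[[id]][k + 1L],
        level_slope = a, disp_slope = b, tst_slope = s_tst,
        mvpa_slope = s_mvpa, alcohol_slope = s_alc,
        z_hrv = a / config$level_slope_sd,
        z_hrvsd = b / config$disp_slope_sd,
        z_tst = s_tst / config$tst_slope_sd,
        z_mvpa = s_mvpa / config$mvpa_slope_sd,
        z_alcohol = s_alc / config$alcohol_slope_sd,
        stringsAsFactors = FALSE)

      base_ln <- base_ln + a * interval
      base_tst <- base_tst + s_tst * interval
      base_mvpa <- max(base_mvpa + s_mvpa * interval, 0)
      base_alc <- max(base_alc + s_alc * interval, 0)
    }
  }

  truth <- do.call(rbind, c(truth, make.row.names = FALSE))
  outc <- simulate_outcomes(config, truth, q_dates)
  scores <- outc$scores
  truth$delta_stress <- outc$deltas$delta_stress
  truth$delta_somatisation <- outc$deltas$delta_somatisation

  resp <- do.call(rbind, lapply(seq_len(nrow(scores)), function(i) {
    items <- .responses_from_scores(scores[i, ])
    out <- data.frame(participant_id = scores$participant_id[i],
                      date = scores$date[i], stringsAsFactors = FALSE)
    out[paste0("item_", 1:50)] <- as.list(items)
    out
  }))

  structure(list(nightly = do.call(rbind, c(nightly, make.row.names = FALSE)),
                 activity = do.call(rbind, c(activity, make.row.names = FALSE)),
                 ema = do.call(rbind, c(ema, make.row.names = FALSE)),
                 responses = resp, scores = scores, truth = truth,
                 gamma = config$gamma, config = config),
            class = "hrv_cohort")
}

#' @export
print.hrv_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(unique(x$nightly$participant_id)),
      "participants,", nrow(x$nightly), "person-days,",
      nrow(x$truth), "windows,", nrow(x$scores), "questionnaires\n")
  invisible(x)
}
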