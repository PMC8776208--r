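# Per-participant daily table: lnRMSSD, 7-day rolling SD (HRVsd), sleep,
# activity, and shift-aware EMA alcohol assignment.

#' Calendar-aware rolling standard deviation of prior days
#'
#' The daily HRV-fluctuation statistic: for each day d the sample standard
#' deviation (n-1 denominator) of the non-missing values on the
#' `window_days` calendar days strictly before d. The value is defined only
#' when at least `min_obs` of those prior days are observed (default: 3 of
#' the 7 prior days), otherwise missing. Missingness never raises an error.
#'
#' Windows are calendar windows, not observation windows: days absent from
#' `dates` count as unobserved.
#'
#' @param dates `Date` vector (unique; need not be contiguous).
#' @param values numeric values aligned with `dates`; `NA` = unobserved.
#' @param window_days window length in days (default 7).
#' @param min_obs minimum observed prior days for a defined value
#'   (default 3).
#' @param include_index include the index day itself in the window (the
#'   window becomes the `window_days` days ending at d). Default `FALSE`:
#'   the window is the `window_days` days ending at d-1. Exposed for
#'   sensitivity analysis only.
#' @return numeric vector aligned with `dates`.
#' @examples
#' d <- as.Date("2020-07-01") + 0:9
#' rolling_sd(d, c(3, 4, 5, rep(NA, 7)))
#' @export
rolling_sd <- function(dates, values, window_days = 7L, min_obs = 3L,
                       include_index = FALSE) {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("dates and values must have equal length")
  if (anyDuplicated(dates)) stop("dates must be unique")
  window_days <- as.integer(window_days)
  min_obs <- as.integer(min_obs)
  if (window_days < 2L) stop("window_days must be at least 2")
  if (min_obs <= 1L || min_obs > window_days)
    stop("min_obs must satisfy 1 < min_obs <= window_days")
  if (length(dates) == 0L) return(numeric(0))

  # full calendar grid so gaps in `dates` count as unobserved days
  grid <- seq(min(dates), max(dates), by = "day")
  full <- rep(NA_real_, length(grid))
  full[match(dates, grid)] <- values

  lag0 <- if (include_index) 0L else 1L
  vapply(match(dates, grid), function(i) {
    hi <- i - lag0
    if (hi < 1L) return(NA_real_)
    w <- full[max(hi - window_days + 1L, 1L):hi]
    w <- w[!is.na(w)]
    if (length(w) >= min_obs) stats::sd(w) else NA_real_
  }, numeric(1))
}

#' Assign an evening EMA response to its study day
#'
#' The daily alcohol item is open from 19:00 to 15:00 the next day to
#' accommodate night shifts; a response belongs to the day the window
#' opened. Timestamps at or after 19:00 map to their own date; at or before
#' 15:00 to the previous date. Times strictly between 15:00 and 19:00 are
#' outside every window and raise an error.
#'
#' @param timestamp `POSIXct` vector or ISO-8601 date-time strings
#'   (study-local wall clock; no time zone handling).
#' @return `Date` vector of assigned study days.
#' @examples
#' assign_ema_day("2020-07-01 22:30:00") # its own day
#' assign_ema_day("2020-07-02 09:00:00") # the previous day
#' @export
assign_ema_day <- function(timestamp) {
  ts <- as.POSIXct(timestamp, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamp(s)")
  secs <- as.numeric(ts) - as.numeric(as.POSIXct(format(ts, "%Y-%m-%d"),
                                                 tz = "UTC"))
  open <- 19 * 3600
  close <- 15 * 3600
  bad <- secs > close & secs < open
  if (any(bad))
    stop("timestamp outside EMA window (15:00-19:00): ",
         format(ts[bad][1], "%Y-%m-%d %H:%M:%S"))
  d <- as.Date(format(ts, "%Y-%m-%d"))
  d[secs <= close] <- d[secs <= close] - 1L
  d
}

.stop_dup <- function(df, keys, what) {
  dup <- duplicated(df[keys])
  if (any(dup)) {
    k <- df[which(dup)[1], keys]
    stop("duplicate ", what, " key: ", paste(unlist(k), collapse = " / "))
  }
}

#' Build the per-participant daily table
#'
#' Full-outer join of nightly HRV, EMA alcohol, and activity on
#' (participant, date) over each participant's continuous study range
#' (missing days are present with missing fields), followed by the rolling
#' HRVsd computation on lnRMSSD.
#'
#' EMA responses are assigned to study days with [assign_ema_day()]; when a
#' participant answered more than once in one window the last response
#' supersedes (with a warning).
#'
#' @param nightly_hrv data frame: `participant_id`, `night_date`,
#'   `ln_rmssd` (other columns ignored).
#' @param ema optional data frame: `participant_id`, `timestamp`, `drinks`.
#' @param activity optional data frame: `participant_id`, `date`,
#'   `tst_min`, `mvpa_min`.
#' @inheritParams rolling_sd
#' @return data frame: `participant_id`, `date`, `ln_rmssd`, `hrv_sd`,
#'   `tst_min`, `mvpa_min`, `alcohol`.
#' @export
build_daily_table <- function(nightly_hrv, ema = NULL, activity = NULL,
                              window_days = 7L, min_obs = 3L,
                              include_index = FALSE) {
  miss <- setdiff(c("participant_id", "night_date", "ln_rmssd"),
                  names(nightly_hrv))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  nightly_hrv$night_date <- as.Date(nightly_hrv$night_date)
  .stop_dup(nightly_hrv, c("participant_id", "night_date"), "(participant, date)")

  if (!is.null(activity) && nrow(activity)) {
    miss <- setdiff(c("participant_id", "date", "tst_min", "mvpa_min"),
                    names(activity))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    activity$date <- as.Date(activity$date)
    .stop_dup(activity, c("participant_id", "date"), "(participant, date)")
  } else activity <- NULL

  ema_daily <- NULL
  if (!is.null(ema) && nrow(ema)) {
    miss <- setdiff(c("participant_id", "timestamp", "drinks"), names(ema))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    ema$.day <- assign_ema_day(ema$timestamp)
    ema <- ema[order(ema$participant_id, ema$.day,
                     as.POSIXct(ema$timestamp, tz = "UTC")), , drop = FALSE]
    dup <- duplicated(ema[c("participant_id", ".day")], fromLast = TRUE)
    if (any(dup)) {
      warning(sum(dup), " duplicate EMA response(s) in one window; ",
              "keeping the last")
      ema <- ema[!dup, , drop = FALSE]
    }
    ema_daily <- data.frame(participant_id = ema$participant_id,
                            date = ema$.day, alcohol = ema$drinks,
                            stringsAsFactors = FALSE)
  }

  ids <- sort(unique(c(nightly_hrv$participant_id,
                       if (!is.null(activity)) activity$participant_id,
                       if (!is.null(ema_daily)) ema_daily$participant_id)))
  out <- lapply(ids, function(id) {
    all_dates <- c(nightly_hrv$night_date[nightly_hrv$participant_id == id],
                   if (!is.null(activity))
                     activity$date[activity$participant_id == id],
                   if (!is.null(ema_daily))
                     ema_daily$date[ema_daily$participant_id == id])
    if (!length(all_dates)) return(NULL)
    grid <- seq(min(all_dates), max(all_dates), by = "day")
    df <- data.frame(participant_id = id, date = grid,
                     stringsAsFactors = FALSE)
    h <- nightly_hrv[nightly_hrv$participant_id == id, , drop = FALSE]
    df$ln_rmssd <- h$ln_rmssd[match(grid, h$night_date)]
    if (!is.null(activity)) {
      a <- activity[activity$participant_id == id, , drop = FALSE]
      df$tst_min <- a$tst_min[match(grid, a$date)]
      df$mvpa_min <- a$mvpa_min[match(grid, a$date)]
    } else df$tst_min <- df$mvpa_min <- NA_real_
    if (!is.null(ema_daily)) {
      e <- ema_daily[ema_daily$participant_id == id, , drop = FALSE]
      df$alcohol <- e$alcohol[match(grid, e$date)]
    } else df$alcohol <- NA_integer_
    df$hrv_sd <- rolling_sd(df$date, df$ln_rmssd, window_days, min_obs,
                            include_index)
    df[c("participant_id", "date", "ln_rmssd", "hrv_sd", "tst_min",
         "mvpa_min", "alcohol")]
  })
  do.call(rbind, out)
}
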