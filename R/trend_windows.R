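# Between-questionnaire observation windows and per-window linear trend
# betas for the five daily variables.

#' Slice a participant's daily table into between-questionnaire windows
#'
#' Window k holds the days d with `q_dates[k] <= d < q_dates[k+1]`
#' (half-open, so a questionnaire day opens the window it precedes and no
#' day lands in two windows). Days after the final questionnaire belong to
#' no window.
#'
#' @param daily data frame for one participant with a `date` column.
#' @param q_dates sorted, distinct questionnaire dates (at least 2).
#' @return list of data frames, one per window, named
#'   `"<start>..<end>"`.
#' @export
window_slices <- function(daily, q_dates) {
  q_dates <- as.Date(q_dates)
  if (length(q_dates) < 2L) stop("at least two questionnaire dates required")
  if (is.unsorted(q_dates, strictly = TRUE))
    stop("questionnaire dates must be sorted and distinct")
  daily$date <- as.Date(daily$date)
  out <- lapply(seq_len(length(q_dates) - 1L), function(k) {
    daily[daily$date >= q_dates[k] & daily$date < q_dates[k + 1L], ,
          drop = FALSE]
  })
  names(out) <- paste0(utils::head(q_dates, -1), "..", q_dates[-1])
  out
}

#' Within-window linear trend (OLS slope per day)
#'
#' Regresses a daily variable on time, with time coded as integer days
#' since the window start; a positive beta is an uptrend. Missing days are
#' simply omitted. With fewer than `min_obs` non-missing days the trend is
#' missing (with a warning) rather than an error.
#'
#' @param dates `Date` vector.
#' @param values numeric values aligned with `dates` (`NA` = missing).
#' @param min_obs minimum non-missing days for a defined trend
#'   (default 10).
#' @return list with `beta` (slope in variable units per day, or `NA`) and
#'   `n` (days used).
#' @export
trend_beta <- function(dates, values, min_obs = 10L) {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("dates and values must have equal length")
  ok <- !is.na(values) & !is.na(dates)
  n <- sum(ok)
  if (n < min_obs) {
    warning("only ", n, " non-missing day(s) (< ", min_obs,
            "); trend set missing")
    return(list(beta = NA_real_, n = n))
  }
  x <- as.numeric(dates[ok] - min(dates[ok]))
  y <- values[ok]
  if (length(unique(x)) < 2L) stop("zero date variance; trend undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(beta = unname(fit$coefficients[2]), n = n)
}

#' Assemble the window-level analysis table
#'
#' One row per consecutive questionnaire pair and participant: the four
#' 4DSQ change scores plus OLS trend betas for lnRMSSD (`hrv_uptrend`),
#' HRVsd (`hrvsd_uptrend`), TST, MVPA, and alcohol, with per-variable
#' day counts. Windows with any missing trend or change score are retained
#' but flagged `incomplete`.
#'
#' @param daily daily table from [build_daily_table()].
#' @param scores scored questionnaires from [score_4dsq_table()].
#' @param min_trend_obs minimum non-missing days per trend (default 10).
#' @return data frame of observation windows.
#' @export
assemble_windows <- function(daily, scores, min_trend_obs = 10L) {
  daily$date <- as.Date(daily$date)
  scores$date <- as.Date(scores$date)
  vars <- c(hrv = "ln_rmssd", hrvsd = "hrv_sd", tst = "tst_min",
            mvpa = "mvpa_min", alcohol = "alcohol")
  ids <- intersect(unique(daily$participant_id),
                   unique(scores$participant_id))
  rows <- list()
  for (id in ids) {
    sc <- scores[scores$participant_id == id, , drop = FALSE]
    sc <- sc[order(sc$date), , drop = FALSE]
    if (nrow(sc) < 2L) next
    slices <- window_slices(daily[daily$participant_id == id, , drop = FALSE],
                            sc$date)
    for (k in seq_along(slices)) {
      win <- slices[[k]]
      row <- data.frame(participant_id = id, start_date = sc$date[k],
                        end_date = sc$date[k + 1L], stringsAsFactors = FALSE)
      ch <- change_scores(unlist(sc[k, .fdsq_scale_names]),
                          unlist(sc[k + 1L, .fdsq_scale_names]),
                          sc$date[k], sc$date[k + 1L])
      row[names(ch)] <- ch
      for (v in names(vars)) {
        tb <- suppressWarnings(
          trend_beta(win$date, win[[vars[[v]]]], min_trend_obs))
        row[[paste0(v, "_uptrend")]] <- tb$beta
        row[[paste0("n_days_", v)]] <- tb$n
      }
      trend_cols <- paste0(names(vars), "_uptrend")
      row$incomplete <- anyNA(unlist(row[c(names(ch), trend_cols)]))
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("no windows could be formed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
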