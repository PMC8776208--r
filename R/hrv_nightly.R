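# Nightly HRV from inter-beat intervals: artifact screening, 5-minute
# segmentation, per-segment RMSSD, and segment averaging.

#' Root mean square of successive differences
#'
#' Time-domain vagal HRV index: \code{sqrt(mean(diff(x)^2))} over an ordered
#' series of inter-beat intervals.
#'
#' @param ibi_ms numeric vector of inter-beat intervals in milliseconds,
#'   in temporal order. Needs at least two values.
#' @return RMSSD in the units of `ibi_ms` (ms), or `NA_real_` if fewer than
#'   two intervals are supplied.
#' @examples
#' rmssd(c(1000, 1010, 990)) # sqrt((10^2 + 20^2)/2)
#' @export
rmssd <- function(ibi_ms) {
  ibi_ms <- as.numeric(ibi_ms)
  if (length(ibi_ms) < 2L) return(NA_real_)
  sqrt(mean(diff(ibi_ms)^2))
}

#' Label inter-beat intervals as normal or abnormal
#'
#' Ectopic-beat / artifact screen: each interval is compared with the median
#' of its nearest `neighborhood` surrounding intervals (itself excluded) and
#' labelled abnormal when its relative deviation from that median exceeds
#' `rel_threshold`.
#'
#' Neighbours are the `neighborhood` intervals nearest in sequence position;
#' at equal distance the earlier interval is preferred, so with the default
#' `neighborhood = 5` an interior beat is compared with positions
#' i-3, i-2, i-1, i+1, i+2. Intervals near the series edge use all available
#' neighbours.
#'
#' @param ibi_ms numeric vector of inter-beat intervals (ms), temporal order.
#' @param neighborhood number of surrounding intervals used for the median
#'   (default 5).
#' @param rel_threshold relative deviation above which an interval is
#'   abnormal (default 0.30, i.e. 30\%).
#' @return character vector, one of `"normal"`/`"abnormal"` per interval.
#' @examples
#' x <- rep(800, 20); x[10] <- 2000
#' table(flag_artifacts(x))
#' @export
flag_artifacts <- function(ibi_ms, neighborhood = 5L, rel_threshold = 0.30) {
  ibi_ms <- as.numeric(ibi_ms)
  n <- length(ibi_ms)
  if (n == 0L) stop("no intervals")
  if (any(!is.finite(ibi_ms)) || any(ibi_ms <= 0))
    stop("all inter-beat intervals must be finite and positive")
  neighborhood <- as.integer(neighborhood)
  if (neighborhood < 2L) stop("neighborhood must be at least 2")
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stop("rel_threshold must be in (0, 1)")
  if (n == 1L) return("normal")

  meds <- rep(NA_real_, n)
  interior <- if (neighborhood == 5L && n >= 7L) 4:(n - 2L) else integer(0)
  if (length(interior)) {
    # nearest-5 neighbour set of an interior beat is {i-3, i-2, i-1, i+1,
    # i+2}; median of 5 via a pmin/pmax selection network
    i <- interior
    a <- ibi_ms[i - 3L]; b <- ibi_ms[i - 2L]; c <- ibi_ms[i - 1L]
    d <- ibi_ms[i + 1L]; e <- ibi_ms[i + 2L]
    f <- pmin(a, b); g <- pmax(a, b)
    h <- pmin(c, d); j <- pmax(c, d)
    lo <- pmax(f, h) # drop the smaller of the two pair-minima
    hi <- pmin(g, j) # drop the larger of the two pair-maxima
    meds[i] <- pmax(pmin(lo, hi), pmin(pmax(lo, hi), e))
  }
  for (i in setdiff(seq_len(n), interior)) {
    others <- seq_len(n)[-i]
    ord <- order(abs(others - i), others)
    nb <- others[ord][seq_len(min(neighborhood, n - 1L))]
    meds[i] <- stats::median(ibi_ms[nb])
  }
  ifelse(abs(ibi_ms - meds) / meds > rel_threshold, "abnormal", "normal")
}

#' Subdivide a night of intervals into fixed-length segments
#'
#' Tiles the night `[0, night end)` into contiguous, non-overlapping
#' `segment_minutes` windows by timestamp and collects each segment's
#' normal-labelled intervals together with its validity fraction
#' (normal / total intervals; 0 for an empty segment).
#'
#' @param t_seconds numeric timestamps (seconds from night start), strictly
#'   increasing, starting at or after 0.
#' @param ibi_ms inter-beat intervals (ms) aligned with `t_seconds`.
#' @param labels labels from [flag_artifacts()] (character
#'   `"normal"`/`"abnormal"`).
#' @param segment_minutes segment length in minutes (default 5).
#' @return list of segments; each a list with `normal_ibis` (numeric, in
#'   order), `n_ibis`, `n_normal`, `validity_fraction`.
#' @export
segment_night <- function(t_seconds, ibi_ms, labels, segment_minutes = 5) {
  t_seconds <- as.numeric(t_seconds)
  ibi_ms <- as.numeric(ibi_ms)
  n <- length(t_seconds)
  if (n == 0L) stop("no intervals")
  if (length(ibi_ms) != n || length(labels) != n)
    stop("t_seconds, ibi_ms and labels must have equal length")
  if (any(diff(t_seconds) <= 0)) stop("timestamps must be strictly increasing")
  if (any(t_seconds < 0)) stop("timestamps must be non-negative")
  segment_minutes <- as.integer(segment_minutes)
  if (segment_minutes < 1L) stop("segment_minutes must be at least 1")

  seg_len <- segment_minutes * 60
  idx <- floor(t_seconds / seg_len) # 0-based segment index per IBI
  n_total <- max(idx) + 1L
  normal <- labels == "normal"

  lapply(seq_len(n_total) - 1L, function(k) {
    in_seg <- idx == k
    list(
      normal_ibis = ibi_ms[in_seg & normal],
      n_ibis = sum(in_seg),
      n_normal = sum(in_seg & normal),
      validity_fraction = if (any(in_seg)) sum(in_seg & normal) / sum(in_seg) else 0
    )
  })
}

#' Nightly RMSSD from screened segments
#'
#' A segment is valid when its validity fraction is at least
#' `min_valid_fraction` and it holds at least `min_normal_ibis` normal
#' intervals (and at least 2, so successive differences exist). The nightly
#' value is the unweighted arithmetic mean of the valid segments' RMSSDs;
#' lnRMSSD is its natural log.
#'
#' A night with no valid segment, or with a zero RMSSD (no successive
#' variation at all, physiologically implausible and read as sensor failure),
#' yields a missing night rather than an error: `rmssd_ms`/`ln_rmssd` are
#' `NA` and the day is simply absent from downstream HRV analyses.
#'
#' @param segments list of segments from [segment_night()].
#' @param min_valid_fraction minimum fraction of normal intervals per
#'   segment (default 0.5).
#' @param min_normal_ibis minimum count of normal intervals per segment
#'   (default 30).
#' @return list with `rmssd_ms`, `ln_rmssd`, `n_valid_segments`,
#'   `n_total_segments`.
#' @export
nightly_rmssd <- function(segments, min_valid_fraction = 0.5,
                          min_normal_ibis = 30L) {
  if (length(segments) == 0L) stop("at least one segment required")
  min_normal_ibis <- max(as.integer(min_normal_ibis), 2L)

  seg_rmssd <- vapply(segments, function(s) {
    if (s$validity_fraction >= min_valid_fraction &&
        s$n_normal >= min_normal_ibis) rmssd(s$normal_ibis) else NA_real_
  }, numeric(1))
  valid <- !is.na(seg_rmssd)

  if (!any(valid)) {
    return(list(rmssd_ms = NA_real_, ln_rmssd = NA_real_,
                n_valid_segments = 0L,
                n_total_segments = length(segments)))
  }
  rm_ms <- mean(seg_rmssd[valid])
  ln <- if (rm_ms > 0) log(rm_ms) else {
    warning("nightly RMSSD is 0; night treated as missing")
    NA_real_
  }
  list(rmssd_ms = rm_ms, ln_rmssd = ln,
       n_valid_segments = sum(valid),
       n_total_segments = length(segments))
}

#' Process one night of inter-beat intervals end to end
#'
#' Convenience wrapper: [flag_artifacts()] then [segment_night()] then
#' [nightly_rmssd()].
#'
#' @inheritParams segment_night
#' @inheritParams flag_artifacts
#' @inheritParams nightly_rmssd
#' @return as [nightly_rmssd()].
#' @export
process_night <- function(t_seconds, ibi_ms, neighborhood = 5L,
                          rel_threshold = 0.30, segment_minutes = 5,
                          min_valid_fraction = 0.5, min_normal_ibis = 30L) {
  labels <- flag_artifacts(ibi_ms, neighborhood, rel_threshold)
  segs <- segment_night(t_seconds, ibi_ms, labels, segment_minutes)
  nightly_rmssd(segs, min_valid_fraction, min_normal_ibis)
}

#' Nightly HRV table from a multi-night IBI data frame
#'
#' @param ibi data frame with columns `participant_id`, `night_date`
#'   (`Date` or ISO-8601 string), `t_seconds`, `ibi_ms`.
#' @inheritParams process_night
#' @return data frame: `participant_id`, `night_date`, `rmssd_ms`,
#'   `ln_rmssd`, `n_valid_segments`, `n_total_segments`, one row per
#'   (participant, night).
#' @export
nightly_hrv_table <- function(ibi, neighborhood = 5L, rel_threshold = 0.30,
                              segment_minutes = 5, min_valid_fraction = 0.5,
                              min_normal_ibis = 30L) {
  need <- c("participant_id", "night_date", "t_seconds", "ibi_ms")
  miss <- setdiff(need, names(ibi))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ibi$night_date <- as.Date(ibi$night_date)

  keys <- unique(ibi[c("participant_id", "night_date")])
  keys <- keys[order(keys$participant_id, keys$night_date), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    sel <- ibi$participant_id == keys$participant_id[r] &
      ibi$night_date == keys$night_date[r]
    night <- ibi[sel, , drop = FALSE]
    night <- night[order(night$t_seconds), , drop = FALSE]
    res <- process_night(night$t_seconds, night$ibi_ms, neighborhood,
                         rel_threshold, segment_minutes, min_valid_fraction,
                         min_normal_ibis)
    data.frame(participant_id = keys$participant_id[r],
               night_date = keys$night_date[r],
               rmssd_ms = res$rmssd_ms, ln_rmssd = res$ln_rmssd,
               n_valid_segments = res$n_valid_segments,
               n_total_segments = res$n_total_segments,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
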