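# 4DSQ scoring: item recoding, scale sums, five-week change scores, and
# floor-effect screening.

.fdsq_levels <- c("no", "sometimes", "regularly", "often", "very_often")
.fdsq_points <- c(no = 0L, sometimes = 1L, regularly = 2L, often = 2L,
                  very_often = 2L)
.fdsq_scale_names <- c("stress", "depression", "anxiety", "somatisation")
.fdsq_n_items <- c(stress = 16L, depression = 5L, anxiety = 12L,
                   somatisation = 16L)
.fdsq_max <- 2L * .fdsq_n_items # 32, 10, 24, 32

#' Default 4DSQ item-to-scale layout
#'
#' The instrument has 50 items; the four scales cover 16 (somatisation),
#' 16 (stress), 12 (anxiety) and 5 (depression) of them, which accounts for
#' 49 — one item stays unassigned. The published item ordering is part of
#' the copyrighted instrument and is not shipped; this synthetic default
#' layout (items 1-16 somatisation, 17-32 stress, 33-44 anxiety, 45-49
#' depression, 50 unassigned) carries the correct scale sizes, and any real
#' deployment should pass the licensed mapping via the `scale_map` argument
#' of [score_4dsq()].
#'
#' @return character vector of length 50: scale name per item, `NA` for the
#'   unassigned item.
#' @export
fdsq_default_map <- function() {
  c(rep("somatisation", 16), rep("stress", 16), rep("anxiety", 12),
    rep("depression", 5), NA_character_)
}

.check_scale_map <- function(scale_map) {
  if (length(scale_map) != 50L) stop("scale_map must have 50 entries")
  cnt <- table(factor(scale_map, levels = .fdsq_scale_names))
  bad <- .fdsq_n_items[names(cnt)] != as.integer(cnt)
  if (any(bad))
    stop("scale_map item counts must be 16/5/12/16 ",
         "(stress/depression/anxiety/somatisation)")
  invisible(scale_map)
}

#' Recode a 4DSQ item response to its score
#'
#' `no` scores 0, `sometimes` 1, and `regularly`/`often`/`very_often` all
#' score 2.
#'
#' @param response character vector of response categories; `NA` allowed
#'   (propagates).
#' @return integer vector of 0/1/2 scores.
#' @examples
#' recode_item(c("no", "sometimes", "very_often"))
#' @export
recode_item <- function(response) {
  response <- as.character(response)
  known <- is.na(response) | response %in% .fdsq_levels
  if (!all(known))
    stop("unknown response category: ",
         paste(unique(response[!known]), collapse = ", "))
  out <- rep(NA_integer_, length(response))
  ok <- !is.na(response)
  out[ok] <- .fdsq_points[response[ok]]
  out
}

#' Score the four 4DSQ scales from 50 item responses
#'
#' Each scale score is the sum of its recoded items. A scale with any
#' missing item yields a missing score (no pro-rating), with a warning.
#'
#' @param items character vector of 50 response categories (`NA` for
#'   missing items).
#' @param scale_map item-to-scale assignment, see [fdsq_default_map()].
#' @return named numeric vector: `stress` (0-32), `depression` (0-10),
#'   `anxiety` (0-24), `somatisation` (0-32).
#' @export
score_4dsq <- function(items, scale_map = fdsq_default_map()) {
  if (length(items) != 50L) stop("exactly 50 item responses required")
  .check_scale_map(scale_map)
  pts <- recode_item(items)
  out <- vapply(.fdsq_scale_names, function(sc) {
    p <- pts[!is.na(scale_map) & scale_map == sc]
    if (anyNA(p)) NA_real_ else sum(p)
  }, numeric(1))
  if (anyNA(out))
    warning("missing item(s); scale score(s) set missing: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Score a table of 4DSQ responses
#'
#' @param responses data frame with `participant_id`, `date`, and item
#'   columns `item_1` ... `item_50`.
#' @inheritParams score_4dsq
#' @return data frame: `participant_id`, `date`, `stress`, `depression`,
#'   `anxiety`, `somatisation`.
#' @export
score_4dsq_table <- function(responses, scale_map = fdsq_default_map()) {
  item_cols <- paste0("item_", 1:50)
  miss <- setdiff(c("participant_id", "date", item_cols), names(responses))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  sc <- t(apply(as.matrix(responses[item_cols]), 1, score_4dsq,
                scale_map = scale_map))
  out <- data.frame(participant_id = responses$participant_id,
                    date = as.Date(responses$date),
                    stringsAsFactors = FALSE)
  out[.fdsq_scale_names] <- as.data.frame(sc)
  out[order(out$participant_id, out$date), , drop = FALSE]
}

#' Change scores between two consecutive questionnaires
#'
#' Later minus earlier, per scale: a positive value is an increase in the
#' measured concept over the interval.
#'
#' @param earlier,later named numeric score vectors as returned by
#'   [score_4dsq()]; `earlier` and `later` must carry `date` attributes or
#'   the dates be supplied.
#' @param earlier_date,later_date the questionnaire dates
#'   (`later_date > earlier_date`).
#' @return named numeric vector: `stress_increase`, `depression_increase`,
#'   `anxiety_increase`, `somatisation_increase`.
#' @export
change_scores <- function(earlier, later, earlier_date, later_date) {
  earlier_date <- as.Date(earlier_date); later_date <- as.Date(later_date)
  if (!later_date > earlier_date)
    stop("later questionnaire must postdate the earlier one")
  d <- later[.fdsq_scale_names] - earlier[.fdsq_scale_names]
  names(d) <- paste0(.fdsq_scale_names, "_increase")
  d
}

#' Screen a scale for floor effects
#'
#' Reports the fraction of scores equal to zero and flags the scale when
#' that fraction reaches `zero_fraction_threshold`. Downstream modelling
#' refuses flagged outcomes unless forced: with nearly all scores at the
#' scale minimum there is too little variance to detect an association, and
#' no model can meaningfully be formed.
#'
#' @param scores numeric scores of one scale across all questionnaires.
#' @param zero_fraction_threshold flag threshold (default 0.8).
#' @return list with `zero_fraction`, `flagged`, `n`.
#' @export
floor_effect_check <- function(scores, zero_fraction_threshold = 0.8) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("at least one score required")
  zf <- mean(scores == 0)
  list(zero_fraction = zf, flagged = zf >= zero_fraction_threshold,
       n = length(scores))
}
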