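# CSV schema validation, run configuration, and the end-to-end pipeline
# driver with its JSON run manifest.

.schemas <- list(
  ibi = list(cols = c(participant_id = "character", night_date = "date",
                      t_seconds = "numeric", ibi_ms = "numeric"),
             key = c("participant_id", "night_date", "t_seconds")),
  nightly_hrv = list(cols = c(participant_id = "character",
                              night_date = "date", ln_rmssd = "numeric"),
                     key = c("participant_id", "night_date")),
  ema = list(cols = c(participant_id = "character",
                      timestamp = "character", drinks = "numeric"),
             key = NULL),
  activity = list(cols = c(participant_id = "character", date = "date",
                           tst_min = "numeric", mvpa_min = "numeric"),
                  key = c("participant_id", "date")),
  daily = list(cols = c(participant_id = "character", date = "date",
                        ln_rmssd = "numeric", hrv_sd = "numeric",
                        tst_min = "numeric", mvpa_min = "numeric",
                        alcohol = "numeric"),
               key = c("participant_id", "date")),
  fdsq_scores = list(cols = c(participant_id = "character", date = "date",
                              stress = "numeric", depression = "numeric",
                              anxiety = "numeric",
                              somatisation = "numeric"),
                     key = c("participant_id", "date")),
  windows = list(cols = c(participant_id = "character",
                          start_date = "date", end_date = "date",
                          stress_increase = "numeric",
                          depression_increase = "numeric",
                          anxiety_increase = "numeric",
                          somatisation_increase = "numeric",
                          hrv_uptrend = "numeric",
                          hrvsd_uptrend = "numeric",
                          tst_uptrend = "numeric",
                          mvpa_uptrend = "numeric",
                          alcohol_uptrend = "numeric"),
                 key = c("participant_id", "start_date")))

#' Read and validate a pipeline CSV
#'
#' Checks that the named schema's columns are present, coerces and checks
#' types (dates must be ISO-8601), rejects duplicate keys naming the
#' offending key, and reports the row count via `message()`.
#'
#' @param path CSV file path.
#' @param schema one of \code{"ibi"}, \code{"nightly_hrv"}, \code{"ema"},
#'   \code{"activity"}, \code{"daily"}, \code{"fdsq_scores"},
#'   \code{"windows"}.
#' @return validated data frame (date columns as `Date`).
#' @export
validate_csv <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- match.arg(schema, names(.schemas))
  sch <- .schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(sch$cols), names(df))
  if (length(miss))
    stop("schema '", schema, "': missing column(s): ",
         paste(miss, collapse = ", "))
  for (cn in names(sch$cols)) {
    type <- sch$cols[[cn]]
    if (type == "date") {
      d <- as.Date(as.character(df[[cn]]), format = "%Y-%m-%d")
      if (any(is.na(d) & !is.na(df[[cn]])))
        stop("schema '", schema, "': column ", cn,
             " has non-ISO-8601 dates")
      df[[cn]] <- d
    } else if (type == "numeric") {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      if (any(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "" &
              !(df[[cn]] %in% c("NA"))))
        stop("schema '", schema, "': column ", cn, " is not numeric")
      df[[cn]] <- v
    } else df[[cn]] <- as.character(df[[cn]])
  }
  if (!is.null(sch$key)) .stop_dup(df, sch$key, paste0("(", schema, ")"))
  message("read ", nrow(df), " row(s), ", ncol(df), " column(s) from ",
          basename(path))
  df
}

#' Default run configuration
#'
#' Every stage parameter of the pipeline with its documented default; see
#' the stage functions for their meaning. `sim` holds [sim_config()]
#' arguments for synthetic runs.
#'
#' @param seed master seed; all stage randomness derives from it.
#' @param ... overrides for any configuration key (unknown keys are
#'   rejected).
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(seed = 20260101L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    neighborhood = 5L, rel_threshold = 0.30,
    segment_minutes = 5L, min_valid_fraction = 0.5, min_normal_ibis = 30L,
    rolling_window_days = 7L, rolling_min_obs = 3L,
    rolling_include_index = FALSE,
    min_trend_obs = 10L,
    floor_threshold = 0.8,
    outcomes = c("stress_increase", "depression_increase",
                 "anxiety_increase", "somatisation_increase"),
    force_floor = FALSE,
    cluster = NULL,
    write_plots = FALSE,
    sim = list())
  structure(.merge_config(cfg, list(...)), class = "run_config")
}

.merge_config <- function(cfg, over) {
  if (!length(over)) return(cfg)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Keys must be a subset of [default_run_config()]'s; unknown keys are
#' rejected. `sim` entries must be [sim_config()] argument names.
#'
#' @param path YAML file.
#' @return `run_config` list.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    known <- names(formals(sim_config))
    unknown <- setdiff(names(y$sim), known)
    if (length(unknown))
      stop("unknown sim key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(default_run_config, c(list(seed = y$seed %||% 20260101L),
                                y[setdiff(names(y), "seed")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 32-bit sub-seed per stage
.sub_seed <- function(seed, stage) {
  (as.numeric(seed) * 977 + stage * 7919) %% 2147483647
}

.write_csv <- function(df, path) {
  for (cn in names(df)) if (inherits(df[[cn]], "Date"))
    df[[cn]] <- format(df[[cn]], "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> nightly -> daily -> windows -> models. Generates a cohort
#' from `config$sim` (seeded from `config$seed`), builds the daily table
#' and observation windows, screens every 4DSQ scale for floor effects,
#' and fits the three-step hierarchical regression for each outcome that
#' passes the screen; floor-flagged outcomes are recorded as refusals
#' ("no models could be formed"). All stage outputs are written to
#' `out_dir` as CSV/JSON together with a run manifest (config echo,
#' seed, per-file MD5); identical config and seed give byte-identical
#' outputs.
#'
#' @param config a [default_run_config()] list.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly: list with `config`, `seed`, `files`
#'   (MD5 by file name), `n_windows`, `floor`, `refusals`, `warnings`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warn <- character(0)
  wh <- function(w) { warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning") }

  withCallingHandlers({
    sim_args <- c(list(seed = .sub_seed(config$seed, 1L)),
                  config$sim[setdiff(names(config$sim), "seed")])
    cohort <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(cohort)

    daily <- build_daily_table(cohort$nightly, cohort$ema, cohort$activity,
                               config$rolling_window_days,
                               config$rolling_min_obs,
                               config$rolling_include_index)
    scores <- score_4dsq_table(cohort$responses)
    windows <- assemble_windows(daily, scores, config$min_trend_obs)

    floor <- lapply(stats::setNames(.fdsq_scale_names, .fdsq_scale_names),
                    function(sc) floor_effect_check(scores[[sc]],
                                                    config$floor_threshold))

    fits <- list(); refusals <- list()
    for (oc in config$outcomes) {
      scale_name <- sub("_increase$", "", oc)
      fc <- floor[[scale_name]]
      if (isTRUE(fc$flagged) && !isTRUE(config$force_floor)) {
        refusals[[oc]] <- paste0(
          "floor effect on ", scale_name, " (",
          round(100 * fc$zero_fraction, 1),
          "% zeros): no models could be formed")
        next
      }
      fit <- fit_hierarchical(windows, oc, floor_check = fc,
                              force = config$force_floor,
                              cluster = config$cluster)
      fits[[oc]] <- fit
    }

    files <- character(0)
    files <- c(files, .write_csv(cohort$nightly,
                                 file.path(out_dir, "nightly_hrv.csv")))
    files <- c(files, .write_csv(daily, file.path(out_dir, "daily.csv")))
    files <- c(files, .write_csv(scores,
                                 file.path(out_dir, "fdsq_scores.csv")))
    files <- c(files, .write_csv(windows,
                                 file.path(out_dir, "windows.csv")))
    for (oc in names(fits)) {
      fit <- fits[[oc]]
      ctab <- do.call(rbind, lapply(1:3, function(k) {
        ct <- fit$steps[[k]]$coefficients
        data.frame(step = k, term = rownames(ct),
                   beta = ct[, "Estimate"], se = ct[, "Std. Error"],
                   p = ct[, "Pr(>|t|)"], row.names = NULL)
      }))
      files <- c(files, .write_csv(ctab,
        file.path(out_dir, paste0("model_", oc, ".csv"))))
      stats_js <- list(
        outcome = oc, n = fit$n,
        r2 = vapply(fit$steps, `[[`, numeric(1), "r.squared"),
        adj_r2 = vapply(fit$steps, `[[`, numeric(1), "adj.r.squared"),
        F = vapply(fit$steps, `[[`, numeric(1), "fstatistic"),
        model_p = vapply(fit$steps, `[[`, numeric(1), "model_p"),
        dR2 = vapply(fit$comparisons, `[[`, numeric(1), "dR2"),
        dF_diff = vapply(fit$comparisons, `[[`, numeric(1), "dF_diff"),
        comparison_p = vapply(fit$comparisons, `[[`, numeric(1), "p"))
      jp <- file.path(out_dir, paste0("model_", oc, ".json"))
      jsonlite::write_json(stats_js, jp, auto_unbox = TRUE, digits = NA)
      files <- c(files, jp)
      ss <- simple_slopes(fit)
      files <- c(files, .write_csv(as.data.frame(ss),
        file.path(out_dir, paste0("interaction_", oc, ".csv"))))
      if (isTRUE(config$write_plots)) {
        pf <- file.path(out_dir, paste0("interaction_", oc, ".png"))
        grDevices::png(pf, width = 800, height = 600)
        plot(fit, which = "moderation")
        grDevices::dev.off()
        sf <- file.path(out_dir, paste0("scatter_", oc, ".png"))
        grDevices::png(sf, width = 800, height = 600)
        plot(fit, which = "association")
        grDevices::dev.off()
      }
    }

    cfg_echo <- config[setdiff(names(config), "out_dir")]
    cfg_tmp <- tempfile()
    jsonlite::write_json(cfg_echo, cfg_tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    cfg_hash <- unname(tools::md5sum(cfg_tmp))
    unlink(cfg_tmp)

    manifest <- list(
      config = cfg_echo, config_hash = cfg_hash, seed = config$seed,
      n_participants = length(unique(daily$participant_id)),
      n_person_days = nrow(daily), n_windows = nrow(windows),
      floor = lapply(floor, function(f)
        list(zero_fraction = f$zero_fraction, flagged = f$flagged,
             n = f$n)),
      refusals = refusals,
      files = stats::setNames(as.list(unname(tools::md5sum(sort(files)))),
                              basename(sort(files))),
      warnings = warn)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    manifest$fits <- fits
    invisible(manifest)
  }, warning = wh)
}
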