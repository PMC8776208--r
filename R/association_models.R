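# Grand-mean standardization, the three-step moderated hierarchical
# regression, simple-slope (buffering) profiles, and the correlation table.

#' Standardize window-level variables at the grand mean
#'
#' z = (x - grand mean) / grand SD per variable, over the analysed windows.
#' Windows with a missing value in any requested variable are excluded
#' listwise (and reported via the `dropped` attribute). Per-variable means
#' and SDs are retained for back-transformation.
#'
#' @param windows window table from [assemble_windows()] (or any data
#'   frame).
#' @param variables character vector of columns to standardize.
#' @param keep extra columns carried through unstandardized (default:
#'   `participant_id` if present).
#' @return object of class `hrv_std`: list with `data` (standardized data
#'   frame), `center`, `scale`, `n`, `dropped` (row indices removed).
#' @export
standardize <- function(windows, variables,
                        keep = intersect("participant_id", names(windows))) {
  miss <- setdiff(variables, names(windows))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(windows[variables])
  dropped <- which(!cc)
  dat <- windows[cc, , drop = FALSE]
  if (nrow(dat) < 3L) stop("at least 3 complete windows required")
  if (length(dropped))
    message(length(dropped), " incomplete window(s) excluded listwise")
  ctr <- vapply(dat[variables], mean, numeric(1))
  scl <- vapply(dat[variables], stats::sd, numeric(1))
  if (any(scl == 0))
    stop("zero standard deviation in: ",
         paste(variables[scl == 0], collapse = ", "))
  z <- as.data.frame(Map(function(x, m, s) (x - m) / s,
                         dat[variables], ctr, scl))
  names(z) <- variables
  for (k in keep) z[[k]] <- dat[[k]]
  structure(list(data = z, center = ctr, scale = scl, n = nrow(z),
                 dropped = dropped),
            class = "hrv_std")
}

#' @export
print.hrv_std <- function(x, ...) {
  cat("Standardized window sample:", x$n, "windows,",
      length(x$center), "variables\n")
  invisible(x)
}

.p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", ifelse(p < 0.1, ".", "")))))
}

#' Three-step moderated hierarchical regression
#'
#' Fits three nested OLS models for one standardized outcome:
#' step 1 regresses the outcome on the control trends (TST, MVPA,
#' alcohol); step 2 adds the main HRV and HRVsd trends; step 3 adds their
#' interaction, formed as the product of the standardized main effects
#' (not re-standardized). All variables (outcome included) are
#' grand-mean-standardized first unless a prepared [standardize()] sample
#' is supplied.
#'
#' Between consecutive steps the fit reports the R-squared increment and
#' two delta-F flavours: `dF_diff`, the difference of the successive model
#' F statistics (which can be negative), and the conventional partial-F
#' test of the added terms, whose p-value is used for the nested-model
#' comparison.
#'
#' A floor-flagged outcome (see [floor_effect_check()]) is refused unless
#' `force = TRUE`: no model can meaningfully be formed when nearly all
#' scores sit at the scale minimum.
#'
#' @param windows window table from [assemble_windows()], or an `hrv_std`
#'   object holding all needed variables.
#' @param outcome outcome column name, e.g. `"stress_increase"`.
#' @param controls control trend columns (step 1).
#' @param predictors main-effect trend columns (step 2); the first is the
#'   moderator and the second the focal predictor of the interaction.
#' @param floor_check optional result of [floor_effect_check()] for the
#'   outcome's scale.
#' @param force fit even when `floor_check$flagged` (default `FALSE`).
#' @param cluster optional name of a grouping column (e.g.
#'   `"participant_id"`); when given, coefficient SEs and p-values use
#'   cluster-robust (CR) covariance via [sandwich::vcovCL()]. Default off:
#'   repeated windows per participant are treated as independent in the
#'   primary fit.
#' @return object of class `hrv_hfit`; see [summary.hrv_hfit()],
#'   [coef.hrv_hfit()], [simple_slopes()], [plot.hrv_hfit()].
#' @export
fit_hierarchical <- function(windows, outcome,
                             controls = c("tst_uptrend", "mvpa_uptrend",
                                          "alcohol_uptrend"),
                             predictors = c("hrv_uptrend", "hrvsd_uptrend"),
                             floor_check = NULL, force = FALSE,
                             cluster = NULL) {
  if (!is.null(floor_check) && isTRUE(floor_check$flagged) && !force)
    stop("outcome '", outcome, "' is floor-flagged (",
         round(100 * floor_check$zero_fraction, 1),
         "% zeros): no models could be formed")
  if (length(predictors) != 2L)
    stop("exactly two main-effect predictors required")

  vars <- c(outcome, controls, predictors)
  std <- if (inherits(windows, "hrv_std")) windows else
    standardize(windows, vars,
                keep = intersect(c("participant_id", cluster),
                                 names(windows)))
  dat <- std$data
  if (!all(vars %in% names(dat)))
    stop("standardized sample lacks required variables")
  n <- nrow(dat)
  if (n <= length(vars) + 1L)
    stop("too few windows (", n, ") for the step-3 model")

  moderator <- predictors[1]; focal <- predictors[2]
  int_term <- paste0(moderator, ":", focal)
  dat$.interaction <- dat[[moderator]] * dat[[focal]]

  f1 <- stats::as.formula(paste(outcome, "~",
                                paste(controls, collapse = " + ")))
  f2 <- stats::update(f1, paste("~ . +", paste(predictors, collapse = " + ")))
  f3 <- stats::update(f2, "~ . + .interaction")
  fits <- list(stats::lm(f1, data = dat), stats::lm(f2, data = dat),
               stats::lm(f3, data = dat))

  steps <- lapply(fits, function(fit) {
    sm <- summary(fit)
    ct <- sm$coefficients
    if (!is.null(cluster) && cluster %in% names(dat)) {
      vc <- sandwich::vcovCL(fit, cluster = dat[[cluster]])
      se <- sqrt(diag(vc))
      tval <- stats::coef(fit) / se
      ct <- cbind(Estimate = stats::coef(fit), `Std. Error` = se,
                  `t value` = tval,
                  `Pr(>|t|)` = 2 * stats::pt(abs(tval), fit$df.residual,
                                             lower.tail = FALSE))
    }
    fs <- sm$fstatistic
    rn <- rownames(ct)
    rn[rn == ".interaction"] <- int_term
    rownames(ct) <- rn
    list(coefficients = ct, r.squared = sm$r.squared,
         adj.r.squared = sm$adj.r.squared,
         fstatistic = unname(fs[1]), df = unname(fs[2:3]),
         model_p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  })

  cmp <- lapply(1:2, function(k) {
    an <- stats::anova(fits[[k]], fits[[k + 1L]])
    list(dR2 = steps[[k + 1L]]$r.squared - steps[[k]]$r.squared,
         dF_diff = steps[[k + 1L]]$fstatistic - steps[[k]]$fstatistic,
         partial_F = an$F[2], partial_df = c(an$Df[2], an$Res.Df[2]),
         p = an$`Pr(>F)`[2])
  })

  structure(list(outcome = outcome, controls = controls,
                 predictors = predictors, moderator = moderator,
                 focal = focal, interaction = int_term,
                 fits = fits, steps = steps, comparisons = cmp,
                 n = n, center = std$center, scale = std$scale,
                 cluster = cluster,
                 cluster_values = if (!is.null(cluster) &&
                                      cluster %in% names(dat))
                   dat[[cluster]],
                 call = match.call()),
            class = "hrv_hfit")
}

#' @export
print.hrv_hfit <- function(x, digits = 3, ...) {
  cat("Hierarchical regression for", x$outcome,
      sprintf("(N = %d windows)\n\n", x$n))
  terms_all <- rownames(x$steps[[3]]$coefficients)
  tab <- sapply(x$steps, function(s) {
    b <- s$coefficients[, "Estimate"][terms_all]
    p <- s$coefficients[, "Pr(>|t|)"][terms_all]
    ifelse(is.na(b), "",
           paste0(formatC(b, digits = digits, format = "f"), .p_stars(p)))
  })
  rownames(tab) <- sub("^\\(Intercept\\)$", "Intercept", terms_all)
  colnames(tab) <- paste("Step", 1:3)
  stats_tab <- rbind(
    `R^2` = sapply(x$steps, function(s) formatC(s$r.squared, digits = digits,
                                                format = "f")),
    `Adj. R^2` = sapply(x$steps, function(s)
      formatC(s$adj.r.squared, digits = digits, format = "f")),
    `F` = sapply(x$steps, function(s)
      paste0(formatC(s$fstatistic, digits = digits, format = "f"),
             .p_stars(s$model_p))),
    `Delta R^2` = c("", sapply(x$comparisons, function(cc)
      formatC(cc$dR2, digits = digits, format = "f"))),
    `Delta F` = c("", sapply(x$comparisons, function(cc)
      paste0(formatC(cc$dF_diff, digits = digits, format = "f"),
             .p_stars(cc$p)))))
  print(rbind(tab, stats_tab), quote = FALSE, right = TRUE)
  cat("\nStars: *** p<0.001, ** p<0.01, * p<0.05, . p<0.1",
      "(Delta F stars: partial-F test p)\n")
  invisible(x)
}

#' Summarize a hierarchical fit
#'
#' @param object an `hrv_hfit`.
#' @param ... unused.
#' @return list of per-step coefficient tables and model statistics, plus
#'   the between-step comparisons, of class `summary.hrv_hfit`.
#' @export
summary.hrv_hfit <- function(object, ...) {
  structure(list(outcome = object$outcome, n = object$n,
                 steps = object$steps, comparisons = object$comparisons,
                 cluster = object$cluster),
            class = "summary.hrv_hfit")
}

#' @export
print.summary.hrv_hfit <- function(x, digits = 4, ...) {
  cat("Hierarchical regression for", x$outcome,
      sprintf("(N = %d windows)\n", x$n))
  if (!is.null(x$cluster))
    cat("Cluster-robust SEs by", x$cluster, "\n")
  for (k in 1:3) {
    s <- x$steps[[k]]
    cat(sprintf("\n-- Step %d: R^2 = %.*f, adj. R^2 = %.*f, F(%d, %d) = %.*f, p = %.4g\n",
                k, digits, s$r.squared, digits, s$adj.r.squared,
                s$df[1], s$df[2], digits, s$fstatistic, s$model_p))
    stats::printCoefmat(s$coefficients, digits = digits,
                        signif.stars = TRUE)
    if (k > 1) {
      cc <- x$comparisons[[k - 1]]
      cat(sprintf("   vs step %d: dR^2 = %.*f, dF (F_k - F_{k-1}) = %.*f, partial F(%d, %d) = %.*f, p = %.4g\n",
                  k - 1, digits, cc$dR2, digits, cc$dF_diff,
                  cc$partial_df[1], cc$partial_df[2], digits, cc$partial_F,
                  cc$p))
    }
  }
  invisible(x)
}

#' @export
coef.hrv_hfit <- function(object, step = 3, ...) {
  stats::coef(object$fits[[step]])
}

#' @export
vcov.hrv_hfit <- function(object, step = 3, ...) {
  fit <- object$fits[[step]]
  if (!is.null(object$cluster_values))
    sandwich::vcovCL(fit, cluster = object$cluster_values)
  else stats::vcov(fit)
}

#' @export
residuals.hrv_hfit <- function(object, step = 3, ...) {
  stats::residuals(object$fits[[step]])
}

#' @export
fitted.hrv_hfit <- function(object, step = 3, ...) {
  stats::fitted(object$fits[[step]])
}

#' @export
nobs.hrv_hfit <- function(object, ...) object$n

#' Predict five-week outcome change for new windows
#'
#' New data are given on the original (unstandardized) scale; they are
#' standardized with the training means/SDs, the interaction product is
#' formed, and the standardized prediction is mapped back to outcome
#' units.
#'
#' @param object an `hrv_hfit`.
#' @param newdata data frame with the control and predictor columns on
#'   their original scales. Omitted: predictions for the training windows.
#' @param step which step's model to use (default 3).
#' @param ... unused.
#' @return numeric vector of predicted outcome changes (original units).
#' @export
predict.hrv_hfit <- function(object, newdata = NULL, step = 3, ...) {
  fit <- object$fits[[step]]
  if (is.null(newdata)) {
    z <- stats::fitted(fit)
  } else {
    vars <- c(object$controls, object$predictors)
    miss <- setdiff(vars, names(newdata))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    zd <- as.data.frame(Map(
      function(v) (newdata[[v]] - object$center[[v]]) / object$scale[[v]],
      stats::setNames(vars, vars)))
    zd$.interaction <- zd[[object$moderator]] * zd[[object$focal]]
    z <- stats::predict(fit, newdata = zd)
  }
  z * object$scale[[object$outcome]] + object$center[[object$outcome]]
}

#' Conditional (simple) slopes of the focal predictor across the moderator
#'
#' For the step-3 model, the conditional coefficient of the focal
#' predictor (HRVsd trend) at standardized moderator value h is
#' `b_focal + h * b_interaction`, with standard error
#' `sqrt(var_f + h^2 var_i + 2 h cov)` and a 95\% t confidence interval on
#' the fit's residual degrees of freedom. At h = 0 it equals the step-3
#' focal coefficient.
#'
#' @param fit an `hrv_hfit`.
#' @param moderator_values grid of standardized moderator values (default
#'   -2 to 2 by 0.1).
#' @param level confidence level (default 0.95).
#' @return data frame of class `hrv_simple_slopes`: `moderator`, `slope`,
#'   `se`, `lower`, `upper`, `t`, `p`, with attributes `df`, `focal`,
#'   `moderator_name`.
#' @export
simple_slopes <- function(fit, moderator_values = seq(-2, 2, by = 0.1),
                          level = 0.95) {
  stopifnot(inherits(fit, "hrv_hfit"))
  m3 <- fit$fits[[3]]
  vc <- vcov(fit, step = 3)
  b <- stats::coef(m3)
  if (anyNA(vc)) stop("coefficient covariance unavailable")
  fterm <- fit$focal; iterm <- ".interaction"
  slope <- b[fterm] + moderator_values * b[iterm]
  se <- sqrt(vc[fterm, fterm] + moderator_values^2 * vc[iterm, iterm] +
               2 * moderator_values * vc[fterm, iterm])
  df <- m3$df.residual
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  tval <- slope / se
  out <- data.frame(moderator = moderator_values, slope = unname(slope),
                    se = unname(se), lower = unname(slope - tcrit * se),
                    upper = unname(slope + tcrit * se), t = unname(tval),
                    p = unname(2 * stats::pt(abs(tval), df,
                                             lower.tail = FALSE)))
  structure(out, df = df, focal = fit$focal,
            moderator_name = fit$moderator, outcome = fit$outcome,
            class = c("hrv_simple_slopes", "data.frame"))
}

#' @export
plot.hrv_simple_slopes <- function(x, ...) {
  mo <- attr(x, "moderator_name"); fo <- attr(x, "focal")
  graphics::plot(x$moderator, x$slope, type = "n",
                 ylim = range(x$lower, x$upper, 0),
                 xlab = paste("Standardized", mo),
                 ylab = paste("Conditional coefficient of", fo), ...)
  graphics::polygon(c(x$moderator, rev(x$moderator)),
                    c(x$lower, rev(x$upper)),
                    col = grDevices::grey(0.85), border = NA)
  graphics::lines(x$moderator, x$slope, lwd = 2)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Plot a hierarchical fit
#'
#' `which = "moderation"` draws the conditional-coefficient (buffering)
#' profile of the focal predictor across the moderator with its 95\% band;
#' `which = "association"` a scatter of the standardized outcome against
#' the standardized focal predictor with the simple OLS line and 95\%
#' confidence band.
#'
#' @param x an `hrv_hfit`.
#' @param which `"moderation"` or `"association"`.
#' @param ... passed to the underlying plot.
#' @export
plot.hrv_hfit <- function(x, which = c("moderation", "association"), ...) {
  which <- match.arg(which)
  if (which == "moderation") {
    plot(simple_slopes(x), main = paste("Buffering profile:", x$outcome), ...)
  } else {
    dat <- x$fits[[3]]$model
    xx <- dat[[x$focal]]; yy <- dat[[x$outcome]]
    sf <- stats::lm(yy ~ xx)
    grid <- seq(min(xx), max(xx), length.out = 100)
    pr <- stats::predict(sf, newdata = data.frame(xx = grid),
                         interval = "confidence")
    graphics::plot(xx, yy, xlab = paste("Standardized", x$focal),
                   ylab = paste("Standardized", x$outcome),
                   main = paste(x$outcome, "vs", x$focal), ...)
    graphics::polygon(c(grid, rev(grid)), c(pr[, "lwr"], rev(pr[, "upr"])),
                      col = grDevices::adjustcolor("grey", 0.5), border = NA)
    graphics::lines(grid, pr[, "fit"], lwd = 2)
    graphics::points(xx, yy)
  }
  invisible(x)
}

#' Pairwise correlation table with significance stars
#'
#' Pearson correlations over pairwise-complete windows with two-sided
#' p-values; stars at 0.05 / 0.01 / 0.001.
#'
#' @param windows window table (or `hrv_std`).
#' @param variables columns to correlate.
#' @return object of class `hrv_cortab`: list with matrices `r`, `p`,
#'   `n`, and `stars`.
#' @export
correlation_table <- function(windows, variables) {
  dat <- if (inherits(windows, "hrv_std")) windows$data else windows
  miss <- setdiff(variables, names(dat))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  k <- length(variables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- dat[[variables[i]]]; y <- dat[[variables[j]]]
    ok <- !is.na(x) & !is.na(y)
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(x[ok], y[ok])
      r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
    }
  }
  stars <- matrix(ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                   ifelse(p < 0.05, "*", ""))), k, k,
                  dimnames = dimnames(r))
  diag(stars) <- ""
  structure(list(r = r, p = p, n = n, stars = stars), class = "hrv_cortab")
}

#' @export
print.hrv_cortab <- function(x, digits = 2, ...) {
  k <- nrow(x$r)
  out <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) next
    out[i, j] <- if (i == j) "-" else if (is.na(x$r[i, j])) "NA" else
      paste0(formatC(x$r[i, j], digits = digits, format = "f"),
             x$stars[i, j])
  }
  print(out, quote = FALSE, right = TRUE)
  cat("Pearson r, pairwise-complete; *** p<0.001, ** p<0.01, * p<0.05\n")
  invisible(x)
}
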