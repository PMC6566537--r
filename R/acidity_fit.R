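#' Interpolated threshold-crossing date
#'
#' The reference date of a plot (the day its mean acidity falls to 1.4, or
#' the day 20% of its fruit turn orange) is estimated by linear interpolation
#' between the two observation dates whose measured values bracket the
#' threshold. The first crossing in time (in the stated direction) is
#' returned; an observation lying exactly on the threshold returns that
#' observation's day. When the series never crosses, a warning of class
#' `acidrop_threshold_not_reached` is signalled and `NA_real_` returned, so
#' callers decide whether to exclude the plot.
#'
#' @param day numeric observation times (season days), strictly increasing.
#' @param value measured values at `day`.
#' @param threshold the value whose crossing date is sought.
#' @param direction `"falling"` (acidity drop) or `"rising"` (coloration).
#' @return the interpolated crossing day (numeric), or `NA_real_`.
#' @examples
#' date_at_threshold(c(280, 294), c(1.6, 1.3), 1.4, "falling") # 289.33
#' @export
date_at_threshold <- function(day, value, threshold,
                              direction = c("falling", "rising")) {
  direction <- match.arg(direction)
  stopifnot(length(day) == length(value))
  keep <- is.finite(day) & is.finite(value)
  day <- day[keep]; value <- value[keep]
  if (length(day) < 2L) {
    return(threshold_not_reached(sprintf(
      "fewer than two finite observations; %s crossing of %.3g undefined",
      direction, threshold
    )))
  }
  if (is.unsorted(day, strictly = TRUE)) {
    stop("observation days must be strictly increasing", call. = FALSE)
  }
  s <- if (direction == "falling") -1 else 1
  v <- s * (value - threshold) # crossing: v goes from < 0 to >= 0

  on_obs <- which(v == 0)
  first_cross <- NA_integer_
  for (i in seq_len(length(day) - 1L)) {
    if (v[i] < 0 && v[i + 1L] >= 0) { first_cross <- i; break }
  }
  if (length(on_obs) && (is.na(first_cross) || on_obs[1] <= first_cross)) {
    return(day[on_obs[1]])
  }
  if (is.na(first_cross)) {
    return(threshold_not_reached(sprintf(
      "series never crosses %.3g %s", threshold, direction
    )))
  }
  i <- first_cross
  day[i] + (threshold - value[i]) * (day[i + 1L] - day[i]) / (value[i + 1L] - value[i])
}

threshold_not_reached <- function(msg) {
  warning(warningCondition(msg, class = "acidrop_threshold_not_reached"))
  NA_real_
}

#' Drop observations after the first harvest
#'
#' Picking removes fruit and can shift the mean acidity of what remains on
#' the tree, so the model is fitted only to data up to each plot's first
#' harvest date. Observations strictly after `first_harvest_date` are
#' removed; an observation on the harvest date itself is retained, and plots
#' with no recorded harvest date are left untouched.
#'
#' @param series a plot series from [build_plot_series()].
#' @param plots plot metadata (`plot_id`, `year`, `first_harvest_date`).
#' @return the filtered series.
#' @export
truncate_at_first_harvest <- function(series, plots) {
  meta <- plots[c("plot_id", "year", "first_harvest_date")]
  out <- dplyr::left_join(series, meta, by = c("plot_id", "year"))
  keep <- is.na(out$first_harvest_date) | out$date <= out$first_harvest_date
  out <- out[keep, , drop = FALSE]
  out$first_harvest_date <- NULL
  out
}

#' Center acidity trajectories at the acidity-1.4 date
#'
#' Each plot's trajectory is re-expressed on a common clock whose origin
#' `t0` is the interpolated date where plot acidity reaches the reference
#' value (default 1.4 g citric acid / 100 g juice, the upper harvestability
#' bound): `t = day - t0_day`, acidities unchanged. Plots that never reach
#' the reference within their observed window are excluded with a warning
#' (no extrapolation). Shifting all of a plot's dates by `d` days shifts its
#' `t0_day` by exactly `d` and leaves the centered series unchanged.
#'
#' @param series plot series (ideally after [truncate_at_first_harvest()]).
#' @param reference centering acidity (default 1.4).
#' @return tibble: `plot_id`, `year`, `day`, `t`, `acidity`, `t0_day`.
#' @export
center_series <- function(series, reference = 1.4) {
  centered <- series |>
    dplyr::group_by(.data$plot_id, .data$year) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::mutate(t0_day = withCallingHandlers(
      date_at_threshold(.data$day, .data$Am, reference, "falling"),
      acidrop_threshold_not_reached = function(w) invokeRestart("muffleWarning")
    )) |>
    dplyr::ungroup()

  dropped <- centered |>
    dplyr::filter(is.na(.data$t0_day)) |>
    dplyr::distinct(.data$plot_id, .data$year)
  if (nrow(dropped)) {
    warning(sprintf(
      "excluding %d plot-year(s) that never reach acidity %.3g: %s",
      nrow(dropped), reference,
      paste(dropped$plot_id, dropped$year, sep = "/", collapse = ", ")
    ), call. = FALSE)
  }

  centered |>
    dplyr::filter(!is.na(.data$t0_day)) |>
    dplyr::transmute(
      .data$plot_id, .data$year, .data$day,
      t = .data$day - .data$t0_day, acidity = .data$Am, .data$t0_day
    )
}

#' Fit the pooled asymptotic acidity-drop model
#'
#' One curve is fitted by unweighted nonlinear least squares to the pooled
#' centered points of every plot and year (Levenberg–Marquardt via
#' [minpack.lm::nlsLM()]), with the reference acidity `A0` held fixed so
#' only `Asym` and `lrc` are estimated. Default start values are
#' `Asym = 0.9 * min(acidity)` and `lrc = log(log(2) / (t half-range))`.
#' `R2 = 1 - SS_res/SS_tot` is computed on the pooled points against their
#' grand mean. On data generated exactly from the model the generating
#' parameters are recovered to numerical precision. Non-convergence (for
#' example a constant series with no spread) yields `converged = FALSE`
#' with `NA` parameters rather than an error.
#'
#' @param centered centered trajectories from [center_series()] (columns
#'   `t`, `acidity`, plus `plot_id`/`year` labels kept on the residuals).
#' @param A0 fixed acidity at `t = 0` (default 1.4).
#' @param start optional named list/vector with `Asym` and `lrc` starts.
#' @param control an [stats::nls.control()] list (default tolerance 1e-10).
#' @return an `acidity_fit`: list with `params` ([asymp_params]),
#'   `residuals` (tibble `plot_id`, `year`, `t`, `acidity`, `fitted`,
#'   `resid`), `R2`, `n_obs`, `converged`, and the underlying `fit` object.
#' @export
fit_acidity_drop <- function(centered, A0 = 1.4, start = NULL,
                             control = stats::nls.control(maxiter = 200, tol = 1e-10)) {
  df <- tibble::tibble(
    plot_id = if ("plot_id" %in% names(centered)) centered$plot_id else "pooled",
    year = if ("year" %in% names(centered)) centered$year else NA_integer_,
    t = centered$t, acidity = centered$acidity, A0 = A0
  )
  failed <- function(msg) {
    structure(list(
      params = NULL, residuals = NULL, R2 = NA_real_,
      n_obs = nrow(df), converged = FALSE, message = msg, fit = NULL
    ), class = "acidity_fit")
  }
  if (length(unique(df$t)) < 2L || sd(df$acidity) == 0) {
    return(failed("degenerate input: need >= 2 distinct t and nonzero acidity spread"))
  }
  if (is.null(start)) {
    start <- list(
      Asym = 0.9 * min(df$acidity),
      lrc = log(log(2) / (diff(range(df$t)) / 2))
    )
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      acidity ~ Asym + (A0 - Asym) * exp(-exp(lrc) * t),
      data = df, start = start, control = control
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))

  est <- coef(fit)
  if (est[["Asym"]] >= A0) return(failed("fitted asymptote at or above A0"))
  params <- asymp_params(Asym = est[["Asym"]], A0 = A0, lrc = est[["lrc"]])
  fitted_vals <- acidity_curve(df$t, params)
  res <- df$acidity - fitted_vals
  structure(list(
    params = params,
    residuals = tibble::tibble(
      plot_id = df$plot_id, year = df$year, t = df$t,
      acidity = df$acidity, fitted = fitted_vals, resid = res
    ),
    R2 = 1 - sum(res^2) / sum((df$acidity - mean(df$acidity))^2),
    n_obs = nrow(df), converged = TRUE, message = NULL, fit = fit
  ), class = "acidity_fit")
}

#' @export
print.acidity_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<acidity_fit> NOT converged (%s), n = %d\n", x$message, x$n_obs))
    return(invisible(x))
  }
  cat(sprintf(
    "<acidity_fit> n = %d, R2 = %.4f\n  Asym = %.5f, A0 = %.5f (fixed), lrc = %.5f\n",
    x$n_obs, x$R2, x$params$Asym, x$params$A0, x$params$lrc
  ))
  invisible(x)
}

#' Genericity check: year and plot effects on the fit residuals
#'
#' If a single pooled curve describes every plot in both years, the fit
#' residuals should carry no year or plot structure. This tests the two main
#' effects on the residuals by ANOVA — by default a two-way additive model
#' with type-II sums of squares ([car::Anova()]); `type = "one-way"` tests
#' each factor separately with [stats::aov()]. A factor with a single
#' observed level gets an `NA` p-value.
#'
#' @param fit an `acidity_fit` from [fit_acidity_drop()] (or any data frame
#'   with `resid`, `year`, `plot_id` columns).
#' @param type `"two-way"` (type-II, default) or `"one-way"`.
#' @return list with `p_year` and `p_plot`.
#' @export
residual_effects_test <- function(fit, type = c("two-way", "one-way")) {
  type <- match.arg(type)
  df <- if (inherits(fit, "acidity_fit")) {
    if (!fit$converged) stop("fit did not converge; no residuals to test", call. = FALSE)
    fit$residuals
  } else {
    tibble::as_tibble(fit)
  }
  df <- tibble::tibble(
    resid = df$resid,
    year = factor(df$year),
    plot = factor(df$plot_id)
  )
  p <- list(p_year = NA_real_, p_plot = NA_real_)
  has_year <- nlevels(droplevels(df$year)) >= 2L
  has_plot <- nlevels(droplevels(df$plot)) >= 2L
  if (type == "two-way" && has_year && has_plot) {
    m <- lm(resid ~ year + plot, data = df)
    a <- car::Anova(m, type = 2)
    p$p_year <- a["year", "Pr(>F)"]
    p$p_plot <- a["plot", "Pr(>F)"]
  } else {
    if (has_year) {
      p$p_year <- summary(aov(resid ~ year, data = df))[[1]][["Pr(>F)"]][1]
    }
    if (has_plot) {
      p$p_plot <- summary(aov(resid ~ plot, data = df))[[1]][["Pr(>F)"]][1]
    }
  }
  p
}
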