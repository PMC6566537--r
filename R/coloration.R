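#' Color milestones: when a plot's fruit turn orange
#'
#' External maturity is tracked through `P_O`, the pooled share of fruit
#' classed orange. `date_percent_orange()` interpolates, per plot-year, the
#' first date `P_O` rises through a threshold (default 20%, the working
#' indicator for the start of the harvest round). `color_milestones()` then
#' situates that date relative to the acidity drop: `offset_days` is the lag
#' after the plot's acidity-1.4 date, and the acidity prevailing at the
#' milestone is reported two ways — `acidity_model`, the pooled model
#' evaluated at the offset, and `acidity_measured`, linear interpolation of
#' the measured `Am` series at the milestone date. Plots that never reach the
#' color threshold (or have no color data) keep `NA` milestones.
#'
#' @param series a plot series from [build_plot_series()] with `P_O`.
#' @param threshold percent-orange threshold as a proportion in (0, 1\];
#'   default 0.20.
#' @return `date_percent_orange()`: tibble `plot_id`, `year`,
#'   `day_reached` (season day, `NA` when never reached).
#' @export
date_percent_orange <- function(series, threshold = 0.20) {
  stopifnot(length(threshold) == 1, threshold > 0, threshold <= 1)
  series |>
    dplyr::group_by(.data$plot_id, .data$year) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      day_reached = withCallingHandlers(
        date_at_threshold(.data$day, .data$P_O, threshold, "rising"),
        acidrop_threshold_not_reached = function(w) invokeRestart("muffleWarning")
      ),
      .groups = "drop"
    )
}

#' @rdname date_percent_orange
#' @param centered centered acidity trajectories from [center_series()]
#'   (supplies each plot's `t0_day`).
#' @param params pooled model parameters ([asymp_params]).
#' @return `color_milestones()`: tibble `plot_id`, `year`, `threshold`,
#'   `day_reached`, `offset_days`, `acidity_model`, `acidity_measured`.
#' @export
color_milestones <- function(series, centered, params, threshold = 0.20) {
  t0 <- dplyr::distinct(centered, .data$plot_id, .data$year, .data$t0_day)
  reached <- date_percent_orange(series, threshold)

  measured_at <- series |>
    dplyr::inner_join(reached, by = c("plot_id", "year")) |>
    dplyr::group_by(.data$plot_id, .data$year) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      acidity_measured = if (is.na(.data$day_reached[1])) NA_real_ else {
        stats::approx(.data$day, .data$Am, xout = .data$day_reached[1], rule = 1)$y
      },
      .groups = "drop"
    )

  reached |>
    dplyr::inner_join(t0, by = c("plot_id", "year")) |>
    dplyr::left_join(measured_at, by = c("plot_id", "year")) |>
    dplyr::mutate(
      threshold = threshold,
      offset_days = .data$day_reached - .data$t0_day,
      acidity_model = ifelse(
        is.na(.data$offset_days), NA_real_,
        acidity_curve(.data$offset_days, params)
      )
    ) |>
    dplyr::select(dplyr::all_of(c(
      "plot_id", "year", "threshold", "day_reached", "offset_days",
      "acidity_model", "acidity_measured"
    )))
}
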