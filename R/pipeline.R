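#' Run the full maturity-analysis pipeline
#'
#' Chains every analysis stage on one dataset: plot-level aggregation,
#' truncation at first harvest, centering at the acidity reference, pooled
#' asymptotic fit with residual genericity ANOVA, color milestones,
#' harvestability windows, and the association table. Thresholds default to
#' the studied quality rules: acidity bounds 0.65–1.4 g citric acid / 100 g
#' juice, color milestone at 20% orange, laboratory sampling above 5%
#' caliber frequency.
#'
#' @param dataset an `orchard_dataset` (e.g. from [simulate_orchards()] or
#'   [read_orchard_dataset()]).
#' @param acid_upper centering reference and upper harvestable acidity.
#' @param acid_lower lower harvestable acidity.
#' @param color_threshold percent-orange milestone threshold (proportion).
#' @param sampling_threshold caliber sampling rule (proportion).
#' @param renormalize renormalize caliber frequencies over sampled calibers
#'   (see [plot_mean_acidity()]).
#' @return list with `series`, `centered`, `fit`, `residual_anova`
#'   (`p_year`, `p_plot`), `milestones`, `windows`, `associations`,
#'   `plot_summary`, and `settings` (the thresholds used).
#' @export
run_maturity_pipeline <- function(dataset,
                                  acid_upper = 1.4, acid_lower = 0.65,
                                  color_threshold = 0.20,
                                  sampling_threshold = 0.05,
                                  renormalize = TRUE) {
  series <- build_plot_series(dataset, sampling_threshold, renormalize)
  truncated <- truncate_at_first_harvest(series, dataset$plots)
  centered <- center_series(truncated, reference = acid_upper)
  fit <- fit_acidity_drop(centered, A0 = acid_upper)
  if (!fit$converged) {
    stop(sprintf("pooled acidity fit failed: %s", fit$message), call. = FALSE)
  }
  res_anova <- residual_effects_test(fit)
  milestones <- color_milestones(series, centered, fit$params, color_threshold)
  windows <- harvest_windows(milestones, centered, fit$params,
                             acid_lower, acid_upper)
  plot_summary <- plot_year_summary(dataset, series, centered, milestones)
  associations <- association_table(plot_summary)
  list(
    series = series,
    centered = centered,
    fit = fit,
    residual_anova = res_anova,
    milestones = milestones,
    windows = windows,
    associations = associations,
    plot_summary = plot_summary,
    settings = list(
      acid_upper = acid_upper, acid_lower = acid_lower,
      color_threshold = color_threshold,
      sampling_threshold = sampling_threshold,
      renormalize = renormalize
    )
  )
}

#' Per-plot-year summary of covariates and estimated milestones
#'
#' Collapses the pipeline stages to one row per plot-year: full-bloom
#' day-of-year, mean fruit weight at the first observation (week 40), the
#' estimated acidity-1.4 day, the 20%-orange day and the measured acidity at
#' that date — the variables entering [association_table()].
#'
#' @param dataset an `orchard_dataset`.
#' @param series plot series from [build_plot_series()].
#' @param centered centered trajectories from [center_series()].
#' @param milestones milestone table from [color_milestones()].
#' @return tibble with one row per plot-year.
#' @export
plot_year_summary <- function(dataset, series, centered, milestones) {
  w40 <- series |>
    dplyr::group_by(.data$plot_id, .data$year) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(weight_week40_g = .data$mean_fruit_weight_g[1],
                     .groups = "drop")
  t0 <- dplyr::distinct(centered, .data$plot_id, .data$year, .data$t0_day)
  bloom <- dplyr::transmute(
    dataset$plots, .data$plot_id, .data$year,
    full_bloom_doy = as.POSIXlt(.data$full_bloom_date)$yday + 1
  )
  bloom |>
    dplyr::left_join(w40, by = c("plot_id", "year")) |>
    dplyr::left_join(t0, by = c("plot_id", "year")) |>
    dplyr::left_join(
      dplyr::transmute(milestones, .data$plot_id, .data$year,
                       day20_orange = .data$day_reached,
                       acidity_at_20 = .data$acidity_measured),
      by = c("plot_id", "year")
    )
}
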