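#' Harvestability windows under acidity bounds
#'
#' Under the studied quality rules, fruit may be picked only while plot
#' acidity lies between `acid_lower` and `acid_upper` (defaults 0.65 and
#' 1.4 g citric acid / 100 g juice) *and* the fruit are naturally colored.
#' The window therefore opens at the later of the plot's color milestone and
#' its acidity-1.4 date (acidity is already below the ceiling from `t0` on),
#' and closes when the fitted model predicts acidity reaching the floor:
#' `close = t0 + acidity_inverse(acid_lower)`. A plot whose coloring arrives
#' after the close — or never — has an empty window. The close is
#' model-based rather than interpolated because late-season measurements are
#' sparse relative to the fitted curve.
#'
#' `harvest_window()` computes one window from scalar inputs;
#' `harvest_windows()` maps over a milestone table.
#'
#' @param t0_day season day at which plot acidity reached `acid_upper`.
#' @param params pooled model parameters ([asymp_params]).
#' @param milestone_day season day of the color milestone (`NA` if never
#'   reached).
#' @param acid_lower,acid_upper harvestable acidity bounds (defaults 0.65
#'   and 1.4).
#' @return `harvest_window()`: one-row tibble with `open_day`, `close_day`,
#'   `width_days`, `empty`, `acid_lower`, `acid_upper`.
#' @export
harvest_window <- function(t0_day, params, milestone_day,
                           acid_lower = 0.65, acid_upper = 1.4) {
  stopifnot(acid_lower < acid_upper)
  if (acid_lower <= params$Asym) {
    stop(sprintf(
      "lower bound unreachable: model asymptote %.4f is at or above %.4f",
      params$Asym, acid_lower
    ), call. = FALSE)
  }
  close_day <- t0_day + acidity_inverse(acid_lower, params)
  open_day <- if (is.na(milestone_day)) NA_real_ else max(milestone_day, t0_day)
  empty <- is.na(open_day) || open_day > close_day
  tibble::tibble(
    open_day = open_day,
    close_day = close_day,
    width_days = if (empty) 0 else close_day - open_day,
    empty = empty,
    acid_lower = acid_lower,
    acid_upper = acid_upper
  )
}

#' @rdname harvest_window
#' @param milestones milestone table from [color_milestones()] (columns
#'   `plot_id`, `year`, `day_reached`) carrying each plot's `t0_day` via
#'   `centered`.
#' @param centered centered trajectories from [center_series()].
#' @return `harvest_windows()`: tibble `plot_id`, `year`, `open_day`,
#'   `close_day`, `open_date`, `close_date`, `width_days`, `empty`,
#'   `acid_lower`, `acid_upper`.
#' @export
harvest_windows <- function(milestones, centered, params,
                            acid_lower = 0.65, acid_upper = 1.4) {
  t0 <- dplyr::distinct(centered, .data$plot_id, .data$year, .data$t0_day)
  df <- dplyr::inner_join(milestones, t0, by = c("plot_id", "year"))
  win <- purrr::pmap_dfr(
    list(df$t0_day, df$day_reached),
    function(t0_day, day_reached) {
      harvest_window(t0_day, params, day_reached, acid_lower, acid_upper)
    }
  )
  dplyr::bind_cols(df[c("plot_id", "year")], win) |>
    dplyr::mutate(
      open_date = dplyr::if_else(
        is.na(.data$open_day), as.Date(NA), season_date(.data$open_day, .data$year)
      ),
      close_date = season_date(.data$close_day, .data$year)
    ) |>
    dplyr::select(dplyr::all_of(c(
      "plot_id", "year", "open_day", "close_day", "open_date", "close_date",
      "width_days", "empty", "acid_lower", "acid_upper"
    )))
}

#' Plot one plot-year's harvestability window
#'
#' Draws the fitted acidity curve and the measured percent-orange trajectory
#' for one plot-year on a common season-day axis, with the harvestability
#' window shaded between its open and close dates and the two acidity bounds
#' marked. The percent-orange curve is scaled onto the acidity axis
#' (secondary axis on the right).
#'
#' @param series plot series for the plot-year (columns `day`, `Am`, `P_O`).
#' @param window one row of [harvest_windows()].
#' @param centered centered trajectories (for the plot's `t0_day`).
#' @param params pooled model parameters.
#' @return a ggplot object.
#' @export
plot_harvest_window <- function(series, window, centered, params) {
  sel <- series$plot_id == window$plot_id & series$year == window$year
  s <- series[sel, , drop = FALSE]
  t0 <- centered$t0_day[centered$plot_id == window$plot_id &
                          centered$year == window$year][1]
  grid <- tibble::tibble(
    day = seq(min(s$day), max(max(s$day), window$close_day + 7), by = 0.5)
  )
  grid$model <- acidity_curve(grid$day - t0, params)
  a_max <- max(s$Am, params$A0, na.rm = TRUE)

  gg <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$day))
  if (!window$empty) {
    gg <- gg + ggplot2::annotate(
      "rect", xmin = window$open_day, xmax = window$close_day,
      ymin = -Inf, ymax = Inf, fill = "palegreen3", alpha = 0.35
    )
  }
  gg +
    ggplot2::geom_hline(yintercept = c(window$acid_lower, window$acid_upper),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "steelblue4") +
    ggplot2::geom_point(data = s, ggplot2::aes(y = .data$Am),
                        colour = "steelblue4") +
    ggplot2::geom_line(data = s[!is.na(s$P_O), ],
                       ggplot2::aes(y = .data$P_O * a_max),
                       colour = "darkorange2") +
    ggplot2::geom_point(data = s[!is.na(s$P_O), ],
                        ggplot2::aes(y = .data$P_O * a_max),
                        colour = "darkorange2") +
    ggplot2::scale_y_continuous(
      "acidity (g citric acid / 100 g juice)",
      sec.axis = ggplot2::sec_axis(~ . / a_max, name = "orange fruit (proportion)")
    ) +
    ggplot2::labs(
      x = "season day (days since July 1)",
      title = sprintf("Plot %s, %d", window$plot_id, window$year),
      subtitle = if (window$empty) "empty harvestability window" else
        sprintf("harvestability window: %.1f days", window$width_days)
    ) +
    ggplot2::theme_minimal()
}
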