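#' Configuration for the synthetic orchard-monitoring generator
#'
#' The study's field data are not public, so the generator emulates the
#' monitoring campaign's statistical structure: two seasons with 19 and 26
#' plots (18 plots in common), five control trees per plot scored biweekly
#' from week 40 (season day 92, early October) to season end; each plot's
#' latent acidity follows the asymptotic drop curve shifted in time, with
#' the acidity-1.4 dates spread over 32 days (2013) and 38 days (2014) and
#' the 2014 dates centered 20 days earlier; fruit coloring is logistic in
#' time, reaching 20% orange 11–47 days after the plot's acidity-1.4 date;
#' week-40 fruit weight is tied to the acidity-drop timing through a
#' Gaussian copula with correlation -0.65 (bigger fruit, earlier drop); and
#' the first harvest falls on the first observation date at or after the
#' 20%-orange date.
#'
#' @param years seasons to simulate.
#' @param n_plots named integer vector, plots per year.
#' @param n_common number of plot ids shared between consecutive years.
#' @param true_params generating [asymp_params] (defaults to the pooled
#'   estimates 0.55852 / -3.50741 with `A0 = 1.4`).
#' @param t0_center_day named: center of each year's acidity-1.4 dates
#'   (season days). Defaults (135 for 2013, 115 for 2014 — mid/late
#'   November vs early November) keep the 20-day year shift and place every
#'   plot's reference crossing inside the week-40-onward observation window,
#'   so each plot's t0 is identifiable by interpolation.
#' @param t0_spread_days named: full width of each year's uniform t0 spread.
#' @param color_offset_range days between a plot's acidity-1.4 date and its
#'   20%-orange date (uniform).
#' @param weight_t0_correlation Gaussian-copula correlation between week-40
#'   fruit weight and t0 (negative: heavier fruit drop earlier).
#' @param obs_start_day,obs_end_day,obs_interval_days observation grid in
#'   season days (defaults: 92 to 204, biweekly).
#' @param n_trees control trees per plot.
#' @param n_calibers ordered fruit-size classes (indices 0..n_calibers-1).
#' @param acidity_noise_sd sd of per-caliber titratable-acidity measurement
#'   noise (g/100 g).
#' @param caliber_acidity_effect relative acidity decrease per caliber class
#'   above the plot's mean class (larger fruit slightly less acidic).
#' @param caliber_concentration,color_noise_concentration Dirichlet
#'   concentrations for per-tree frequency scores around the plot-level
#'   truth (`Inf` = no tree-to-tree noise).
#' @param caliber_sd sd (in class units) of the within-plot caliber
#'   distribution.
#' @param caliber_drift_per_day upward drift of the mean caliber class as
#'   fruit grow.
#' @param color_slope logistic slope of the orange share (1/day).
#' @param yellow_lead_days how many days the yellow stage precedes orange.
#' @param weight_mean_g,weight_sd_g distribution of plot mean fruit weight
#'   at week 40.
#' @param mass_base_g,mass_per_class_g linear map from caliber class to
#'   fruit mass.
#' @param mass_noise_sd_g sd of sample mean fruit mass around the class mass.
#' @param juice_mean,juice_sd juice fraction distribution.
#' @param bloom_mean_doy,bloom_sd_days full-bloom day-of-year distribution.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(
    years = c(2013L, 2014L),
    n_plots = c("2013" = 19L, "2014" = 26L),
    n_common = 18L,
    true_params = asymp_params(Asym = 0.55852, A0 = 1.4, lrc = -3.50741),
    t0_center_day = c("2013" = 135, "2014" = 115),
    t0_spread_days = c("2013" = 32, "2014" = 38),
    color_offset_range = c(11, 47),
    weight_t0_correlation = -0.65,
    obs_start_day = 92, obs_end_day = 204, obs_interval_days = 14,
    n_trees = 5L, n_calibers = 10L,
    acidity_noise_sd = 0.05,
    caliber_acidity_effect = 0.015,
    caliber_concentration = 60,
    color_noise_concentration = 80,
    caliber_sd = 1.3,
    caliber_drift_per_day = 0.018,
    color_slope = 0.1,
    yellow_lead_days = 12,
    weight_mean_g = 65, weight_sd_g = 7,
    mass_base_g = 40, mass_per_class_g = 6,
    mass_noise_sd_g = 1.5,
    juice_mean = 0.45, juice_sd = 0.015,
    bloom_mean_doy = 121, bloom_sd_days = 6) {
  cfg <- as.list(environment())
  yrs <- as.character(years)
  if (!all(yrs %in% names(n_plots)) || !all(yrs %in% names(t0_center_day)) ||
      !all(yrs %in% names(t0_spread_days))) {
    stop("n_plots, t0_center_day and t0_spread_days must be named by year",
         call. = FALSE)
  }
  if (abs(weight_t0_correlation) >= 1) {
    stop("weight_t0_correlation must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (diff(color_offset_range) < 0 || any(color_offset_range < 0)) {
    stop("color_offset_range must be a nonnegative, nondecreasing pair", call. = FALSE)
  }
  if (acidity_noise_sd < 0 || juice_sd < 0 || mass_noise_sd_g < 0 ||
      caliber_concentration <= 0 || color_noise_concentration <= 0) {
    stop("noise parameters must be nonnegative (concentrations positive)", call. = FALSE)
  }
  if (obs_end_day <= obs_start_day || obs_interval_days <= 0) {
    stop("observation grid is empty", call. = FALSE)
  }
  if (n_common > min(n_plots[yrs])) {
    stop("n_common exceeds a year's plot count", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Dirichlet draws via normalized gamma variates; alpha rows -> simplex rows.
# concentration = Inf returns the mean proportions exactly.
rdirichlet_rows <- function(alpha) {
  if (any(!is.finite(alpha))) stop("alpha must be finite", call. = FALSE)
  g <- matrix(rgamma(length(alpha), shape = pmax(alpha, 1e-8)), nrow = nrow(alpha))
  g / rowSums(g)
}

#' Simulate a full orchard-monitoring campaign
#'
#' Draws the latent per-plot quantities (acidity-drop timing `t0`, week-40
#' fruit weight, color-milestone offset, full-bloom date), then generates
#' the four observation tables a field campaign would produce (plot
#' metadata, per-tree caliber scores, per-tree color scores, per-caliber
#' laboratory samples). Laboratory samples are produced for every caliber
#' whose realized pooled frequency exceeds the 5% sampling rule. All latent
#' quantities are returned in a ground-truth table so parameter recovery can
#' be scored.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; identical config + seed reproduces the dataset
#'   exactly.
#' @return list with `dataset` (an `orchard_dataset`), `truth` (tibble:
#'   `plot_id`, `year`, `t0_day`, `color20_day`, `offset_days`,
#'   `weight_week40_g`, `full_bloom_doy`), and `config`.
#' @export
simulate_orchards <- function(config = simulation_config(), seed = 20130407) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  cfg <- config
  obs_days <- seq(cfg$obs_start_day, cfg$obs_end_day, by = cfg$obs_interval_days)

  plot_ids_year <- function(year_idx, n, n_common) {
    if (year_idx == 1) return(sprintf("P%02d", seq_len(n)))
    c(sprintf("P%02d", seq_len(n_common)),
      sprintf("P%02d", seq(cfg$n_plots[1] + 1, length.out = n - n_common)))
  }

  truth <- purrr::map_dfr(seq_along(cfg$years), function(k) {
    yr <- cfg$years[k]
    ychr <- as.character(yr)
    n <- cfg$n_plots[[ychr]]
    rho <- cfg$weight_t0_correlation
    z_t0 <- rnorm(n)
    z_w <- rho * z_t0 + sqrt(1 - rho^2) * rnorm(n)
    ctr <- cfg$t0_center_day[[ychr]]
    spr <- cfg$t0_spread_days[[ychr]]
    t0 <- ctr - spr / 2 + spr * pnorm(z_t0)
    offs <- runif(n, cfg$color_offset_range[1], cfg$color_offset_range[2])
    tibble::tibble(
      plot_id = plot_ids_year(k, n, cfg$n_common),
      year = as.integer(yr),
      t0_day = t0,
      offset_days = offs,
      color20_day = t0 + offs,
      weight_week40_g = cfg$weight_mean_g + cfg$weight_sd_g * z_w,
      full_bloom_doy = round(rnorm(n, cfg$bloom_mean_doy, cfg$bloom_sd_days))
    )
  })

  # plot metadata
  first_harvest_day <- vapply(truth$color20_day, function(cd) {
    h <- obs_days[obs_days >= cd]
    if (length(h)) h[1] else NA_real_
  }, numeric(1))
  plots <- tibble::tibble(
    plot_id = truth$plot_id,
    year = truth$year,
    management = sample(c("organic", "conventional"), nrow(truth),
                        replace = TRUE, prob = c(0.25, 0.75)),
    rootstock = sample(c("Poncirus Pomeroy", "Citrange Carrizo", "Citrange Troyer"),
                       nrow(truth), replace = TRUE),
    full_bloom_date = as.Date(sprintf("%d-01-01", truth$year)) + truth$full_bloom_doy - 1,
    first_harvest_date = dplyr::if_else(
      is.na(first_harvest_day), as.Date(NA),
      season_date(first_harvest_day, truth$year)
    )
  )

  # plot-date latent state (one row per plot-year x observation day)
  pd <- tidyr::expand_grid(
    truth[c("plot_id", "year", "t0_day", "color20_day", "weight_week40_g")],
    day = obs_days
  )
  mu0 <- pmin(pmax((pd$weight_week40_g - cfg$mass_base_g) / cfg$mass_per_class_g,
                   0.5), cfg$n_calibers - 1.5)
  pd$mu_c <- pmin(mu0 + cfg$caliber_drift_per_day * (pd$day - cfg$obs_start_day),
                  cfg$n_calibers - 0.5)
  pd$acidity <- acidity_curve(pd$day - pd$t0_day, cfg$true_params)
  dmid <- pd$color20_day + stats::qlogis(0.8) / cfg$color_slope
  pd$p_orange <- plogis(cfg$color_slope * (pd$day - dmid))
  p_colored <- plogis(cfg$color_slope * (pd$day - dmid + cfg$yellow_lead_days))
  pd$p_yellow <- p_colored - pd$p_orange
  pd$p_green <- 1 - p_colored
  pd$date <- season_date(pd$day, pd$year)

  # per-tree caliber scores: Dirichlet around the plot-level class profile
  classes <- seq_len(cfg$n_calibers) - 1L
  f_true <- outer(pd$mu_c, classes, function(m, c) {
    stats::dnorm(c, mean = m, sd = cfg$caliber_sd)
  })
  f_true <- f_true / rowSums(f_true)

  cells <- tidyr::expand_grid(
    pd_row = seq_len(nrow(pd)),
    tree = seq_len(cfg$n_trees) - 1L
  )
  f_rep <- f_true[cells$pd_row, , drop = FALSE]
  f_tree <- if (is.finite(cfg$caliber_concentration)) {
    rdirichlet_rows(f_rep * cfg$caliber_concentration)
  } else {
    f_rep
  }
  idx <- rep(seq_len(nrow(cells)), each = cfg$n_calibers)
  calibers <- tibble::tibble(
    plot_id = pd$plot_id[cells$pd_row][idx],
    year = pd$year[cells$pd_row][idx],
    date = pd$date[cells$pd_row][idx],
    tree = cells$tree[idx],
    caliber = rep(classes, times = nrow(cells)),
    freq = round(as.vector(t(f_tree)) * 100, 3) # row-major: cell by cell
  )

  # per-tree color scores
  col_true <- cbind(pd$p_green, pd$p_yellow, pd$p_orange)
  col_rep <- col_true[cells$pd_row, , drop = FALSE]
  col_tree <- if (is.finite(cfg$color_noise_concentration)) {
    rdirichlet_rows(pmax(col_rep, 1e-6) * cfg$color_noise_concentration)
  } else {
    col_rep
  }
  cidx <- rep(seq_len(nrow(cells)), each = 3L)
  colors <- tibble::tibble(
    plot_id = pd$plot_id[cells$pd_row][cidx],
    year = pd$year[cells$pd_row][cidx],
    date = pd$date[cells$pd_row][cidx],
    tree = cells$tree[cidx],
    color = rep(c("green", "yellow", "orange"), times = nrow(cells)),
    freq = round(as.vector(t(col_tree)) * 100, 3)
  )

  # laboratory samples for calibers above the realized 5% rule
  pooledF <- calibers |>
    dplyr::group_by(.data$plot_id, .data$year, .data$date, .data$caliber) |>
    dplyr::summarise(f = sum(.data$freq), .groups = "drop_last") |>
    dplyr::mutate(F = .data$f / sum(.data$f)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$F > 0.05)
  samp <- pooledF |>
    dplyr::left_join(
      pd[c("plot_id", "year", "date", "mu_c", "acidity")],
      by = c("plot_id", "year", "date")
    )
  tA <- samp$acidity * (1 - cfg$caliber_acidity_effect * (samp$caliber - samp$mu_c)) +
    rnorm(nrow(samp), 0, cfg$acidity_noise_sd)
  samples <- tibble::tibble(
    plot_id = samp$plot_id, year = samp$year, date = samp$date,
    caliber = samp$caliber, n_fruit = 10L,
    mean_fruit_mass_g = cfg$mass_base_g + cfg$mass_per_class_g * samp$caliber +
      rnorm(nrow(samp), 0, cfg$mass_noise_sd_g),
    juice_fraction = pmin(pmax(
      rnorm(nrow(samp), cfg$juice_mean, cfg$juice_sd), 0.2), 0.8),
    titratable_acidity = pmax(tA, 0.05)
  )

  dataset <- orchard_dataset(
    plots = plots,
    calibers = calibers[c("plot_id", "year", "date", "tree", "caliber", "freq")],
    colors = colors[c("plot_id", "year", "date", "tree", "color", "freq")],
    samples = samples,
    n_calibers = cfg$n_calibers, n_trees = cfg$n_trees
  )
  list(dataset = dataset, truth = truth, config = cfg)
}

#' Generate centered acidity trajectories directly
#'
#' A direct fixture for [fit_acidity_drop()]: `n_plots` trajectories whose
#' acidities are the asymptotic curve evaluated on `t_grid` plus independent
#' Gaussian noise.
#'
#' @param params generating [asymp_params].
#' @param t_grid days relative to the reference date.
#' @param n_plots number of trajectories.
#' @param noise_sd Gaussian noise sd (0 = points exactly on the curve).
#' @param seed integer seed.
#' @return tibble: `plot_id`, `year` (`NA`), `t`, `acidity`.
#' @export
generate_centered_trajectories <- function(params, t_grid, n_plots = 10,
                                           noise_sd = 0, seed = 20130407) {
  stopifnot(length(t_grid) >= 1, n_plots >= 1, noise_sd >= 0)
  set.seed(seed)
  out <- tidyr::crossing(
    plot_id = sprintf("S%02d", seq_len(n_plots)),
    t = as.numeric(t_grid)
  )
  out$year <- NA_integer_
  out$acidity <- acidity_curve(out$t, params) + rnorm(nrow(out), 0, noise_sd)
  out[c("plot_id", "year", "t", "acidity")]
}
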