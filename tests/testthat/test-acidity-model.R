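test_that("date_at_threshold interpolates the first crossing", {
  expect_equal(date_at_threshold(c(280, 294), c(1.6, 1.3), 1.4, "falling"),
               280 + 14 * (1.6 - 1.4) / (1.6 - 1.3))
  # an observation exactly on the threshold returns its own day
  expect_equal(date_at_threshold(c(280, 290, 300), c(1.6, 1.4, 1.2), 1.4,
                                 "falling"), 290)
  # never crossing: NA plus a classed warning
  expect_warning(
    res <- date_at_threshold(c(280, 294), c(1.8, 1.5), 1.4, "falling"),
    class = "acidrop_threshold_not_reached"
  )
  expect_true(is.na(res))
  # a noisy re-crossing series: the first falling crossing wins
  expect_equal(
    date_at_threshold(c(0, 10, 20, 30), c(1.6, 1.2, 1.5, 1.1), 1.4, "falling"),
    5 # between 1.6 and 1.2
  )
  # rising direction mirrors falling
  expect_equal(date_at_threshold(c(300, 314), c(0.10, 0.30), 0.20, "rising"),
               307)
  expect_error(date_at_threshold(c(10, 5), c(1, 2), 1.5, "falling"),
               "strictly increasing")
})

test_that("observations after the first harvest are removed, boundary kept", {
  days <- seq(92, 162, by = 14) # 6 observation dates
  series <- tibble::tibble(
    plot_id = "P01", year = 2013L,
    date = season_date(days, 2013), day = days,
    Am = seq(2.2, 0.9, length.out = 6)
  )
  plots <- tibble::tibble(plot_id = "P01", year = 2013L,
                          first_harvest_date = season_date(days[4], 2013))
  kept <- truncate_at_first_harvest(series, plots)
  expect_equal(nrow(kept), 4L)
  expect_equal(max(kept$date), plots$first_harvest_date) # boundary retained

  plots$first_harvest_date <- as.Date(NA)
  expect_equal(nrow(truncate_at_first_harvest(series, plots)), 6L)
})

test_that("centering puts t = 0 at the interpolated 1.4 date and is shift-equivariant", {
  p <- eq7_params()
  days <- seq(92, 176, by = 14)
  t0_true <- 120
  series <- tibble::tibble(
    plot_id = "A", year = 2013L, date = season_date(days, 2013),
    day = days, Am = acidity_curve(days - t0_true, p)
  )
  cen <- center_series(series)
  # noiseless interpolation: t0 within the biweekly discretization bound
  expect_lt(abs(cen$t0_day[1] - t0_true), 1)
  expect_equal(cen$t, cen$day - cen$t0_day[1])
  expect_equal(cen$acidity, series$Am)

  # shifting every date by +7 days shifts t0 by 7, centered series unchanged
  shifted <- series
  shifted$day <- shifted$day + 7
  shifted$date <- season_date(shifted$day, 2013)
  cen7 <- center_series(shifted)
  expect_equal(cen7$t0_day[1], cen$t0_day[1] + 7, tolerance = 1e-9)
  expect_equal(cen7$t, cen$t, tolerance = 1e-9)
  expect_equal(cen7$acidity, cen$acidity)

  # plots never reaching the reference are excluded with a warning
  high <- series
  high$Am <- high$Am + 1
  both <- dplyr::bind_rows(series, dplyr::mutate(high, plot_id = "B"))
  expect_warning(cen_b <- center_series(both), "B/2013")
  expect_equal(unique(cen_b$plot_id), "A")
})

test_that("the asymptotic curve matches its closed-form values and inverse", {
  p <- eq7_params()
  expect_identical(acidity_curve(0, p), 1.4) # anchor, exact
  expect_equal(acidity_curve(20, p), 1.02057008, tolerance = 1e-7)
  expect_equal(acidity_curve(1e6, p), p$Asym, tolerance = 1e-9)
  t <- seq(-30, 90, by = 0.5)
  expect_true(all(diff(acidity_curve(t, p)) < 0)) # strictly decreasing

  expect_equal(acidity_inverse(0.65, p), 74.0311178, tolerance = 1e-6)
  expect_equal(acidity_inverse(1.4, p), 0)
  expect_equal(acidity_inverse(1.10, p), 14.7077310, tolerance = 1e-6)
  expect_error(acidity_inverse(0.5, p), "must lie in")
  expect_error(acidity_inverse(1.5, p), "must lie in")

  # round-trip identities on the domain
  a <- seq(p$Asym + 1e-3, p$A0, length.out = 50)
  expect_equal(acidity_curve(acidity_inverse(a, p), p), a, tolerance = 1e-9)
  tt <- seq(0, 120, length.out = 50)
  expect_equal(acidity_inverse(acidity_curve(tt, p), p), tt, tolerance = 1e-9)

  expect_error(asymp_params(Asym = 1.5, A0 = 1.4, lrc = -3), "below A0")
})

test_that("the pooled fit recovers generating parameters", {
  p <- eq7_params()
  traj <- generate_centered_trajectories(p, seq(-28, 56, by = 14),
                                         n_plots = 5, noise_sd = 0)
  fit <- fit_acidity_drop(traj)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$Asym - p$Asym) / abs(p$Asym), 1e-6)
  expect_lt(abs(fit$params$lrc - p$lrc) / abs(p$lrc), 1e-6)
  expect_equal(fit$R2, 1, tolerance = 1e-9)
  expect_equal(mean(fit$residuals$resid), 0, tolerance = 1e-9)

  # degenerate: constant series is flagged, not an error
  flat <- tibble::tibble(t = c(0, 10, 20), acidity = c(1.4, 1.4, 1.4))
  expect_false(fit_acidity_drop(flat)$converged)

  # noisy recovery stays near the truth
  noisy <- generate_centered_trajectories(p, seq(-28, 56, by = 14),
                                          n_plots = 20, noise_sd = 0.05,
                                          seed = 99)
  nf <- fit_acidity_drop(noisy)
  expect_true(nf$converged)
  expect_lt(abs(nf$params$Asym - p$Asym), 0.03)
  expect_lt(abs(nf$params$lrc - p$lrc), 0.15)
})

test_that("noisy fits are unbiased over Monte-Carlo replicates", {
  p <- eq7_params()
  asym_hat <- vapply(1:200, function(i) {
    traj <- generate_centered_trajectories(p, seq(-28, 56, by = 14),
                                           n_plots = 15, noise_sd = 0.05,
                                           seed = 5000 + i)
    fit_acidity_drop(traj)$params$Asym
  }, numeric(1))
  expect_lt(abs(mean(asym_hat) - p$Asym), 0.02)
})

test_that("residual ANOVA flags real effects and ignores absent ones", {
  set.seed(11)
  base <- tidyr::expand_grid(
    plot_id = sprintf("P%02d", 1:8), year = c(2013L, 2014L), rep = 1:5
  )
  # a strong year effect is detected
  shifted <- base
  shifted$resid <- rnorm(nrow(base), 0, 0.03) + ifelse(base$year == 2014L, 0.3, 0)
  p_eff <- residual_effects_test(shifted)
  expect_lt(p_eff$p_year, 0.001)

  # residual values identical across plots: no plot effect whatsoever
  same <- base
  same$resid <- rep(seq(-0.02, 0.02, length.out = 5),
                    times = nrow(base) / 5)
  p_same <- residual_effects_test(same)
  expect_gt(p_same$p_plot, 0.999)

  # a single year level yields NA for that factor
  one_year <- shifted[shifted$year == 2013L, ]
  p_one <- residual_effects_test(one_year)
  expect_true(is.na(p_one$p_year))
  expect_false(is.na(p_one$p_plot))
})
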