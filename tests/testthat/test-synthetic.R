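test_that("same config and seed reproduce the dataset exactly", {
  cfg <- simulation_config()
  a <- simulate_orchards(cfg, seed = 123)
  b <- simulate_orchards(cfg, seed = 123)
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth, b$truth)
  c <- simulate_orchards(cfg, seed = 124)
  expect_false(identical(a$dataset$samples, c$dataset$samples))

  # byte-identical files under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_orchard_dataset(a$dataset, d1)
  write_orchard_dataset(b$dataset, d2)
  for (f in c("plots.csv", "calibers.csv", "colors.csv", "samples.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generated datasets satisfy every input invariant", {
  sim <- simulate_orchards(seed = 9)
  expect_silent(validate_orchard_dataset(sim$dataset))
  expect_equal(nrow(sim$dataset$plots), 19 + 26)
  expect_equal(sum(sim$dataset$plots$year == 2013), 19)
  expect_equal(sum(sim$dataset$plots$year == 2014), 26)
  # 18 plot ids observed in both years
  both <- table(unique(sim$dataset$plots[c("plot_id", "year")])$plot_id)
  expect_equal(sum(both == 2), 18)
  # per-year t0 spreads and year shift follow the configured conditions
  tr <- sim$truth
  rng <- tapply(tr$t0_day, tr$year, function(v) diff(range(v)))
  expect_lte(rng[["2013"]], 32)
  expect_lte(rng[["2014"]], 38)
  expect_true(all(tr$offset_days >= 11 & tr$offset_days <= 47))
  expect_lt(mean(tr$t0_day[tr$year == 2014]), mean(tr$t0_day[tr$year == 2013]))
})

test_that("zero-noise single-plot data reproduce the latent curve exactly", {
  cfg <- simulation_config(
    years = 2013L, n_plots = c("2013" = 1L), n_common = 1L,
    acidity_noise_sd = 0, caliber_acidity_effect = 0
  )
  sim <- simulate_orchards(cfg, seed = 4)
  series <- build_plot_series(sim$dataset)
  latent <- acidity_curve(series$day - sim$truth$t0_day, cfg$true_params)
  # Am is a weighted mean of per-caliber acidities that all equal the latent
  # value, so it matches to rounding of the stored scores
  expect_equal(series$Am, latent, tolerance = 1e-9)
})

test_that("the weight/t0 copula hits the configured correlation", {
  cfg <- simulation_config(n_plots = c("2013" = 150L, "2014" = 150L),
                           n_common = 18L)
  sim <- simulate_orchards(cfg, seed = 21)
  tr <- sim$truth
  for (yr in c(2013L, 2014L)) {
    r <- cor(tr$weight_week40_g[tr$year == yr], tr$t0_day[tr$year == yr])
    expect_lt(abs(r - (-0.65)), 0.15) # n = 150 sampling band
  }
})

test_that("generate_centered_trajectories is exact at zero noise and seeded", {
  p <- eq7_params()
  grid <- seq(-28, 56, by = 14)
  tr <- generate_centered_trajectories(p, grid, n_plots = 3, noise_sd = 0)
  expect_equal(nrow(tr), 3 * length(grid))
  expect_equal(tr$acidity, acidity_curve(tr$t, p))
  a <- generate_centered_trajectories(p, grid, 5, 0.05, seed = 31)
  b <- generate_centered_trajectories(p, grid, 5, 0.05, seed = 31)
  expect_identical(a, b)
})

test_that("impossible configurations are rejected", {
  expect_error(simulation_config(weight_t0_correlation = -1), "strictly inside")
  expect_error(simulation_config(color_offset_range = c(47, 11)), "nondecreasing")
  expect_error(simulation_config(acidity_noise_sd = -0.1), "nonnegative")
  expect_error(simulation_config(n_common = 25L), "exceeds")
})
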