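one_plot_date <- function(caliber, freq) {
  tibble::tibble(caliber = caliber, freq = freq)
}

test_that("caliber_frequency pools tree scores and normalizes to 1", {
  # tree-summed scores {0: 30, 1: 10} split over trees
  obs <- tibble::tibble(caliber = c(0L, 0L, 1L), freq = c(20, 10, 10))
  prof <- caliber_frequency(obs)
  expect_equal(prof$F, c(0.75, 0.25))
  expect_equal(sum(prof$F), 1)

  expect_equal(caliber_frequency(one_plot_date(3L, 12))$F, 1)
  expect_equal(caliber_frequency(one_plot_date(0:2, c(1, 1, 2)))$F,
               c(0.25, 0.25, 0.5))
  expect_error(caliber_frequency(one_plot_date(0:1, c(0, 0))), "all frequencies")

  # invariance to a positive rescaling of every raw score
  scaled <- caliber_frequency(one_plot_date(0:2, 17.3 * c(1, 1, 2)))
  expect_equal(scaled$F, c(0.25, 0.25, 0.5))
})

test_that("the 5% sampling rule is a strict inequality", {
  prof <- caliber_frequency(one_plot_date(0:2, c(5, 15, 80)))
  expect_equal(prof$sampled, c(FALSE, TRUE, TRUE)) # exactly 5% excluded
})

test_that("percent_orange is the pooled orange share", {
  obs <- tibble::tibble(
    color = c("green", "yellow", "orange"), freq = c(40, 40, 20)
  )
  expect_equal(percent_orange(obs), 0.20)
  expect_equal(percent_orange(obs[obs$color == "green", ]), 0)
  expect_equal(percent_orange(obs[obs$color == "orange", ]), 1)
  obs$freq <- obs$freq * 3.7
  expect_equal(percent_orange(obs), 0.20)
  expect_error(
    percent_orange(tibble::tibble(color = "green", freq = 0)),
    "all color frequencies"
  )
})

test_that("plot_mean_acidity does the juice-mass bookkeeping", {
  profile <- tibble::tibble(caliber = 0:1, F = c(0.6, 0.4),
                            sampled = c(TRUE, TRUE))
  samples <- tibble::tibble(
    caliber = 0:1, mean_fruit_mass_g = c(80, 100),
    juice_fraction = c(0.45, 0.50), titratable_acidity = c(1.2, 1.0)
  )
  res <- plot_mean_acidity(profile, samples)
  expect_equal(res$breakdown$m_juice_g, c(21.6, 20.0))
  expect_equal(res$Am, 45.92 / 41.6, tolerance = 1e-12)

  expect_equal(mean_fruit_weight(profile, samples), 88)
  samples_eq <- samples
  profile_eq <- profile
  profile_eq$F <- c(0.5, 0.5)
  expect_equal(mean_fruit_weight(profile_eq, samples_eq), 90)

  # one caliber only -> its own acidity
  expect_equal(
    plot_mean_acidity(profile[1, ], samples[1, ])$Am, 1.2
  )
  # constant acidity -> Am equals it whatever F, J, m
  samples_const <- samples
  samples_const$titratable_acidity <- 0.93
  expect_equal(plot_mean_acidity(profile, samples_const)$Am, 0.93)

  # missing sample for a sampled caliber is an error naming the caliber
  expect_error(plot_mean_acidity(profile, samples[1, ]), "caliber\\(s\\): 1")
})

test_that("Am is a weighted mean: bounded by the sampled acidities", {
  set.seed(101)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    profile <- tibble::tibble(
      caliber = seq_len(k) - 1L,
      F = {
        w <- runif(k); w / sum(w)
      },
      sampled = TRUE
    )
    samples <- tibble::tibble(
      caliber = profile$caliber,
      mean_fruit_mass_g = runif(k, 50, 120),
      juice_fraction = runif(k, 0.3, 0.6),
      titratable_acidity = runif(k, 0.6, 2.5)
    )
    Am <- plot_mean_acidity(profile, samples)$Am
    expect_gte(Am, min(samples$titratable_acidity))
    expect_lte(Am, max(samples$titratable_acidity))
    # invariance to uniform rescaling of the profile
    profile2 <- profile
    profile2$F <- profile$F * 4.2
    expect_equal(plot_mean_acidity(profile2, samples, renormalize = FALSE)$Am,
                 plot_mean_acidity(profile, samples, renormalize = FALSE)$Am)
  }
})

test_that("aggregated Am equals the brute-force per-fruit weighted mean", {
  for (seed in 1:10) {
    pop <- brute_force_population(seed)
    expect_equal(population_Am_via_aggregation(pop), pop$Am_brute,
                 tolerance = 1e-9)
  }
})

test_that("build_plot_series composes the per-date operations", {
  ds <- toy_dataset()
  series <- build_plot_series(ds)
  expect_equal(nrow(series), 2L)
  expect_equal(series$Am, rep(45.92 / 41.6, 2), tolerance = 1e-12)
  expect_equal(series$P_O, rep(0.2, 2))
  expect_equal(series$mean_fruit_weight_g, rep(88, 2))
  expect_equal(series$day, c(92, 106))

  # order-invariance: shuffled input rows give the identical series
  shuffled <- orchard_dataset(
    ds$plots,
    ds$calibers[sample(nrow(ds$calibers)), ],
    ds$colors[sample(nrow(ds$colors)), ],
    ds$samples[sample(nrow(ds$samples)), ]
  )
  expect_equal(build_plot_series(shuffled), series)

  # no color data: the series still carries Am, with P_O absent
  no_color <- orchard_dataset(ds$plots, ds$calibers, ds$colors[0, ], ds$samples)
  s2 <- build_plot_series(no_color)
  expect_equal(s2$Am, series$Am)
  expect_true(all(is.na(s2$P_O)))
})
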