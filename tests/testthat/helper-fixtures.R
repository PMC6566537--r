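# Shared fixtures: tiny handcrafted datasets and brute-force oracles.

eq7_params <- function() asymp_params(Asym = 0.55852, A0 = 1.4, lrc = -3.50741)

# one plot, two dates, two calibers (0 and 1) with the hand-worked sample
# values: F = 0.6/0.4, J = 0.45/0.50, m = 80/100 g, tA = 1.2/1.0
toy_dataset <- function() {
  dates <- as.Date(c("2013-10-01", "2013-10-15"))
  calibers <- tidyr::expand_grid(
    plot_id = "P01", year = 2013L, date = dates,
    tree = 0:4, caliber = 0:1
  )
  calibers$freq <- ifelse(calibers$caliber == 0, 6, 4) # pooled 30 vs 20 -> 0.6/0.4
  colors <- tidyr::expand_grid(
    plot_id = "P01", year = 2013L, date = dates,
    tree = 0:4, color = c("green", "yellow", "orange")
  )
  colors$freq <- c(green = 8, yellow = 8, orange = 4)[colors$color]
  samples <- tidyr::expand_grid(
    plot_id = "P01", year = 2013L, date = dates, caliber = 0:1
  )
  samples$n_fruit <- 10L
  samples$mean_fruit_mass_g <- ifelse(samples$caliber == 0, 80, 100)
  samples$juice_fraction <- ifelse(samples$caliber == 0, 0.45, 0.50)
  samples$titratable_acidity <- ifelse(samples$caliber == 0, 1.2, 1.0)
  plots <- tibble::tibble(
    plot_id = "P01", year = 2013L, management = "organic",
    rootstock = "Poncirus Pomeroy",
    full_bloom_date = as.Date("2013-05-01"),
    first_harvest_date = as.Date(NA)
  )
  orchard_dataset(plots, calibers, colors, samples)
}

# brute-force oracle: a fully enumerated fruit population where each fruit
# carries its caliber, mass, juice fraction and acidity; plot mean acidity is
# the juice-mass-weighted mean over individual fruit
brute_force_population <- function(seed = 1, n_calibers = 4) {
  set.seed(seed)
  counts <- sample(5:40, n_calibers)
  per_caliber <- tibble::tibble(
    caliber = seq_len(n_calibers) - 1L,
    count = counts,
    mass = runif(n_calibers, 60, 110),
    juice = runif(n_calibers, 0.35, 0.55),
    acid = runif(n_calibers, 0.7, 2.2)
  )
  fruit <- per_caliber[rep(seq_len(n_calibers), per_caliber$count), ]
  juice_mass <- fruit$mass * fruit$juice
  list(
    per_caliber = per_caliber,
    Am_brute = sum(fruit$acid * juice_mass) / sum(juice_mass)
  )
}

# run plot_mean_acidity on the per-caliber summary of a brute-force population
population_Am_via_aggregation <- function(pop) {
  pc <- pop$per_caliber
  profile <- tibble::tibble(
    caliber = pc$caliber,
    F = pc$count / sum(pc$count),
    sampled = TRUE
  )
  samples <- tibble::tibble(
    caliber = pc$caliber,
    mean_fruit_mass_g = pc$mass,
    juice_fraction = pc$juice,
    titratable_acidity = pc$acid
  )
  plot_mean_acidity(profile, samples)$Am
}
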