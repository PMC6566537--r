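#' Plot-level aggregation of field observations
#'
#' The monitoring protocol records, per control tree and date, frequency
#' scores over fruit-size classes (calibers) and over three color classes,
#' plus one ten-fruit laboratory sample for each caliber representing more
#' than 5% of the plot's fruit. These operations pool them to the plot level:
#'
#' * `caliber_frequency()` — plot caliber profile
#'   \eqn{F(c) = \sum_i f_c(i) / f_t}: tree scores summed per caliber, then
#'   divided by the plot-date total, so the profile sums to 1. Calibers with
#'   `F(c)` strictly above `sampling_threshold` are flagged `sampled`.
#' * `percent_orange()` — \eqn{P_O = \sum_i p_O(i) / p_t}, the pooled orange
#'   share of all color scores, in \[0, 1\].
#' * `plot_mean_acidity()` — juice-mass bookkeeping over the sampled
#'   calibers: per caliber, juice mass \eqn{m_{juice}(c) = J_c m_c F(c)} and
#'   acid mass \eqn{m_{acid}(c) = t_A(c)\, m_{juice}(c)}; the plot mean
#'   acidity is \eqn{Am = \sum_c m_{acid}(c) / \sum_c m_{juice}(c)} — the
#'   juice-mass-weighted mean of per-caliber titratable acidities, invariant
#'   to any uniform rescaling of the profile.
#' * `mean_fruit_weight()` — \eqn{\sum_c F(c) m_c} with `F` renormalized over
#'   sampled calibers.
#'
#' Both frequency operations are invariant to multiplying all raw scores by a
#' positive constant, so scores need not be normalized per tree.
#'
#' @param calibers caliber rows (`caliber`, `freq`) for one plot-date.
#' @param sampling_threshold proportion above which a caliber is laboratory
#'   sampled; strictly `F(c) > threshold` (default 0.05).
#' @return `caliber_frequency()`: tibble with `caliber`, `F`, `sampled`.
#' @export
caliber_frequency <- function(calibers, sampling_threshold = 0.05) {
  tot <- sum(calibers$freq)
  if (!isTRUE(tot > 0)) {
    stop("caliber profile undefined: all frequencies are zero", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(calibers, .data$caliber),
    F = sum(.data$freq) / tot, .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$caliber)
  out$sampled <- out$F > sampling_threshold
  out
}

#' @rdname caliber_frequency
#' @param colors color rows (`color`, `freq`) for one plot-date.
#' @export
percent_orange <- function(colors) {
  tot <- sum(colors$freq)
  if (!isTRUE(tot > 0)) {
    stop("percent orange undefined: all color frequencies are zero", call. = FALSE)
  }
  sum(colors$freq[colors$color == "orange"]) / tot
}

#' @rdname caliber_frequency
#' @param profile a caliber profile from `caliber_frequency()`.
#' @param samples laboratory sample rows for the same plot-date (`caliber`,
#'   `mean_fruit_mass_g`, `juice_fraction`, `titratable_acidity`).
#' @param renormalize if `TRUE` (default) the profile is renormalized over
#'   the sampled calibers before weighting, so `Am` stays a proper weighted
#'   mean when sub-threshold calibers are dropped; if `FALSE` the raw `F`
#'   values are used (the two agree whenever every caliber is sampled, since
#'   `Am` is scale-invariant in `F`).
#' @return `plot_mean_acidity()`: list with `Am` (g citric acid / 100 g
#'   juice) and `breakdown` (per-caliber `F_used`, `m_juice_g`, `m_acid`).
#' @export
plot_mean_acidity <- function(profile, samples, renormalize = TRUE) {
  use <- merge_sampled(profile, samples, renormalize)
  m_juice <- use$juice_fraction * use$mean_fruit_mass_g * use$F_used
  m_acid <- use$titratable_acidity * m_juice
  list(
    Am = sum(m_acid) / sum(m_juice),
    breakdown = tibble::tibble(
      caliber = use$caliber, F_used = use$F_used,
      m_juice_g = m_juice, m_acid = m_acid,
      titratable_acidity = use$titratable_acidity
    )
  )
}

#' @rdname caliber_frequency
#' @export
mean_fruit_weight <- function(profile, samples) {
  use <- merge_sampled(profile, samples, renormalize = TRUE)
  sum(use$F_used * use$mean_fruit_mass_g)
}

# join sampled calibers of a profile with their laboratory samples
merge_sampled <- function(profile, samples, renormalize) {
  sampled <- profile[profile$sampled, , drop = FALSE]
  if (nrow(sampled) == 0L) {
    stop("no caliber exceeds the sampling threshold", call. = FALSE)
  }
  missing <- setdiff(sampled$caliber, samples$caliber)
  if (length(missing)) {
    stop(sprintf(
      "missing laboratory sample for sampled caliber(s): %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  use <- dplyr::inner_join(sampled, samples, by = "caliber")
  use$F_used <- if (renormalize) use$F / sum(use$F) else use$F
  use
}

#' Build per-plot maturity series
#'
#' Runs the plot-level aggregation over every (plot_id, year, date) of a
#' dataset and returns one row per plot-date with the three maturity
#' summaries: mean acidity `Am`, percent orange `P_O` (NA on plot-dates
#' without color scores, as in a campaign whose color protocol started late),
#' and mean fruit weight. Rows are sorted by plot, year and date regardless
#' of input order; `day` is the season-day of `date`.
#'
#' @param dataset an `orchard_dataset`.
#' @inheritParams caliber_frequency
#' @inheritParams plot_mean_acidity
#' @return tibble: `plot_id`, `year`, `date`, `day`, `Am`, `P_O`,
#'   `mean_fruit_weight_g`.
#' @export
build_plot_series <- function(dataset, sampling_threshold = 0.05,
                              renormalize = TRUE) {
  stopifnot(inherits(dataset, "orchard_dataset"))
  keys <- c("plot_id", "year", "date")

  # caliber profiles, vectorized over plot-dates
  prof <- dataset$calibers |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "caliber")))) |>
    dplyr::summarise(f = sum(.data$freq), .groups = "drop_last") |>
    dplyr::mutate(tot = sum(.data$f), F = .data$f / .data$tot) |>
    dplyr::ungroup()
  if (any(prof$tot == 0)) {
    stop("caliber profile undefined: all frequencies are zero on some plot-date",
         call. = FALSE)
  }
  prof$sampled <- prof$F > sampling_threshold

  acid <- prof |>
    dplyr::filter(.data$sampled) |>
    dplyr::inner_join(dataset$samples, by = c(keys, "caliber")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_sampled = dplyr::n(),
      F_tot = sum(.data$F),
      Am = {
        w <- if (renormalize) .data$F / sum(.data$F) else .data$F
        mj <- .data$juice_fraction * .data$mean_fruit_mass_g * w
        sum(.data$titratable_acidity * mj) / sum(mj)
      },
      mean_fruit_weight_g = sum(.data$F / sum(.data$F) * .data$mean_fruit_mass_g),
      .groups = "drop"
    )

  # guard: every sampled caliber must carry a sample
  n_sampled_expected <- prof |>
    dplyr::filter(.data$sampled) |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "n_expected")
  chk <- dplyr::left_join(n_sampled_expected, acid, by = keys)
  bad <- is.na(chk$n_sampled) | chk$n_sampled != chk$n_expected
  if (any(bad)) {
    b <- chk[bad, ][1, ]
    stop(sprintf(
      "missing laboratory sample for sampled caliber(s) on %s/%s %s",
      b$plot_id, b$year, format(b$date)
    ), call. = FALSE)
  }

  po <- dataset$colors |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      P_O = sum(.data$freq[.data$color == "orange"]) / sum(.data$freq),
      .groups = "drop"
    )

  acid |>
    dplyr::left_join(po, by = keys) |>
    dplyr::mutate(day = season_day(.data$date, .data$year)) |>
    dplyr::arrange(.data$plot_id, .data$year, .data$date) |>
    dplyr::select(dplyr::all_of(c(
      "plot_id", "year", "date", "day", "Am", "P_O", "mean_fruit_weight_g"
    )))
}
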