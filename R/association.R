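#' Pairwise association as signed R-squared
#'
#' Associations between orchard characteristics (full-bloom date, week-40
#' fruit weight) and ripening milestones are summarized as the squared
#' Pearson correlation carrying the sign of the correlation —
#' `signed_R2 = sign(r) * r^2` — with the usual two-sided t-test p-value and
#' conventional significance stars (`*` p<0.05, `**` p<0.01, `***` p<0.001).
#' The raw `r` is always reported alongside. The statistic is symmetric in
#' its arguments and invariant under positive affine transforms of either.
#'
#' @param x,y numeric vectors of equal length; pairs with missing values are
#'   dropped; at least 3 complete pairs and nonzero variance required.
#' @return one-row tibble: `n`, `r`, `signed_R2`, `p`, `stars`.
#' @export
pairwise_association <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: association undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  tibble::tibble(
    n = length(x),
    r = r,
    signed_R2 = sign(r) * r^2,
    p = ct$p.value,
    stars = significance_stars(ct$p.value)
  )
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; used to
#' summarize the dispersion of plot acidities at a common color stage.
#' Scale-invariant: multiplying all values by a positive constant leaves the
#' CV unchanged.
#'
#' @param values numeric vector, `n >= 2`, positive mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("coefficient of variation requires a positive mean", call. = FALSE)
  100 * sd(values) / m
}

#' One-way ANOVA comparison across years
#'
#' Tests whether a per-plot summary (e.g. the day 20% of fruit are orange)
#' differs between years, by one-way ANOVA on the year factor.
#'
#' @param values numeric vector of per-plot values.
#' @param year grouping labels, at least 2 groups with `n >= 2` each.
#' @return the ANOVA p-value for the year effect.
#' @export
year_comparison <- function(values, year) {
  ok <- is.finite(values) & !is.na(year)
  values <- values[ok]; year <- factor(year[ok])
  tab <- table(year)
  if (nlevels(year) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  summary(aov(values ~ year))[[1]][["Pr(>F)"]][1]
}

#' Association table across maturity variables
#'
#' Builds, per year, the signed-R2 association table between orchard
#' characteristics and ripening milestones: full-bloom day-of-year and
#' week-40 fruit weight against the acidity-1.4 day, the 20%-orange day and
#' the acidity at the 20%-orange date, plus the associations among the three
#' milestones themselves.
#'
#' @param plot_summary tibble with one row per plot-year and (a subset of)
#'   the columns `year`, `full_bloom_doy`, `weight_week40_g`, `t0_day`,
#'   `day20_orange`, `acidity_at_20`.
#' @param pairs optional two-column character matrix/data.frame of variable
#'   pairs; defaults to the standard set above.
#' @return tibble: `year`, `x`, `y`, `n`, `r`, `signed_R2`, `p`, `stars`.
#' @export
association_table <- function(plot_summary, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- rbind(
      c("full_bloom_doy", "t0_day"),
      c("full_bloom_doy", "day20_orange"),
      c("full_bloom_doy", "acidity_at_20"),
      c("weight_week40_g", "t0_day"),
      c("weight_week40_g", "day20_orange"),
      c("weight_week40_g", "acidity_at_20"),
      c("t0_day", "day20_orange"),
      c("t0_day", "acidity_at_20"),
      c("day20_orange", "acidity_at_20")
    )
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs) <- c("x", "y")
  years <- sort(unique(plot_summary$year))
  purrr::map_dfr(years, function(yr) {
    d <- plot_summary[plot_summary$year == yr, , drop = FALSE]
    purrr::pmap_dfr(pairs, function(x, y) {
      if (!all(c(x, y) %in% names(d))) return(NULL)
      res <- tryCatch(pairwise_association(d[[x]], d[[y]]),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble::tibble(year = yr, x = x, y = y), res)
    })
  })
}
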