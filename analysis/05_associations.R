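#!/usr/bin/env Rscript
# Stage 5 — association table, dispersion and year comparisons.
#
# Signed-R2 associations between orchard characteristics (full-bloom date,
# week-40 fruit weight) and ripening milestones; the CV of acidity at the
# 20%-orange stage per year; and one-way ANOVA year comparisons of the
# milestone dates.

library(acidrop)

dataset <- read_orchard_dataset("results/synthetic")
series <- readr::read_csv("results/plot_series.csv", show_col_types = FALSE)
centered <- readr::read_csv("results/centered.csv", show_col_types = FALSE)
milestones <- readr::read_csv("results/milestones.csv", show_col_types = FALSE)

summary_tbl <- plot_year_summary(dataset, series, centered, milestones)
assoc <- association_table(summary_tbl)
readr::write_csv(assoc, "results/associations.csv")

cvs <- summary_tbl |>
  dplyr::filter(!is.na(acidity_at_20)) |>
  dplyr::group_by(year) |>
  dplyr::summarise(
    cv_acidity_at_20 = coefficient_of_variation(acidity_at_20),
    mean_acidity_at_20 = mean(acidity_at_20)
  )
readr::write_csv(cvs, "results/acidity_at_color_cv.csv")

ok <- !is.na(summary_tbl$day20_orange)
p_day20 <- year_comparison(summary_tbl$day20_orange[ok], summary_tbl$year[ok])
p_t0 <- year_comparison(summary_tbl$t0_day, summary_tbl$year)

cat("fruit weight at week 40 vs acidity-1.4 date (expected negative):\n")
print(as.data.frame(dplyr::filter(assoc, x == "weight_week40_g", y == "t0_day")))
for (i in seq_len(nrow(cvs))) {
  cat(sprintf("acidity at 20%% orange, %d: mean %.2f, CV %.1f%%\n",
              cvs$year[i], cvs$mean_acidity_at_20[i], cvs$cv_acidity_at_20[i]))
}
cat(sprintf("year effect: acidity-1.4 date p = %.2g, 20%%-orange date p = %.2g\n",
            p_t0, p_day20))
cat("-> results/associations.csv, results/acidity_at_color_cv.csv\n")
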