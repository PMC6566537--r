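#!/usr/bin/env Rscript
# Stage 4 — color milestones and harvestability windows.
#
# For each plot: the interpolated date 20% of fruit are orange, its offset
# after the acidity-1.4 date, the acidity prevailing then (model-based and
# measured), and the harvestability window [max(color date, acidity-1.4
# date), modelled 0.65 date]. Figures for the widest and narrowest non-empty
# windows go to results/figures/.

library(acidrop)

series <- readr::read_csv("results/plot_series.csv", show_col_types = FALSE)
centered <- readr::read_csv("results/centered.csv", show_col_types = FALSE)
fr <- jsonlite::read_json("results/fit_result.json")
params <- asymp_params(Asym = fr$Asym, A0 = fr$A0, lrc = fr$lrc)

milestones <- color_milestones(series, centered, params, threshold = 0.20)
windows <- harvest_windows(milestones, centered, params,
                           acid_lower = 0.65, acid_upper = 1.4)
readr::write_csv(milestones, "results/milestones.csv")
readr::write_csv(windows, "results/windows.csv")

off <- milestones$offset_days[!is.na(milestones$offset_days)]
cat(sprintf("20%%-orange dates fall %.0f-%.0f days after the acidity-1.4 date\n",
            min(off), max(off)))
cat(sprintf("windows: %d non-empty of %d; widths %.0f-%.0f days (median %.0f)\n",
            sum(!windows$empty), nrow(windows),
            min(windows$width_days[!windows$empty]),
            max(windows$width_days[!windows$empty]),
            median(windows$width_days[!windows$empty])))

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
nonempty <- windows[!windows$empty, ]
for (w in list(nonempty[which.max(nonempty$width_days), ],
               nonempty[which.min(nonempty$width_days), ])) {
  gg <- plot_harvest_window(series, w, centered, params)
  ggplot2::ggsave(
    sprintf("results/figures/window_%s_%d.pdf", w$plot_id, w$year),
    gg, width = 7, height = 4.5
  )
}
cat("-> results/milestones.csv, results/windows.csv, results/figures/\n")
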