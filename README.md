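# acidrop

Acidity-drop modelling and harvestability windows for clementine orchards
monitored without post-harvest degreening.

## The problem

Where degreening is prohibited (organic farming, protected-origin labels),
clementine can only be harvested while the fruit are *naturally colored on
the tree* **and** their titratable acidity sits inside the quality band —
0.65 to 1.4 g citric acid per 100 g juice. Internal ripening (the acidity
drop) and external ripening (peel coloration) are distinct processes that
need not coincide, so the interval during which a plot is legally and
commercially harvestable — its **harvestability window** — varies widely
between plots and years.

`acidrop` is for agronomists and analysts running longitudinal orchard
monitoring campaigns: per-tree caliber and color-class frequency scores plus
per-caliber ten-fruit laboratory samples, taken biweekly from week 40 until
the end of harvest.

## The model

Plot mean acidity is the juice-mass-weighted mean over laboratory-sampled
calibers,

    Am = Σ_c tA(c)·J_c·m_c·F(c) / Σ_c J_c·m_c·F(c),

and each plot's trajectory is centered at t₀, the interpolated date Am falls
to 1.4. On that common clock, one asymptotic decay curve is fitted to all
plots and years pooled:

    A(t) = Asym + (A0 − Asym)·exp(−exp(lrc)·t),   A0 = 1.4 fixed,

with `Asym` the end-of-ripening asymptote and `lrc` the log rate constant.
The window for a plot opens at the later of its 20%-orange date and t₀, and
closes at t₀ + t(0.65) from the closed-form inverse of the curve.

## Worked example

```r
library(acidrop)

sim <- simulate_orchards(seed = 20130407)   # two-season synthetic campaign
out <- run_maturity_pipeline(sim$dataset)

out$fit
#> <acidity_fit> n = 260, R2 = 0.9984
#>   Asym = 0.54502, A0 = 1.40000 (fixed), lrc = -3.53667

head(out$windows[c("plot_id", "year", "open_date", "close_date",
                   "width_days", "empty")], 3)
#> # A tibble: 3 × 6
#>   plot_id  year open_date  close_date width_days empty
#>   <chr>   <int> <date>     <date>          <dbl> <lgl>
#> 1 P01      2013 2013-11-26 2014-01-22       56.5 FALSE
#> 2 P01      2014 2014-11-15 2015-01-12       57.4 FALSE
#> 3 P02      2013 2013-12-24 2014-02-08       46.3 FALSE
```

`out$fit` is the pooled acidity-drop fit: the asymptote estimate (g citric
acid/100 g juice), the fixed reference acidity, and the log rate constant,
with R² over the pooled centered points. Each window row gives the first
date the plot's fruit are both colored (20% orange) and below the acidity
ceiling, the model-predicted date acidity reaches the 0.65 floor, and the
resulting number of harvestable days.

The same chain is available as numbered drivers under `analysis/`
(`01_simulate.R` … `05_associations.R`), each writing its tables to
`results/`.

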