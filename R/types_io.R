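#' Orchard monitoring dataset: readers, writers and validation
#'
#' A dataset is a list of four tibbles mirroring the four CSV files of a
#' monitoring campaign:
#'
#' * `plots` — one row per (plot_id, year): `plot_id`, `year`, `management`
#'   (`"organic"` or `"conventional"`), `rootstock`, `full_bloom_date`,
#'   `first_harvest_date` (may be `NA`).
#' * `calibers` — per-tree fruit-size scores: `plot_id`, `year`, `date`,
#'   `tree` (0-based control-tree index), `caliber` (ordered class index,
#'   default 0..9), `freq` (nonnegative score; scores need not sum to 1 —
#'   aggregation normalizes by the plot total).
#' * `colors` — per-tree color-class scores: `plot_id`, `year`, `date`,
#'   `tree`, `color` (`green`/`yellow`/`orange`), `freq`.
#' * `samples` — per-caliber ten-fruit laboratory samples: `plot_id`, `year`,
#'   `date`, `caliber`, `n_fruit`, `mean_fruit_mass_g`, `juice_fraction`
#'   (proportion in \[0, 1\]), `titratable_acidity` (g citric acid / 100 g
#'   juice).
#'
#' `read_orchard_dataset()` reads and validates the four files;
#' `write_orchard_dataset()` writes them back in the same schema (the two are
#' exact inverses for valid datasets). `validate_orchard_dataset()` checks
#' every invariant and fails with the file, row and violated rule.
#'
#' @param dir directory containing `plots.csv`, `calibers.csv`, `colors.csv`,
#'   `samples.csv` (individual paths can be overridden).
#' @param plots,calibers,colors,samples file paths (for `read_…`) or tibbles
#'   (for `orchard_dataset()`).
#' @param n_calibers number of ordered caliber classes (indices
#'   `0 .. n_calibers - 1`).
#' @param n_trees number of control trees per plot (tree indices
#'   `0 .. n_trees - 1`).
#' @return a validated `orchard_dataset` (list of the four tibbles).
#' @export
read_orchard_dataset <- function(dir = NULL,
                                 plots = file.path(dir, "plots.csv"),
                                 calibers = file.path(dir, "calibers.csv"),
                                 colors = file.path(dir, "colors.csv"),
                                 samples = file.path(dir, "samples.csv"),
                                 n_calibers = 10, n_trees = 5) {
  read1 <- function(path, cols) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    readr::read_csv(path, col_types = cols, progress = FALSE)
  }
  ds <- orchard_dataset(
    plots = read1(plots, readr::cols(
      plot_id = "c", year = "i", management = "c", rootstock = "c",
      full_bloom_date = readr::col_date(), first_harvest_date = readr::col_date()
    )),
    calibers = read1(calibers, readr::cols(
      plot_id = "c", year = "i", date = readr::col_date(),
      tree = "i", caliber = "i", freq = "d"
    )),
    colors = read1(colors, readr::cols(
      plot_id = "c", year = "i", date = readr::col_date(),
      tree = "i", color = "c", freq = "d"
    )),
    samples = read1(samples, readr::cols(
      plot_id = "c", year = "i", date = readr::col_date(), caliber = "i",
      n_fruit = "i", mean_fruit_mass_g = "d", juice_fraction = "d",
      titratable_acidity = "d"
    )),
    n_calibers = n_calibers, n_trees = n_trees
  )
  ds
}

#' @rdname read_orchard_dataset
#' @export
orchard_dataset <- function(plots, calibers, colors, samples,
                            n_calibers = 10, n_trees = 5) {
  ds <- structure(
    list(
      plots = tibble::as_tibble(plots),
      calibers = tibble::as_tibble(calibers),
      colors = tibble::as_tibble(colors),
      samples = tibble::as_tibble(samples)
    ),
    n_calibers = n_calibers, n_trees = n_trees,
    class = "orchard_dataset"
  )
  validate_orchard_dataset(ds)
  ds
}

#' @rdname read_orchard_dataset
#' @param x an `orchard_dataset`.
#' @export
validate_orchard_dataset <- function(x) {
  stopifnot(inherits(x, "orchard_dataset"))
  n_calibers <- attr(x, "n_calibers")
  n_trees <- attr(x, "n_trees")

  fail <- function(table, rows, rule) {
    stop(sprintf(
      "invalid %s.csv, row(s) %s: %s", table,
      paste(head(rows, 5L), collapse = ", "), rule
    ), call. = FALSE)
  }
  check <- function(table, ok, rule) {
    ok[is.na(ok)] <- FALSE
    if (!all(ok)) fail(table, which(!ok), rule)
  }

  p <- x$plots
  if (anyDuplicated(p[c("plot_id", "year")])) {
    fail("plots", which(duplicated(p[c("plot_id", "year")])), "(plot_id, year) must be unique")
  }
  check("plots", p$management %in% c("organic", "conventional"),
        "management must be 'organic' or 'conventional'")
  check("plots", is.na(p$first_harvest_date) | p$first_harvest_date > p$full_bloom_date,
        "first_harvest_date must fall after full_bloom_date")

  key <- function(df) paste(df$plot_id, df$year)
  declared <- key(p)
  for (tab in c("calibers", "colors", "samples")) {
    check(tab, key(x[[tab]]) %in% declared,
          "observation references an undeclared (plot_id, year)")
  }

  cal <- x$calibers
  check("calibers", cal$freq >= 0, "freq must be nonnegative")
  check("calibers", cal$tree >= 0 & cal$tree < n_trees,
        sprintf("tree index must be in 0..%d", n_trees - 1))
  check("calibers", cal$caliber >= 0 & cal$caliber < n_calibers,
        sprintf("caliber must be in 0..%d", n_calibers - 1))

  col <- x$colors
  check("colors", col$freq >= 0, "freq must be nonnegative")
  check("colors", col$color %in% c("green", "yellow", "orange"),
        "color must be green|yellow|orange")
  check("colors", col$tree >= 0 & col$tree < n_trees,
        sprintf("tree index must be in 0..%d", n_trees - 1))
  if (nrow(col)) {
    n_classes <- dplyr::count(col, .data$plot_id, .data$year, .data$date, .data$tree)
    if (any(n_classes$n != 3L)) {
      fail("colors", which(n_classes$n != 3L),
           "each tree-date must carry all three color classes (zeros allowed)")
    }
  }

  s <- x$samples
  check("samples", s$mean_fruit_mass_g > 0, "mean_fruit_mass_g must be > 0")
  check("samples", s$juice_fraction >= 0 & s$juice_fraction <= 1,
        "juice_fraction must lie in [0, 1]")
  check("samples", s$titratable_acidity > 0, "titratable_acidity must be > 0")
  check("samples", s$caliber >= 0 & s$caliber < n_calibers,
        sprintf("caliber must be in 0..%d", n_calibers - 1))

  invisible(x)
}

#' @rdname read_orchard_dataset
#' @export
write_orchard_dataset <- function(x, dir) {
  stopifnot(inherits(x, "orchard_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("plots", "calibers", "colors", "samples")) {
    readr::write_csv(x[[tab]], file.path(dir, paste0(tab, ".csv")), na = "")
  }
  invisible(file.path(dir, paste0(c("plots", "calibers", "colors", "samples"), ".csv")))
}

#' @export
print.orchard_dataset <- function(x, ...) {
  cat("<orchard_dataset>\n")
  cat(sprintf("  plots:    %d plot-years (%s)\n", nrow(x$plots),
              paste(sort(unique(x$plots$year)), collapse = ", ")))
  cat(sprintf("  calibers: %d rows | colors: %d rows | samples: %d rows\n",
              nrow(x$calibers), nrow(x$colors), nrow(x$samples)))
  invisible(x)
}
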