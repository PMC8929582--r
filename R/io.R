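#' Aggregate a daily series into fixed-length periods
#'
#' Non-overlapping consecutive bins of `period_length` units (e.g. 30-day
#' periods).  A bin's value is the mean over its *fully logged* days; bins
#' with no fully logged day are absent, and a bin's `logged_fraction` is
#' the fraction of its days that were fully logged.  Aggregation tames the
#' instability of day-level ratios when daily counts are low, at the price
#' of a coarser cycle (365 daily units become 12 thirty-day periods).
#'
#' @param series A [daily_series()].
#' @param period_length Days per bin, >= 1.
#' @param cycle Cycle configuration of the aggregated series.  Defaults to
#'   `round(C / period_length)` periods per cycle with unit `"period"` and
#'   a bin-level full-log threshold of 0.5 (a bin counts as fully logged
#'   for pairing when at least half of its days were).
#' @return A [daily_series()] in period units (`day_index` = bin number).
#' @export
aggregate_periods <- function(series, period_length, cycle = NULL) {
  stopifnot(inherits(series, "daily_series"))
  period_length <- as.integer(period_length)
  if (is.na(period_length) || period_length < 1L) {
    stop("`period_length` must be an integer >= 1", call. = FALSE)
  }
  if (is.null(cycle)) {
    cycle <- cycle_config(C = max(2L, round(series$cycle$C / period_length)),
                          unit = "period", full_log_threshold = 0.5)
  }
  r <- series$records
  thr <- series$cycle$full_log_threshold
  full <- !is.na(r$logged_fraction) & r$logged_fraction >= thr &
    is.finite(r$value)
  r <- r[full, , drop = FALSE]
  if (!nrow(r)) {
    stop("no fully logged days to aggregate", call. = FALSE)
  }
  bin <- (r$day_index - 1L) %/% period_length + 1L
  value <- tapply(r$value, bin, mean)
  n_full <- tapply(r$value, bin, length)
  daily_series(day_index = as.integer(names(value)),
               value = as.numeric(value),
               logged_fraction = pmin(1, as.numeric(n_full) / period_length),
               site_id = series$site_id, cycle = cycle)
}

#' Write a trend series to CSV
#'
#' Columns `time`, `ratio`, `ci_low`, `ci_high`, `n_pairs` — every number
#' shown in the population trend plot, so the plot is a view and never the
#' only record.
#'
#' @param x A [pyra()] fit or a [pyra_series()] trend series.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trend_csv <- function(x, path) {
  tr <- if (inherits(x, "pyra")) {
    x$trend
  } else if (inherits(x, "trend_series")) {
    df <- as.data.frame(x)
    df$ci_low <- df$ci_high <- NA_real_
    df[c("time", "ratio", "ci_low", "ci_high", "n_pairs")]
  } else {
    stop("`x` must be a pyra fit or a trend_series", call. = FALSE)
  }
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' Write the summary trend as one-line JSON
#'
#' @param x A [pyra()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  stopifnot(inherits(x, "pyra"))
  s <- x$summary
  obj <- list(P_T = s$P_T, ci_low = s$ci[1L], ci_high = s$ci[2L],
              conf_level = x$config$conf_level,
              K = s$K, T_cycles = s$T_cycles,
              percent_change_over_span = s$percent_change_over_span,
              percent_change_per_year = s$percent_change_per_year,
              w = x$config$w, B = x$config$B)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a scenario triplet as CSV files
#'
#' Writes `complete.csv`, `incomplete.csv` (standard input dialect with
#' `day_index`) and `paired.csv` (audit dialect of [write_paired_csv()])
#' into a directory.
#'
#' @param triplet A [make_triplet()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_triplet_csv <- function(triplet, dir) {
  stopifnot(is.list(triplet),
            inherits(triplet$complete, "daily_series"),
            inherits(triplet$incomplete, "daily_series"),
            inherits(triplet$paired, "paired_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("complete", "incomplete")) {
    s <- triplet[[nm]]
    df <- data.frame(site_id = s$site_id,
                     day_index = s$records$day_index,
                     value = s$records$value,
                     logged_fraction = s$records$logged_fraction)
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  write_paired_csv(triplet$paired, file.path(dir, "paired.csv"))
  invisible(dir)
}
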