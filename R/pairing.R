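#' Extract paired observations from a daily series
#'
#' A day position takes part in a pair when it is fully logged in both
#' members of a pair of successive cycles: day `k` (the year-1 member) is
#' matched with day `k + C` (the year-2 member), `C` units later at the same
#' day-of-cycle.  Only consecutive cycles are ever paired, and a day may
#' belong to two pairs — as second member of one and first member of the
#' next.  These paired observations are the only data the trend estimator
#' uses; unpaired days carry no information about year-on-year change.
#'
#' @param series A [daily_series()].
#' @return An object of class `"paired_series"`: list with `cycle`, `K`
#'   (number of pairs) and `pairs`, a data frame sorted by
#'   (`pair_cycle`, `day_of_cycle`) with columns `site_id`, `pair_cycle`
#'   (cycle index of the first member), `day_of_cycle`, `k` (day_index of
#'   the year-1 member), `y1` and `y2`.  A span shorter than two cycles
#'   yields an empty `paired_series` with a warning, not an error.
#' @export
pair_extract <- function(series) {
  stopifnot(inherits(series, "daily_series"))
  r <- series$records
  C <- series$cycle$C
  thr <- series$cycle$full_log_threshold
  full <- !is.na(r$logged_fraction) & r$logged_fraction >= thr &
    is.finite(r$value)
  idx <- r$day_index[full]
  val <- r$value[full]
  names(val) <- idx
  k <- idx[(idx + C) %in% idx]
  pairs <- data.frame(
    site_id = rep(series$site_id, length(k)),
    pair_cycle = (k - 1L) %/% C + 1L,
    day_of_cycle = (k - 1L) %% C + 1L,
    k = k,
    y1 = unname(val[as.character(k)]),
    y2 = unname(val[as.character(k + C)])
  )
  pairs <- pairs[order(pairs$pair_cycle, pairs$day_of_cycle), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L &&
      (nrow(r) == 0L || max(r$day_index) - min(r$day_index) + 1L < 2L * C)) {
    warning("series spans less than two cycles; no pairs can be formed",
            call. = FALSE)
  }
  new_paired_series(pairs, series$cycle)
}

new_paired_series <- function(pairs, cycle) {
  structure(list(cycle = cycle, K = nrow(pairs), pairs = pairs),
            class = "paired_series")
}

#' @export
print.paired_series <- function(x, ...) {
  cat(sprintf("Paired series: K = %d pairs, %d site(s), %d distinct days\n",
              x$K, length(unique(x$pairs$site_id)),
              n_paired_days(x)))
  print(x$cycle)
  invisible(x)
}

n_paired_days <- function(paired) {
  p <- paired$pairs
  nrow(unique(data.frame(s = c(p$site_id, p$site_id),
                         d = c(p$k, p$k + paired$cycle$C))))
}

#' Count day positions fully logged in every cycle
#'
#' How many day-of-cycle positions are fully logged in all of the first
#' `n_cycles` cycles of the series.  With a window of logged days that
#' shifts between years, this shrinks with `n_cycles`: requiring a day in
#' all years is far more demanding than requiring it in two successive ones,
#' which is why pairing consecutive cycles retains so much more data.
#'
#' @param series A [daily_series()].
#' @param n_cycles Number of cycles that must each contain the position.
#' @return Integer count of qualifying day-of-cycle positions.
#' @export
days_logged_in_all_cycles <- function(series, n_cycles) {
  stopifnot(inherits(series, "daily_series"))
  r <- series$records
  C <- series$cycle$C
  avail <- if (nrow(r)) max(r$cycle_index) else 0L
  if (n_cycles > avail) {
    stop(sprintf("series has %d cycle(s), fewer than n_cycles = %d",
                 avail, n_cycles), call. = FALSE)
  }
  thr <- series$cycle$full_log_threshold
  full <- !is.na(r$logged_fraction) & r$logged_fraction >= thr &
    is.finite(r$value)
  r <- r[full & r$cycle_index <= n_cycles, , drop = FALSE]
  sum(tabulate(r$day_of_cycle, nbins = C) == n_cycles)
}

#' Pool paired series across sites (regional trend)
#'
#' Concatenates the pairs of several sites into one pooled series.  All
#' downstream ratios sum `y1` and `y2` over the pooled pairs, which is
#' numerically identical to summing per-site year totals first: the pooled
#' estimate is a detection-weighted regional trend.  Sites are aligned by
#' day-of-cycle position (each site's cycle is anchored at its own first
#' record), not by calendar date — the pooling convention this estimator
#' family assumes.
#'
#' @param ... `paired_series` objects, or a single list of them.
#' @return A pooled `paired_series`.
#' @export
combine_sites <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "paired_series")) xs <- xs[[1L]]
  if (!length(xs) || !all(vapply(xs, inherits, TRUE, "paired_series"))) {
    stop("inputs must be paired_series objects", call. = FALSE)
  }
  cyc <- xs[[1L]]$cycle
  for (x in xs[-1L]) {
    if (!same_cycle(cyc, x$cycle)) {
      stop("all sites must share the same cycle configuration", call. = FALSE)
    }
  }
  pairs <- do.call(rbind, lapply(xs, `[[`, "pairs"))
  key <- with(pairs, paste(site_id, pair_cycle, day_of_cycle))
  if (anyDuplicated(key)) {
    stop("duplicate (site, pair_cycle, day_of_cycle) among inputs",
         call. = FALSE)
  }
  pairs <- pairs[order(pairs$pair_cycle, pairs$day_of_cycle), , drop = FALSE]
  rownames(pairs) <- NULL
  new_paired_series(pairs, cyc)
}

#' Rebuild the day-level series underlying a paired set
#'
#' The distinct logged days taking part in at least one pair, as a daily
#' series in time order (a day serving as second member of one pair and
#' first member of the next appears once).  This is the "paired data set"
#' on which trend tests are run when comparing them with the paired-ratio
#' estimator on identical information.
#'
#' @param paired A [pair_extract()] result from a single site.
#' @return A [daily_series()] of the distinct paired days.
#' @export
paired_day_series <- function(paired) {
  stopifnot(inherits(paired, "paired_series"))
  p <- paired$pairs
  if (length(unique(p$site_id)) > 1L) {
    stop("paired_day_series needs a single-site paired series", call. = FALSE)
  }
  d <- data.frame(day_index = c(p$k, p$k + paired$cycle$C),
                  value = c(p$y1, p$y2))
  d <- unique(d)
  daily_series(day_index = d$day_index, value = d$value,
               logged_fraction = 1,
               site_id = if (nrow(p)) p$site_id[1L] else "site1",
               cycle = paired$cycle)
}

#' Write paired observations to CSV for audit
#'
#' @param paired A `paired_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(paired, path) {
  stopifnot(inherits(paired, "paired_series"))
  utils::write.csv(paired$pairs[c("site_id", "pair_cycle", "day_of_cycle",
                                  "y1", "y2")],
                   path, row.names = FALSE)
  invisible(path)
}
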