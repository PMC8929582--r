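#' Construct a daily detection series from day indices
#'
#' The basic container for one monitoring site: one record per fully or
#' partially logged time unit, indexed by `day_index` (sequential calendar
#' position, with 29 February already removed if the data were dated; see
#' [strip_leap_days()]).  Missing days are represented by absence of a
#' record, never by zeros: a recorded zero is a real observation of no
#' detections.
#'
#' Cycles are anchored at the first record (day_index 1 opens cycle 1), so a
#' deployment starting mid-calendar-year is compared with the same
#' deployment-relative day positions one cycle later.
#'
#' @param day_index Integer vector >= 1, strictly increasing after sorting;
#'   position of each record counted in calendar days from the series origin
#'   (leap days excluded).
#' @param value Non-negative detection metric per unit (clicks/day, DPM/day,
#'   DPM/period ...).  `NA`/negative values are admitted here and flagged by
#'   [validate_series()].
#' @param logged_fraction Fraction of the unit actually monitored, in
#'   \[0, 1\]. Recycled if length 1.
#' @param site_id Single string identifying the site.
#' @param date Optional `Date` vector parallel to `day_index`.
#' @param cycle A [cycle_config()].
#'
#' @return An object of class `"daily_series"`: a list with elements
#'   `site_id`, `cycle` and `records` (a data frame with columns
#'   `day_index`, `cycle_index`, `day_of_cycle`, `value`, `logged_fraction`
#'   and optionally `date`).
#' @seealso [as_daily_series()] for dated/CSV input, [pair_extract()].
#' @export
daily_series <- function(day_index, value, logged_fraction = 1,
                         site_id = "site1", date = NULL,
                         cycle = cycle_config()) {
  stopifnot(inherits(cycle, "cycle_config"))
  if (!is.character(site_id) || length(site_id) != 1L || is.na(site_id)) {
    stop("`site_id` must be a single string", call. = FALSE)
  }
  day_index <- as.integer(day_index)
  if (anyNA(day_index) || any(day_index < 1L)) {
    stop("`day_index` must be positive integers", call. = FALSE)
  }
  n <- length(day_index)
  value <- as.numeric(value)
  if (length(value) != n) stop("`value` must match `day_index` in length",
                               call. = FALSE)
  if (length(logged_fraction) == 1L) logged_fraction <- rep(logged_fraction, n)
  logged_fraction <- as.numeric(logged_fraction)
  if (length(logged_fraction) != n ||
      any(!is.na(logged_fraction) &
          (logged_fraction < 0 | logged_fraction > 1))) {
    stop("`logged_fraction` must lie in [0, 1]", call. = FALSE)
  }
  ord <- order(day_index)
  day_index <- day_index[ord]
  if (anyDuplicated(day_index)) {
    dup <- day_index[duplicated(day_index)][1L]
    stop(sprintf("duplicate record for site '%s' at day_index %d",
                 site_id, dup), call. = FALSE)
  }
  rec <- data.frame(
    day_index = day_index,
    cycle_index = (day_index - 1L) %/% cycle$C + 1L,
    day_of_cycle = (day_index - 1L) %% cycle$C + 1L,
    value = value[ord],
    logged_fraction = logged_fraction[ord]
  )
  if (!is.null(date)) {
    if (!inherits(date, "Date") || length(date) != n) {
      stop("`date` must be a Date vector parallel to `day_index`",
           call. = FALSE)
    }
    rec$date <- date[ord]
  }
  structure(list(site_id = site_id, cycle = cycle, records = rec),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  r <- x$records
  cat(sprintf("Daily detection series: site '%s', %d records spanning %s %d..%d (%0.2f cycles)\n",
              x$site_id, nrow(r), x$cycle$unit,
              min(r$day_index), max(r$day_index),
              max(r$day_index) / x$cycle$C))
  print(x$cycle)
  invisible(x)
}

# Dates of every 29 February falling in (from, to], vectorised over `to`.
n_feb29_between <- function(from, to) {
  yrs <- seq.int(as.integer(format(from, "%Y")),
                 max(as.integer(format(to, "%Y"))))
  leap <- yrs[(yrs %% 4 == 0 & yrs %% 100 != 0) | yrs %% 400 == 0]
  if (length(leap) == 0L) return(integer(length(to)))
  feb29 <- as.Date(sprintf("%d-02-29", leap))
  findInterval(to, feb29) - findInterval(from, feb29)
}

#' Remove leap days and assign calendar-aligned day indices
#'
#' Drops every 29 February record and numbers the remaining records with a
#' `day_index` that counts calendar days from the first retained date but
#' skips leap days.  Gaps in the record leave gaps in `day_index`, so the
#' same calendar month-day falls on the same day-of-cycle in every year and
#' cross-year pairing stays aligned.
#'
#' @param x A data frame with a `date` column (`Date` or ISO-8601 strings)
#'   and optionally a `site_id` column; any other columns are carried
#'   through.
#' @return `x` with 29 February rows removed, `date` parsed, rows sorted by
#'   date (within site), and an integer `day_index` column added (numbered
#'   per site from each site's first retained date).
#' @examples
#' d <- data.frame(date = as.Date("2015-12-30") + 0:64, value = 1)
#' s <- strip_leap_days(d)          # 2016-02-29 dropped, indices closed up
#' nrow(s)
#' @export
strip_leap_days <- function(x) {
  if (!is.data.frame(x) || is.null(x$date)) {
    stop("`x` must be a data frame with a `date` column", call. = FALSE)
  }
  raw <- x$date
  date <- if (inherits(raw, "Date")) raw else as.Date(as.character(raw),
                                                      format = "%Y-%m-%d")
  if (anyNA(date)) {
    bad <- as.character(raw[is.na(date)])[1L]
    stop(sprintf("unparseable date '%s' (expected ISO-8601, YYYY-MM-DD)",
                 bad), call. = FALSE)
  }
  x$date <- date
  site <- if (is.null(x$site_id)) rep("site1", nrow(x)) else as.character(x$site_id)
  key <- paste(site, format(date), sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("duplicate record for site '%s' on %s", d[1L], d[2L]),
         call. = FALSE)
  }
  keep <- !(format(date, "%m-%d") == "02-29")
  x <- x[keep, , drop = FALSE]
  site <- site[keep]
  out <- lapply(split(seq_len(nrow(x)), site), function(i) {
    xi <- x[i, , drop = FALSE]
    xi <- xi[order(xi$date), , drop = FALSE]
    origin <- xi$date[1L]
    xi$day_index <- as.integer(xi$date - origin) + 1L -
      n_feb29_between(origin, xi$date)
    xi
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Coerce dated records to one or more daily series
#'
#' Applies [strip_leap_days()] (when a `date` column is present; a
#' `day_index` column is honoured as-is otherwise, e.g. for monthly data
#' with `C = 12` where no leap handling applies) and builds a
#' [daily_series()] per site.
#'
#' @param x Data frame with columns `value`, either `date` or `day_index`,
#'   and optionally `site_id`, plus one of `logged_fraction` or
#'   `logged_minutes` (converted as `logged_minutes / 1440`; both absent
#'   means fully logged).
#' @param cycle A [cycle_config()].
#' @return A `daily_series` when `x` holds a single site, otherwise a named
#'   list of `daily_series`.
#' @export
as_daily_series <- function(x, cycle = cycle_config()) {
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  if (is.null(x$value)) stop("`x` must have a `value` column", call. = FALSE)
  if (is.null(x$logged_fraction)) {
    x$logged_fraction <- if (!is.null(x$logged_minutes)) {
      as.numeric(x$logged_minutes) / 1440
    } else 1
  }
  if (!is.null(x$date)) {
    x <- strip_leap_days(x)
  } else if (is.null(x$day_index)) {
    stop("`x` must have a `date` or a `day_index` column", call. = FALSE)
  }
  if (is.null(x$site_id)) x$site_id <- "site1"
  out <- lapply(split(x, as.character(x$site_id)), function(xi) {
    daily_series(day_index = xi$day_index, value = xi$value,
                 logged_fraction = xi$logged_fraction,
                 site_id = as.character(xi$site_id[1L]),
                 date = if (!is.null(xi$date)) xi$date,
                 cycle = cycle)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Read a detection CSV
#'
#' One dialect: a header row and columns `site_id`, `date` (ISO-8601) or
#' `day_index`, `value`, and optionally `logged_fraction` or
#' `logged_minutes`.  UTF-8.
#'
#' @param path Path to the CSV file.
#' @param cycle A [cycle_config()] applied to every site in the file.
#' @return As [as_daily_series()]: one `daily_series` or a named list.
#' @export
read_detections <- function(path, cycle = cycle_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    stop(sprintf("no records in '%s'", path), call. = FALSE)
  }
  as_daily_series(df, cycle = cycle)
}

#' Validation report for a daily series
#'
#' A pure report (never an error): counts of fully logged units, gap run
#' lengths between successive records, and negative or non-finite values.
#' The caller decides what is fatal.
#'
#' @param series A [daily_series()].
#' @return An object of class `"series_validation"`: list with `n_records`,
#'   `n_fully_logged`, `n_partial`, `gap_runs` (integer vector of missing-run
#'   lengths between first and last record), `n_negative`, `n_nonfinite`,
#'   `span` (days from first to last record inclusive) and `threshold`.
#' @export
validate_series <- function(series) {
  stopifnot(inherits(series, "daily_series"))
  r <- series$records
  thr <- series$cycle$full_log_threshold
  full <- !is.na(r$logged_fraction) & r$logged_fraction >= thr
  gaps <- diff(r$day_index) - 1L
  gaps <- gaps[gaps > 0L]
  structure(list(
    site_id = series$site_id,
    n_records = nrow(r),
    n_fully_logged = sum(full),
    n_partial = sum(!full),
    gap_runs = as.integer(gaps),
    n_negative = sum(!is.na(r$value) & r$value < 0),
    n_nonfinite = sum(!is.finite(r$value)),
    span = if (nrow(r)) max(r$day_index) - min(r$day_index) + 1L else 0L,
    threshold = thr
  ), class = "series_validation")
}

#' @export
print.series_validation <- function(x, ...) {
  cat(sprintf("Series '%s': %d records over a span of %d units\n",
              x$site_id, x$n_records, x$span))
  cat(sprintf("  fully logged: %d (threshold %g); partial: %d\n",
              x$n_fully_logged, x$threshold, x$n_partial))
  cat(sprintf("  gaps: %d run(s)%s\n", length(x$gap_runs),
              if (length(x$gap_runs))
                sprintf(", longest %d units", max(x$gap_runs)) else ""))
  if (x$n_negative || x$n_nonfinite) {
    cat(sprintf("  ERRORS: %d negative, %d non-finite values\n",
                x$n_negative, x$n_nonfinite))
  }
  invisible(x)
}
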