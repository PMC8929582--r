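#' Cycle configuration
#'
#' Describes the periodic cycle over which day positions are matched across
#' years: the cycle length `C` (365 for daily data, 12 for monthly data), the
#' unit label, and the minimum logged fraction for a unit of time to count as
#' "fully logged".  Only fully logged units take part in pairing, so that a
#' partially monitored day is never compared with a whole one.
#'
#' @param C Positive integer, cycle length in time units.  Must be >= 2.
#' @param unit Single string labelling the time unit ("day", "month",
#'   "period", ...).  Informational only.
#' @param full_log_threshold Minimum `logged_fraction` for a unit to count as
#'   fully logged, in (0, 1].  Defaults to 1 (only whole days of logging are
#'   used); lower it for sensor clocks that record e.g. 1439/1440 minutes.
#'
#' @return An object of class `"cycle_config"`.
#' @examples
#' cycle_config()                      # daily data, annual cycle
#' cycle_config(C = 12, unit = "month")
#' @export
cycle_config <- function(C = 365L, unit = "day", full_log_threshold = 1) {
  if (length(C) != 1L || is.na(C) || C != as.integer(C) || C < 2) {
    stop("`C` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.character(unit) || length(unit) != 1L || is.na(unit)) {
    stop("`unit` must be a single string", call. = FALSE)
  }
  if (!is.numeric(full_log_threshold) || length(full_log_threshold) != 1L ||
      is.na(full_log_threshold) ||
      full_log_threshold <= 0 || full_log_threshold > 1) {
    stop("`full_log_threshold` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(C = as.integer(C), unit = unit,
         full_log_threshold = as.numeric(full_log_threshold)),
    class = "cycle_config"
  )
}

#' @export
print.cycle_config <- function(x, ...) {
  cat(sprintf("Cycle: C = %d %ss, fully logged when logged_fraction >= %g\n",
              x$C, x$unit, x$full_log_threshold))
  invisible(x)
}

same_cycle <- function(a, b) {
  a$C == b$C && identical(a$unit, b$unit) &&
    isTRUE(all.equal(a$full_log_threshold, b$full_log_threshold))
}
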