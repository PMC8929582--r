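#' Configuration of the synthetic detection scenarios
#'
#' Two extreme-case daily click scenarios for evaluating trend estimators on
#' seasonally patterned, gappy data:
#'
#' * **S1** (seasonal, no trend): the daily mean drops linearly within each
#'   cycle from `start_mean` to `end_mean_within_cycle`, resetting every
#'   cycle — a pure seasonal sawtooth with no cross-year change.
#' * **S2** (uniform decline): the daily mean declines linearly across the
#'   whole span, from `start_mean` on day 1 to
#'   `start_mean * (1 - total_decline_fraction)` on the last day, with no
#'   seasonal component.
#'
#' Daily fluctuations are Normal with standard deviation `noise_sd`
#' (negative draws truncated at 0: detection counts are non-negative).  The
#' gap design retains a `window_length`-day observation window per cycle
#' that shifts forward `window_shift` days each cycle, so the temporal
#' overlap between successive years is `window_length - window_shift` day
#' positions.
#'
#' The named noise levels are fractions of `start_mean` (1\%, 2\% and 4\%
#' for `"low"`, `"moderate"` and `"high"`): at these levels an imposed
#' decline of the default size clearly dominates the day-to-day noise,
#' which is the situation the scenarios are meant to portray; at `"high"`
#' that separation begins to break down.
#'
#' @param scenario `"S1"` / `"S1_seasonal_no_trend"` or `"S2"` /
#'   `"S2_uniform_decline"` (also accepts `1`/`2`).
#' @param n_cycles Number of cycles (default 4).
#' @param C Cycle length in days (default 365).
#' @param start_mean Mean daily detections at the start (default 100).
#' @param end_mean_within_cycle S1 within-cycle end mean (default 50).
#' @param total_decline_fraction S2 total decline over the whole span, in
#'   \[0, 1) (default 0.75).
#' @param noise_sd Daily Normal standard deviation, or one of `"low"`,
#'   `"moderate"`, `"high"` (1, 2 and 4 for `start_mean = 100`, scaled
#'   proportionally with `start_mean`).
#' @param truncate_at_zero Truncate negative draws at zero (default TRUE).
#' @param window_length Observation window length per cycle (default 100).
#' @param window_shift Forward shift of the window per cycle (default 30).
#' @param seed Optional integer seed used by the generator.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("S1", "S2"),
                            n_cycles = 4L, C = 365L,
                            start_mean = 100,
                            end_mean_within_cycle = start_mean / 2,
                            total_decline_fraction = 0.75,
                            noise_sd = "moderate",
                            truncate_at_zero = TRUE,
                            window_length = 100L, window_shift = 30L,
                            seed = NULL) {
  scenario <- as.character(scenario)[1L]
  scenario <- switch(scenario,
                     "1" = , "S1" = , "S1_seasonal_no_trend" = "S1",
                     "2" = , "S2" = , "S2_uniform_decline" = "S2",
                     stop("`scenario` must identify S1 or S2", call. = FALSE))
  if (is.character(noise_sd)) {
    lev <- match.arg(noise_sd, c("low", "moderate", "high"))
    noise_sd <- start_mean * c(low = 0.01, moderate = 0.02, high = 0.04)[[lev]]
  }
  cfg <- list(scenario = scenario, n_cycles = as.integer(n_cycles),
              C = as.integer(C), start_mean = as.numeric(start_mean),
              end_mean_within_cycle = as.numeric(end_mean_within_cycle),
              total_decline_fraction = as.numeric(total_decline_fraction),
              noise_sd = as.numeric(noise_sd),
              truncate_at_zero = isTRUE(truncate_at_zero),
              window_length = as.integer(window_length),
              window_shift = as.integer(window_shift),
              seed = if (!is.null(seed)) as.integer(seed))
  checks <- c(
    n_cycles = cfg$n_cycles >= 2L,
    C = cfg$C >= 2L,
    start_mean = is.finite(cfg$start_mean) && cfg$start_mean > 0,
    end_mean_within_cycle = is.finite(cfg$end_mean_within_cycle) &&
      cfg$end_mean_within_cycle >= 0,
    total_decline_fraction = is.finite(cfg$total_decline_fraction) &&
      cfg$total_decline_fraction >= 0 && cfg$total_decline_fraction < 1,
    noise_sd = is.finite(cfg$noise_sd) && cfg$noise_sd >= 0,
    window_length = cfg$window_length >= 1L,
    window_shift = cfg$window_shift >= 0L
  )
  if (any(!checks)) {
    stop(sprintf("invalid scenario field(s): %s",
                 paste(names(checks)[!checks], collapse = ", ")),
         call. = FALSE)
  }
  if (cfg$window_length + (cfg$n_cycles - 1L) * cfg$window_shift > cfg$C) {
    stop("window design exceeds the cycle: need window_length + (n_cycles - 1) * window_shift <= C",
         call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %s: %d cycles of %d days, start mean %g, noise sd %g\n",
              x$scenario, x$n_cycles, x$C, x$start_mean, x$noise_sd))
  if (x$scenario == "S1") {
    cat(sprintf("  seasonal ramp to %g each cycle, no cross-year trend\n",
                x$end_mean_within_cycle))
  } else {
    cat(sprintf("  uniform decline of %g%% over the span\n",
                100 * x$total_decline_fraction))
  }
  cat(sprintf("  gap design: %d-day window shifting +%d days per cycle\n",
              x$window_length, x$window_shift))
  invisible(x)
}

#' Deterministic mean function of a scenario
#'
#' The noise-free expected value at each day, used both by the generator
#' and as a closed-form reference for the estimator on noiseless data.
#'
#' @param config A [scenario_config()].
#' @param day_index Integer day positions in `1..n_cycles * C`.
#' @return Numeric vector of means.
#' @export
scenario_mean <- function(config, day_index) {
  stopifnot(inherits(config, "scenario_config"))
  day_index <- as.numeric(day_index)
  if (config$scenario == "S1") {
    d <- (day_index - 1) %% config$C          # 0-based day of cycle
    config$start_mean +
      (config$end_mean_within_cycle - config$start_mean) * d / (config$C - 1)
  } else {
    n_days <- config$n_cycles * config$C
    config$start_mean *
      (1 - config$total_decline_fraction * (day_index - 1) / (n_days - 1))
  }
}

#' Generate a complete (fully logged) scenario series
#'
#' Every day of every cycle is fully logged; values are Normal draws around
#' [scenario_mean()], truncated at zero when `truncate_at_zero` is set.
#' Seeded through `config$seed` (or the `seed` argument) for
#' reproducibility.
#'
#' @param config A [scenario_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A [daily_series()] of `n_cycles * C` fully logged days.
#' @export
gen_complete <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n_days <- config$n_cycles * config$C
  mu <- scenario_mean(config, seq_len(n_days))
  value <- mu + if (config$noise_sd > 0) {
    stats::rnorm(n_days, 0, config$noise_sd)
  } else 0
  if (config$truncate_at_zero) value <- pmax(value, 0)
  daily_series(day_index = seq_len(n_days), value = value,
               logged_fraction = 1,
               site_id = sprintf("synthetic_%s", config$scenario),
               cycle = cycle_config(C = config$C))
}

#' Apply the shifting-window gap design
#'
#' Cycle `j` retains only day-of-cycle positions
#' `[1 + (j - 1) * shift, (j - 1) * shift + window_length]`; all other days
#' are removed (absent, not zeroed).  This emulates a deployment window
#' that drifts later into the season every year — a gap pattern that, by
#' design, correlates with the seasonal cycle and so can fabricate a
#' spurious trend in naive analyses.
#'
#' @param complete A [daily_series()] spanning `n_cycles * C` days.
#' @param config The [scenario_config()] holding the window design.
#' @return The windowed (incomplete) `daily_series`.
#' @export
apply_window_design <- function(complete, config) {
  stopifnot(inherits(complete, "daily_series"),
            inherits(config, "scenario_config"))
  r <- complete$records
  j <- r$cycle_index
  lo <- 1L + (j - 1L) * config$window_shift
  hi <- (j - 1L) * config$window_shift + config$window_length
  if (any(hi > config$C)) {
    stop("window design exceeds cycle bounds", call. = FALSE)
  }
  keep <- r$day_of_cycle >= lo & r$day_of_cycle <= hi
  daily_series(day_index = r$day_index[keep], value = r$value[keep],
               logged_fraction = r$logged_fraction[keep],
               site_id = complete$site_id, cycle = complete$cycle)
}

#' Generate the complete / incomplete / paired triplet of a scenario
#'
#' One seeded draw of the scenario, returned in the three forms the
#' evaluation uses: the fully logged series, the shifting-window subset,
#' and the paired observations extracted from that subset.
#'
#' @inheritParams gen_complete
#' @return List with elements `complete` and `incomplete`
#'   ([daily_series()]) and `paired` ([pair_extract()] of the incomplete
#'   series).
#' @export
make_triplet <- function(config, seed = config$seed) {
  complete <- gen_complete(config, seed = seed)
  incomplete <- apply_window_design(complete, config)
  list(complete = complete, incomplete = incomplete,
       paired = pair_extract(incomplete))
}
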