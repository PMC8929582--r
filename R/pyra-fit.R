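#' Fit a paired year ratio trend model
#'
#' The main entry point: pairs the data, computes the summary trend ratio
#' and the windowed trend series, and attaches moving-block bootstrap
#' percentile confidence intervals to both.
#'
#' The estimator compares detections on day positions fully logged in both
#' members of a pair of successive cycles.  Its summary statistic is the
#' ratio of all second-year to all first-year paired detections: 1 means no
#' trend, 0.9 a 10\% decline over the monitored span.  Because numerator
#' and denominator always cover the identical day positions, diel and
#' seasonal patterns cancel and gaps merely reduce the amount of paired
#' data rather than biasing the ratio.
#'
#' @param x A [daily_series()], a list of them (multiple sites, pooled with
#'   [combine_sites()]), or a ready-made `paired_series`.
#' @param I Trend-series window span in time units; defaults to the cycle
#'   length `C` (the natural choice, averaging over one full seasonal
#'   cycle).
#' @param w Bootstrap block span in pairs (default 21 for daily data; use
#'   about 3 for monthly data).
#' @param B Bootstrap resamples (default 1000).
#' @param conf_level Confidence level for all intervals (default 0.95).
#' @param min_pairs Windows with fewer pairs are reported missing
#'   (default 30).
#' @param zero_denominator,epsilon Zero-denominator policy, see
#'   [pyra_point()].
#' @param series_ci Also compute per-window percentile bands for the trend
#'   series (default TRUE; the costly part of the fit).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `"pyra"`: list with `paired`, `summary` (a
#'   [pyra_summary()] augmented with `ci`), `trend` (a data frame `time`,
#'   `ratio`, `ci_low`, `ci_high`, `n_pairs`), `boot` (the summary
#'   [pyra_boot()]), and `config`.  Methods: `print`, `summary`, `coef`
#'   (the summary ratio), `confint`, `plot`.
#' @examples
#' trip <- make_triplet(scenario_config("S1", seed = 42))
#' fit <- pyra(trip$paired, B = 200, series_ci = FALSE, seed = 1)
#' print(fit)
#' coef(fit)
#' confint(fit)
#' @export
pyra <- function(x, I = NULL, w = 21L, B = 1000L, conf_level = 0.95,
                 min_pairs = 30L,
                 zero_denominator = c("missing", "epsilon"), epsilon = 1,
                 series_ci = TRUE, seed = NULL) {
  zero_denominator <- match.arg(zero_denominator)
  paired <- if (inherits(x, "paired_series")) {
    x
  } else if (inherits(x, "daily_series")) {
    pair_extract(x)
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "daily_series"))) {
    combine_sites(lapply(x, pair_extract))
  } else {
    stop("`x` must be a daily_series, a list of daily_series, or a paired_series",
         call. = FALSE)
  }
  if (paired$K == 0L) stop("no paired observations: cannot fit", call. = FALSE)
  if (is.null(I)) I <- paired$cycle$C
  if (!is.null(seed)) set.seed(seed)
  smry <- pyra_summary(paired)
  boot <- pyra_boot(paired, w = w, B = B, conf_level = conf_level,
                    zero_denominator = zero_denominator, epsilon = epsilon)
  smry$ci <- boot$ci
  trend <- pyra_series(paired, I = I, min_pairs = min_pairs,
                       zero_denominator = zero_denominator,
                       epsilon = epsilon)
  if (series_ci) {
    bands <- series_boot_bands(paired, I = as.integer(I), w = as.integer(w),
                               B = as.integer(B), conf_level = conf_level,
                               min_pairs = min_pairs)
    trend$ci_low <- bands$ci_low[match(trend$time, bands$time)]
    trend$ci_high <- bands$ci_high[match(trend$time, bands$time)]
  } else {
    trend$ci_low <- NA_real_
    trend$ci_high <- NA_real_
  }
  trend <- trend[c("time", "ratio", "ci_low", "ci_high", "n_pairs")]
  structure(list(
    paired = paired,
    summary = smry,
    trend = trend,
    boot = boot,
    config = list(I = as.integer(I), w = as.integer(w), B = as.integer(B),
                  conf_level = conf_level, min_pairs = as.integer(min_pairs),
                  zero_denominator = zero_denominator, epsilon = epsilon),
    call = match.call()
  ), class = "pyra")
}

#' @export
print.pyra <- function(x, ...) {
  s <- x$summary
  cat("Paired year ratio trend fit\n")
  cat(sprintf("  pairs: K = %d over %.2f cycles (%d site(s))\n",
              s$K, s$T_cycles, length(unique(x$paired$pairs$site_id))))
  cat(sprintf("  summary ratio P_T = %.4f, %g%% CI [%.4f, %.4f]\n",
              s$P_T, 100 * x$config$conf_level, s$ci[1L], s$ci[2L]))
  cat(sprintf("  change over span: %+.1f%% (per year: %+.1f%%)\n",
              -s$percent_change_over_span, -s$percent_change_per_year))
  invisible(x)
}

#' @export
summary.pyra <- function(object, ...) {
  print(object)
  ok <- !is.na(object$trend$ratio)
  if (any(ok)) {
    cat(sprintf("  trend series: %d windows, ratio range [%.3f, %.3f]\n",
                sum(ok), min(object$trend$ratio[ok]),
                max(object$trend$ratio[ok])))
  }
  if (object$boot$n_dropped) {
    cat(sprintf("  bootstrap: %d resample(s) with undefined statistic dropped\n",
                object$boot$n_dropped))
  }
  invisible(object)
}

#' @export
coef.pyra <- function(object, ...) {
  c(P_T = object$summary$P_T)
}

#' @export
confint.pyra <- function(object, parm = "P_T", level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$config$conf_level))) {
    stop("intervals were computed at conf_level = ",
         object$config$conf_level,
         "; refit with a different `conf_level` to change it", call. = FALSE)
  }
  lv <- object$config$conf_level
  m <- matrix(object$summary$ci, nrow = 1L,
              dimnames = list("P_T", sprintf("%g %%",
                                             100 * c((1 - lv) / 2,
                                                     1 - (1 - lv) / 2))))
  m
}

#' Population trend plot
#'
#' The windowed year-on-year ratio against time (in cycles), with its
#' percentile band where available, the summary ratio and its interval as
#' horizontal dashed lines, and the no-trend baseline at 1.
#'
#' @param x A [pyra()] fit.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pyra <- function(x, ...) {
  tr <- x$trend[!is.na(x$trend$ratio), , drop = FALSE]
  if (!nrow(tr)) stop("nothing to plot: trend series is all missing",
                      call. = FALSE)
  C <- x$paired$cycle$C
  tt <- tr$time / C
  ylim <- range(1, tr$ratio, tr$ci_low, tr$ci_high, x$summary$ci,
                na.rm = TRUE)
  graphics::plot(tt, tr$ratio, type = "n", ylim = ylim,
                 xlab = sprintf("time (cycles of %d %ss)", C,
                                x$paired$cycle$unit),
                 ylab = "year-on-year ratio", ...)
  band <- !is.na(tr$ci_low) & !is.na(tr$ci_high)
  if (any(band)) {
    bb <- tr[band, , drop = FALSE]
    graphics::polygon(c(bb$time / C, rev(bb$time / C)),
                      c(bb$ci_low, rev(bb$ci_high)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
  }
  graphics::abline(h = 1, col = "darkgreen")
  graphics::abline(h = x$summary$P_T, lty = 2)
  graphics::abline(h = x$summary$ci, lty = 2, col = "steelblue")
  graphics::lines(tt, tr$ratio, lwd = 1.5)
  invisible(x)
}
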