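#' Point ratio of a paired observation
#'
#' The unsmoothed year-on-year ratio `y2 / y1` for a single pair.  A ratio
#' with a zero denominator is an increasingly unstable estimate as counts
#' approach zero; by default it is returned as missing, or under the
#' `"epsilon"` policy as `(y2 + epsilon) / (y1 + epsilon)` (the same device
#' as the log(1 + x) transform for zero counts).
#'
#' @param y1,y2 Non-negative detection totals for the first- and
#'   second-year members of the pair(s); vectorised.
#' @param zero_denominator `"missing"` (default) or `"epsilon"`.
#' @param epsilon Small positive constant for the `"epsilon"` policy.
#' @return Numeric vector of ratios, `NA` where undefined.
#' @export
pyra_point <- function(y1, y2, zero_denominator = c("missing", "epsilon"),
                       epsilon = 1) {
  zero_denominator <- match.arg(zero_denominator)
  if (zero_denominator == "epsilon") {
    if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
      stop("`epsilon` must be a positive number", call. = FALSE)
    }
    (y2 + epsilon) / (y1 + epsilon)
  } else {
    out <- y2 / y1
    out[!is.na(y1) & y1 == 0] <- NA_real_
    out
  }
}

#' Forward moving average over sparse positions
#'
#' Smooths a sequence observed at (possibly gappy) integer positions with a
#' forward window: the output at position `k` is the mean of the values
#' available at positions in `[k, k + I)`.  Windows holding fewer than
#' `min_pairs` values are reported missing rather than risk an unstable
#' mean.
#'
#' @param values Numeric vector.
#' @param positions Strictly increasing integer positions of `values`.
#' @param I Window span, integer >= 1.
#' @param min_pairs Minimum number of values per window.
#' @return Data frame with `position` (every start from `min(positions)` to
#'   `max(positions)`), `mean` (`NA` where the window is too thin) and `n`.
#' @export
forward_moving_mean <- function(values, positions = seq_along(values), I,
                                min_pairs = 1L) {
  if (length(I) != 1L || is.na(I) || I < 1) {
    stop("`I` must be an integer >= 1 (the point ratio handles I = 0)",
         call. = FALSE)
  }
  positions <- as.integer(positions)
  if (length(positions) != length(values) || is.unsorted(positions,
                                                         strictly = TRUE)) {
    stop("`positions` must be strictly increasing and parallel to `values`",
         call. = FALSE)
  }
  w <- window_sums(values, positions, as.integer(I))
  mean <- w$sum / w$n
  mean[w$n < min_pairs] <- NA_real_
  data.frame(position = w$position, mean = mean, n = w$n)
}

# Rolling sums of `values` over forward windows [s, s + I) for every integer
# start s in [min(positions), max(positions)], tolerant of gaps and of
# repeated positions (multi-site pooling).  NA values count 0 with n
# unaffected unless `na_zero` is FALSE, in which case they are excluded.
window_sums <- function(values, positions, I) {
  lo <- min(positions)
  hi <- max(positions)
  len <- hi - lo + 1L
  ok <- !is.na(values)
  tot <- numeric(len)
  cnt <- integer(len)
  at <- positions - lo + 1L
  for (i in which(ok)) {            # duplicates at a position accumulate
    tot[at[i]] <- tot[at[i]] + values[i]
    cnt[at[i]] <- cnt[at[i]] + 1L
  }
  ctot <- cumsum(tot)
  ccnt <- cumsum(cnt)
  starts <- seq_len(len)
  ends <- pmin(starts + I - 1L, len)
  data.frame(
    position = lo:hi,
    sum = ctot[ends] - c(0, ctot)[starts],
    n = ccnt[ends] - c(0L, ccnt)[starts]
  )
}

#' Windowed year-on-year trend series
#'
#' Slides a forward window of span `I` (by default one full cycle, `C`) one
#' unit at a time over the paired observations and reports, for each window
#' start `k`, the ratio of the year-2 sum to the year-1 sum over the pairs
#' whose first member falls in `[k, k + I)`.  Numerator and denominator
#' windows contain the identical pair set by construction, so the ratio of
#' forward moving means reduces to a ratio of sums and no divide-by-count
#' asymmetry can arise from missing days.  Each ratio is plotted at the
#' window midpoint `k + floor(C/2)`, which centres the two-year comparison
#' on the point in time it describes.
#'
#' @param paired A [pair_extract()] or [combine_sites()] result.
#' @param I Window span in time units; defaults to the cycle length `C`.
#' @param min_pairs Windows with fewer pairs than this are reported missing
#'   (default 30, about 8 percent of an annual window).
#' @param zero_denominator,epsilon As [pyra_point()]: policy for windows
#'   whose year-1 sum is zero.
#' @return Object of class `"trend_series"`: data frame with columns `time`
#'   (midpoint-shifted position), `ratio`, `n_pairs`, and attribute `I`.
#' @export
pyra_series <- function(paired, I = NULL, min_pairs = 30L,
                        zero_denominator = c("missing", "epsilon"),
                        epsilon = 1) {
  stopifnot(inherits(paired, "paired_series"))
  zero_denominator <- match.arg(zero_denominator)
  if (paired$K == 0L) stop("no pairs: cannot compute a trend series",
                           call. = FALSE)
  C <- paired$cycle$C
  if (is.null(I)) I <- C
  p <- paired$pairs
  s1 <- window_sums(p$y1, p$k, as.integer(I))
  s2 <- window_sums(p$y2, p$k, as.integer(I))
  if (zero_denominator == "epsilon") {
    ratio <- (s2$sum + epsilon) / (s1$sum + epsilon)
  } else {
    ratio <- ifelse(s1$sum > 0, s2$sum / s1$sum, NA_real_)
  }
  ratio[s1$n < min_pairs] <- NA_real_
  out <- data.frame(time = s1$position + C %/% 2L,
                    ratio = ratio,
                    n_pairs = s1$n)
  attr(out, "I") <- as.integer(I)
  attr(out, "cycle") <- paired$cycle
  class(out) <- c("trend_series", "data.frame")
  out
}

#' Summary trend statistic over the whole span
#'
#' The ratio of all year-2 paired detections to all year-1 paired
#' detections, over every pair in the series (all cycle pairs, all pooled
#' sites).  A value of 1 is the no-trend baseline; `100 * (1 - P_T)` reads
#' as the percent change over the monitored span, and dividing further by
#' the span in cycles gives an average year-on-year percent change.
#'
#' @param paired A `paired_series`.
#' @return List of class `"pyra_summary"`: `P_T`, `K`, `T_cycles` (span of
#'   the underlying days in cycles), `percent_change_over_span` and
#'   `percent_change_per_year`.
#' @export
pyra_summary <- function(paired) {
  stopifnot(inherits(paired, "paired_series"))
  p <- paired$pairs
  s1 <- sum(p$y1)
  if (paired$K == 0L || !is.finite(s1) || s1 <= 0) {
    stop("summary undefined: no year-1 detections", call. = FALSE)
  }
  C <- paired$cycle$C
  P_T <- sum(p$y2) / s1
  T_cycles <- (max(p$k) + C - min(p$k) + 1) / C
  structure(list(
    P_T = P_T,
    K = paired$K,
    T_cycles = T_cycles,
    percent_change_over_span = 100 * (1 - P_T),
    percent_change_per_year = 100 * (1 - P_T) / T_cycles
  ), class = "pyra_summary")
}

#' @export
print.pyra_summary <- function(x, ...) {
  cat(sprintf("Summary trend ratio P_T = %.4f over %d pairs (span %.2f cycles)\n",
              x$P_T, x$K, x$T_cycles))
  cat(sprintf("  change over span: %+.1f%%  (average per year: %+.1f%%)\n",
              -x$percent_change_over_span, -x$percent_change_per_year))
  invisible(x)
}

#' Mean of windowed ratios at a given span
#'
#' The average over window starts `kk = 1..K - I + 1` of the ratio of the
#' forward moving means of `y2` and `y1` over pairs `kk..kk + I - 1` (in
#' pair order).  With `I = K` this reduces to the summary statistic of
#' [pyra_summary()]; with small `I` it approaches the mean of point ratios.
#'
#' @param paired A `paired_series`.
#' @param I Window span in pairs, `1 <= I <= K`.
#' @return The mean windowed ratio (windows with a zero year-1 sum are
#'   excluded from the mean).
#' @export
pyra_summary_windowed <- function(paired, I) {
  stopifnot(inherits(paired, "paired_series"))
  K <- paired$K
  if (length(I) != 1L || is.na(I) || I < 1 || I > K) {
    stop(sprintf("`I` must lie in [1, K = %d]", K), call. = FALSE)
  }
  I <- as.integer(I)
  p <- paired$pairs
  c1 <- cumsum(p$y1)
  c2 <- cumsum(p$y2)
  kk <- seq_len(K - I + 1L)
  s1 <- c1[kk + I - 1L] - c(0, c1)[kk]
  s2 <- c2[kk + I - 1L] - c(0, c2)[kk]
  mean((s2 / s1)[s1 > 0])
}
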