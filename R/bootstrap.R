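#' Moving-block resample of a paired series
#'
#' Draws `ceiling(K / w)` blocks of `w` consecutive pairs, uniformly with
#' replacement from the `K - w + 1` overlapping blocks, concatenates them in
#' draw order and truncates to the original length `K`.  Each `(y1, y2)`
#' pair travels intact inside its block — resampling the two years
#' independently would destroy exactly the pairing the estimator relies on —
#' and blocks of consecutive pairs preserve short-range serial dependence.
#'
#' @param paired A `paired_series` with `K >= w`.
#' @param w Block span in pairs, `2 <= w <= K`.
#' @return A resampled `paired_series` of length `K` (pairs in draw order).
#' @export
block_resample <- function(paired, w) {
  stopifnot(inherits(paired, "paired_series"))
  K <- paired$K
  w <- as.integer(w)
  if (is.na(w) || w < 2L || w > K) {
    stop(sprintf("`w` must lie in [2, K = %d]", K), call. = FALSE)
  }
  nb <- ceiling(K / w)
  starts <- sample.int(K - w + 1L, nb, replace = TRUE)
  idx <- as.vector(outer(0:(w - 1L), starts, `+`))[seq_len(K)]
  pairs <- paired$pairs[idx, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(cycle = paired$cycle, K = K, pairs = pairs),
            class = "paired_series")
}

# Sums of y over each truncated-block resample, vectorised over B resamples.
# cy = cumsum of the vector being resampled; returns a B-vector of sums.
resample_sums <- function(cy, starts_mat, w, K) {
  nb <- nrow(starts_mat)
  last_len <- K - w * (nb - 1L)
  pre <- c(0, cy)
  full <- 0
  if (nb > 1L) {
    s <- starts_mat[-nb, , drop = FALSE]
    full <- colSums(matrix(cy[s + w - 1L] - pre[s], nrow = nb - 1L))
  }
  s <- starts_mat[nb, ]
  full + cy[s + last_len - 1L] - pre[s]
}

#' Moving-block bootstrap confidence intervals for the trend
#'
#' Percentile confidence intervals for the summary trend ratio (and,
#' through [pyra()], per-window intervals for the trend series) obtained by
#' recomputing the statistic on [block_resample()]s of the paired data.
#'
#' @param paired A `paired_series`.
#' @param w Block span in pairs.  21 is a reasonable daily-data default (a
#'   three-week block comfortably exceeds the day-to-day correlation scale
#'   of most detection series); use about 3 for monthly data.  Choose `w`
#'   large enough that the first and last observations of a block are
#'   nearly uncorrelated — this is the user's scientific judgement, not
#'   something the code can check.
#' @param B Number of resamples (default 1000).
#' @param conf_level Confidence level (default 0.95).
#' @param zero_denominator,epsilon Policy for resamples with a zero year-1
#'   sum: under `"missing"` such resamples are dropped and counted.
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `"pyra_boot"`: `t0` (observed statistic), `ci`
#'   (length-2 vector), `t` (the resample statistics), `B`, `w`,
#'   `conf_level`, `n_dropped`.
#' @export
pyra_boot <- function(paired, w = 21L, B = 1000L, conf_level = 0.95,
                      zero_denominator = c("missing", "epsilon"),
                      epsilon = 1, seed = NULL) {
  stopifnot(inherits(paired, "paired_series"))
  zero_denominator <- match.arg(zero_denominator)
  if (conf_level <= 0 || conf_level >= 1) {
    stop("`conf_level` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  K <- paired$K
  w <- as.integer(w)
  if (is.na(w) || w < 2L || w > K) {
    stop(sprintf("`w` must lie in [2, K = %d]", K), call. = FALSE)
  }
  p <- paired$pairs
  c1 <- cumsum(p$y1)
  c2 <- cumsum(p$y2)
  nb <- ceiling(K / w)
  starts <- matrix(sample.int(K - w + 1L, nb * B, replace = TRUE), nrow = nb)
  s1 <- resample_sums(c1, starts, w, K)
  s2 <- resample_sums(c2, starts, w, K)
  if (zero_denominator == "epsilon") {
    t <- (s2 + epsilon) / (s1 + epsilon)
    t0 <- (sum(p$y2) + epsilon) / (sum(p$y1) + epsilon)
  } else {
    t <- ifelse(s1 > 0, s2 / s1, NA_real_)
    t0 <- if (sum(p$y1) > 0) sum(p$y2) / sum(p$y1) else NA_real_
  }
  dropped <- sum(is.na(t))
  t <- t[!is.na(t)]
  if (!length(t)) {
    stop("all resample statistics were undefined (zero year-1 sums)",
         call. = FALSE)
  }
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(t, c(alpha / 2, 1 - alpha / 2)))
  structure(list(t0 = t0, ci = ci, t = t, B = as.integer(B), w = w,
                 conf_level = conf_level, n_dropped = dropped),
            class = "pyra_boot")
}

#' @export
print.pyra_boot <- function(x, ...) {
  cat(sprintf("Moving-block bootstrap: B = %d, block span w = %d\n",
              x$B, x$w))
  cat(sprintf("  statistic %.4f, %g%% percentile CI [%.4f, %.4f]\n",
              x$t0, 100 * x$conf_level, x$ci[1L], x$ci[2L]))
  if (x$n_dropped) {
    cat(sprintf("  %d resample(s) dropped (undefined statistic)\n",
                x$n_dropped))
  }
  invisible(x)
}

# Per-window percentile bands for the trend series: within each forward
# C-window's own pairs, blocks of w pairs are resampled as in pyra_boot.
# Returns a data frame aligned with pyra_series(paired, I, min_pairs).
series_boot_bands <- function(paired, I, w, B, conf_level, min_pairs) {
  p <- paired$pairs
  k <- p$k
  lo <- min(k)
  hi <- max(k)
  starts_all <- lo:hi
  nwin <- length(starts_all)
  ci_low <- rep(NA_real_, nwin)
  ci_high <- rep(NA_real_, nwin)
  alpha <- 1 - conf_level
  # pairs are sorted by k within pair_cycle but k is globally sorted too
  # (pair_cycle increases with k), so each window is a contiguous run
  i1 <- findInterval(starts_all - 1L, k) + 1L
  i2 <- findInterval(starts_all + I - 1L, k)
  for (j in seq_len(nwin)) {
    a <- i1[j]; b <- i2[j]
    n <- b - a + 1L
    if (n < max(min_pairs, w)) next
    c1 <- cumsum(p$y1[a:b])
    c2 <- cumsum(p$y2[a:b])
    nb <- ceiling(n / w)
    sm <- matrix(sample.int(n - w + 1L, nb * B, replace = TRUE), nrow = nb)
    s1 <- resample_sums(c1, sm, w, n)
    s2 <- resample_sums(c2, sm, w, n)
    r <- (s2 / s1)[s1 > 0]
    if (!length(r)) next
    q <- stats::quantile(r, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    ci_low[j] <- q[1L]
    ci_high[j] <- q[2L]
  }
  data.frame(time = starts_all + paired$cycle$C %/% 2L,
             ci_low = ci_low, ci_high = ci_high)
}
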