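#' Trend test statistics
#'
#' The four classical nonparametric trend statistics used by the
#' randomisation tests:
#'
#' * `rt_stat_linear_slope()` — ordinary least-squares slope of value on
#'   time (`RT1`): a significantly negative or positive slope indicates a
#'   downward or upward trend.
#' * `rt_stat_runs_median()` — number of runs above and below the median
#'   (`RT2`), values equal to the median removed first: a trend produces
#'   long one-sided stretches and hence few runs.
#' * `rt_stat_positive_diffs()` — number of positive successive differences
#'   (`RT3`), zero differences not counted: low counts suggest decline,
#'   high counts suggest increase.
#' * `rt_stat_runs_updown()` — number of runs of same-sign successive
#'   differences (`RT4`), zero differences removed: few runs indicate
#'   persistent movement in one direction.
#'
#' Tie handling (dropping median-equal values and zero differences) follows
#' standard runs-test practice.
#'
#' @param x Numeric vector of observations in time order.
#' @param times Observation times for the slope statistic (default equally
#'   spaced).
#' @return A single number (integer-valued for the run/count statistics).
#' @name rt_statistics
NULL

#' @rdname rt_statistics
#' @export
rt_stat_linear_slope <- function(x, times = seq_along(x)) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  tc <- times - mean(times)
  den <- sum(tc^2)
  if (den == 0) stop("degenerate times: all observation times equal",
                     call. = FALSE)
  sum(tc * x) / den
}

#' @rdname rt_statistics
#' @export
rt_stat_runs_median <- function(x) {
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  m <- stats::median(x)
  s <- x[x != m] > m
  if (!length(s)) stop("statistic undefined: all values equal the median",
                       call. = FALSE)
  1L + sum(s[-1L] != s[-length(s)])
}

#' @rdname rt_statistics
#' @export
rt_stat_positive_diffs <- function(x) {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  sum(diff(x) > 0)
}

#' @rdname rt_statistics
#' @export
rt_stat_runs_updown <- function(x) {
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  s <- sign(diff(x))
  s <- s[s != 0]
  if (!length(s)) stop("statistic undefined: all differences are zero",
                       call. = FALSE)
  1L + sum(s[-1L] != s[-length(s)])
}

rt_default_tails <- c(RT1 = "two_sided", RT2 = "lower",
                      RT3 = "two_sided", RT4 = "lower")

# All four statistics over a matrix of permuted series (rows = permutations
# of the same values), sharing one permutation set.  Fast vectorised paths
# cover the common no-ties cases; rows with ties fall back to the scalar
# statistics.
rt_stats_matrix <- function(M, which = c("RT1", "RT2", "RT3", "RT4"),
                            times = seq_len(ncol(M))) {
  n <- ncol(M)
  x <- M[1L, ]
  out <- list()
  if ("RT1" %in% which) {
    tc <- times - mean(times)
    out$RT1 <- as.vector(M %*% tc) / sum(tc^2)
  }
  if ("RT2" %in% which) {
    m <- stats::median(x)
    if (any(x == m)) {
      out$RT2 <- apply(M, 1L, rt_stat_runs_median)
    } else {
      S <- M > m
      out$RT2 <- 1L + rowSums(S[, -1L, drop = FALSE] !=
                                S[, -n, drop = FALSE])
    }
  }
  if ("RT3" %in% which) {
    out$RT3 <- rowSums(M[, -1L, drop = FALSE] > M[, -n, drop = FALSE])
  }
  if ("RT4" %in% which) {
    if (anyDuplicated(x)) {
      out$RT4 <- apply(M, 1L, rt_stat_runs_updown)
    } else {
      A <- M[, -1L, drop = FALSE] > M[, -n, drop = FALSE]
      out$RT4 <- 1L + rowSums(A[, -1L, drop = FALSE] !=
                                A[, -(n - 1L), drop = FALSE])
    }
  }
  out
}

rt_pvalue <- function(obs, perm, tail, B) {
  p_lower <- (1 + sum(perm <= obs)) / (B + 1)
  p_upper <- (1 + sum(perm >= obs)) / (B + 1)
  switch(tail,
         lower = p_lower,
         upper = p_upper,
         two_sided = min(1, 2 * min(p_lower, p_upper)))
}

#' Randomisation (permutation) trend test
#'
#' Compares an observed trend statistic with its distribution over `B`
#' random re-orderings of the series.  Under the null hypothesis of no
#' trend the observations are exchangeable, so any permutation is as likely
#' as the observed order; gaps in the record do not affect the test's
#' validity.  P-values use the add-one correction
#' `p = (1 + #extreme) / (B + 1)`, so `p >= 1/(B + 1)` always.
#'
#' Default tails follow each statistic's directional reading: `RT1`
#' two-sided on the absolute slope, `RT2` lower (few runs indicate trend),
#' `RT3` two-sided (`2 * min(lower, upper)` tail doubling), `RT4` lower.
#'
#' @param x Numeric vector in time order, or a [daily_series()] (values are
#'   taken in day order and `day_index` supplies the times).
#' @param test One of `"RT1"`, `"RT2"`, `"RT3"`, `"RT4"`.
#' @param B Number of random permutations (default 5000).
#' @param tail Override the default tail: `"two_sided"`, `"lower"` or
#'   `"upper"`.
#' @param times Observation times for `RT1`; defaults to `day_index` for a
#'   series and to `1..n` otherwise.
#' @param seed Optional integer seed.
#' @return An object of classes `"pyra_rt"` and `"htest"` with fields
#'   `statistic`, `p.value`, `parameter` (B), `alternative`, `method`,
#'   `data.name` and `perm_stats` (the permutation distribution sample).
#' @examples
#' set.seed(1)
#' rt_test(cumsum(rnorm(40, -0.2)), "RT2", B = 999)
#' @export
rt_test <- function(x, test = c("RT1", "RT2", "RT3", "RT4"), B = 5000L,
                    tail = NULL, times = NULL, seed = NULL) {
  test <- match.arg(test)
  dn <- deparse(substitute(x))
  if (inherits(x, "daily_series")) {
    if (is.null(times)) times <- x$records$day_index
    x <- x$records$value
  }
  x <- as.numeric(x)
  if (is.null(times)) times <- seq_along(x)
  if (is.null(tail)) tail <- rt_default_tails[[test]]
  tail <- match.arg(tail, c("two_sided", "lower", "upper"))
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(B)
  n <- length(x)
  obs <- switch(test,
                RT1 = rt_stat_linear_slope(x, times),
                RT2 = rt_stat_runs_median(x),
                RT3 = rt_stat_positive_diffs(x),
                RT4 = rt_stat_runs_updown(x))
  M <- matrix(x[vapply(seq_len(B), function(i) sample.int(n), integer(n))],
              nrow = B, byrow = TRUE)
  perm <- rt_stats_matrix(M, which = test, times = times)[[test]]
  p <- if (test == "RT1" && tail == "two_sided") {
    (1 + sum(abs(perm) >= abs(obs))) / (B + 1)  # slope null is centred at 0
  } else {
    rt_pvalue(obs, perm, tail, B)
  }
  structure(list(
    statistic = stats::setNames(obs, "stat"),
    p.value = p,
    parameter = c(B = B),
    alternative = tail,
    method = sprintf("Randomisation trend test %s (%s)", test,
                     switch(test,
                            RT1 = "linear regression slope",
                            RT2 = "runs above and below the median",
                            RT3 = "number of positive differences",
                            RT4 = "runs of up/down differences")),
    data.name = dn,
    test = test,
    n = n,
    perm_stats = perm
  ), class = c("pyra_rt", "htest"))
}

#' All four randomisation trend tests on one series
#'
#' Runs RT1-RT4 against a single shared set of `B` permutations and returns
#' a compact table, one row per test.
#'
#' @inheritParams rt_test
#' @return Data frame with columns `test`, `statistic`, `p_value`, `tail`
#'   and `B`.
#' @export
rt_table <- function(x, B = 5000L, times = NULL, seed = NULL) {
  if (inherits(x, "daily_series")) {
    if (is.null(times)) times <- x$records$day_index
    x <- x$records$value
  }
  x <- as.numeric(x)
  if (is.null(times)) times <- seq_along(x)
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(B)
  n <- length(x)
  M <- matrix(x[vapply(seq_len(B), function(i) sample.int(n), integer(n))],
              nrow = B, byrow = TRUE)
  perm <- rt_stats_matrix(M, times = times)
  obs <- c(RT1 = rt_stat_linear_slope(x, times),
           RT2 = rt_stat_runs_median(x),
           RT3 = rt_stat_positive_diffs(x),
           RT4 = rt_stat_runs_updown(x))
  tests <- names(rt_default_tails)
  p <- vapply(tests, function(tt) {
    if (tt == "RT1") {
      (1 + sum(abs(perm[[tt]]) >= abs(obs[[tt]]))) / (B + 1)
    } else {
      rt_pvalue(obs[[tt]], perm[[tt]], rt_default_tails[[tt]], B)
    }
  }, numeric(1L))
  data.frame(test = tests,
             statistic = unname(obs),
             p_value = unname(p),
             tail = unname(rt_default_tails),
             B = B,
             row.names = NULL)
}
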