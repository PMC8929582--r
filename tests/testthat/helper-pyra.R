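# Shared fixtures and independent oracles for the test suite.

# quick fully logged series on day indices 1..n (or a given index set)
make_days <- function(value, day_index = seq_along(value),
                      logged_fraction = 1, site_id = "s1",
                      cycle = cycle_config()) {
  daily_series(day_index = day_index, value = value,
               logged_fraction = logged_fraction, site_id = site_id,
               cycle = cycle)
}

# all permutations of a vector, one per row (n! rows; keep n tiny)
permutations_all <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L, 1L))
  out <- NULL
  for (i in seq_along(v)) {
    out <- rbind(out, cbind(v[i], permutations_all(v[-i])))
  }
  unname(out)
}

# independent trend statistics, built on different primitives than the
# package (lm, rle) so they can serve as oracles
oracle_slope <- function(x, times = seq_along(x)) {
  unname(stats::coef(stats::lm(x ~ times))[2L])
}
oracle_runs_median <- function(x) {
  s <- x[x != stats::median(x)] > stats::median(x)
  length(rle(s)$lengths)
}
oracle_pos_diffs <- function(x) {
  n <- length(x)
  sum(x[-1L] > x[-n])
}
oracle_runs_updown <- function(x) {
  s <- sign(diff(x))
  length(rle(s[s != 0])$lengths)
}

# exact permutation p-values over full enumeration, using the same tail
# conventions as rt_test (add-one-free: the identity ordering is a member
# of the enumeration)
oracle_exact_p <- function(x, stat_fun, tail) {
  perms <- permutations_all(x)
  stats <- apply(perms, 1L, stat_fun)
  obs <- stat_fun(x)
  n <- length(stats)
  switch(tail,
         lower = sum(stats <= obs) / n,
         upper = sum(stats >= obs) / n,
         abs_two_sided = sum(abs(stats) >= abs(obs)) / n,
         two_sided = min(1, 2 * min(sum(stats <= obs) / n,
                                    sum(stats >= obs) / n)))
}
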