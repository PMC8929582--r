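test_that("noise-free scenario means follow their design exactly", {
  c1 <- gen_complete(scenario_config("S1", noise_sd = 0))
  r1 <- c1$records
  expect_equal(nrow(r1), 1460L)
  expect_true(all(r1$logged_fraction == 1))
  expect_equal(r1$value[1], 100)
  expect_equal(r1$value[365], 50)
  # every cycle repeats the same seasonal ramp
  m <- matrix(r1$value, nrow = 365)
  expect_equal(m[, 2], m[, 1])
  expect_equal(m[, 4], m[, 1])

  c2 <- gen_complete(scenario_config("S2", noise_sd = 0,
                                     total_decline_fraction = 0.5))
  expect_equal(c2$records$value[1], 100)
  expect_equal(c2$records$value[1460], 50)
  # linear throughout
  expect_equal(unique(round(diff(c2$records$value), 12)),
               round(-50 / 1459, 12))
})

test_that("the shifting window keeps the designed day counts", {
  cfg <- scenario_config("S1", noise_sd = 0)
  inc <- apply_window_design(gen_complete(cfg), cfg)
  expect_equal(nrow(inc$records), 400L)           # 27% of 1460
  expect_equal(as.vector(table(inc$records$cycle_index)), rep(100L, 4))
  # cycle j's window starts 30 days later than cycle j-1's
  starts <- tapply(inc$records$day_of_cycle, inc$records$cycle_index, min)
  expect_equal(as.vector(diff(starts)), rep(30L, 3))

  # no shift: the same positions every cycle
  cfg0 <- scenario_config("S1", noise_sd = 0, window_shift = 0)
  inc0 <- apply_window_design(gen_complete(cfg0), cfg0)
  expect_equal(days_logged_in_all_cycles(inc0, 4), 100L)

  # designs that leave the cycle are rejected up front
  expect_error(scenario_config("S1", window_length = 300, window_shift = 30),
               "window")
})

test_that("window combinatorics hold over a parameter grid", {
  for (len in c(40L, 100L, 160L)) for (shift in c(0L, 10L, 30L)) {
    if (len + 3L * shift > 365L) next
    cfg <- scenario_config("S1", noise_sd = 0, window_length = len,
                           window_shift = shift)
    trip <- make_triplet(cfg)
    expect_equal(nrow(trip$incomplete$records), 4L * len)
    expect_equal(trip$paired$K, 3L * (len - shift))
    expect_equal(days_logged_in_all_cycles(trip$incomplete, 2),
                 len - shift)
  }
})

test_that("seeded triplets are reproducible and internally consistent", {
  a <- make_triplet(scenario_config("S2", seed = 77))
  b <- make_triplet(scenario_config("S2", seed = 77))
  expect_identical(a$complete$records, b$complete$records)
  expect_identical(a$paired$pairs, b$paired$pairs)
  # paired really is the pairing of incomplete
  expect_equal(a$paired$pairs, pair_extract(a$incomplete)$pairs)
  # truncation keeps counts non-negative even under heavy noise
  h <- gen_complete(scenario_config("S2", noise_sd = 200, seed = 1))
  expect_true(all(h$records$value >= 0))
})

test_that("noise-free summaries equal their closed forms downstream", {
  t1 <- make_triplet(scenario_config("S1", noise_sd = 0))
  expect_equal(pyra_summary(t1$paired)$P_T, 1)
  tr <- pyra_series(t1$paired)
  expect_true(all(abs(tr$ratio[!is.na(tr$ratio)] - 1) < 1e-12))

  # S2: ratio of mean-function sums over the paired positions, computed
  # here independently of the generator's own mean function
  cfg <- scenario_config("S2", noise_sd = 0)
  mu <- function(t) 100 * (1 - 0.75 * (t - 1) / 1459)
  num <- den <- 0
  for (j in 1:3) {
    doc <- (1 + 30 * j):(100 + 30 * (j - 1))
    t1j <- 365 * (j - 1) + doc
    num <- num + sum(mu(t1j + 365))
    den <- den + sum(mu(t1j))
  }
  got <- pyra_summary(make_triplet(cfg)$paired)$P_T
  expect_equal(got, num / den, tolerance = 1e-13)
})

test_that("summary stays near its design value across noise levels", {
  for (lev in c("low", "moderate", "high")) {
    p1 <- vapply(1:20, function(s)
      pyra_summary(make_triplet(scenario_config("S1", noise_sd = lev,
                                                seed = 600 + s))$paired)$P_T,
      numeric(1))
    expect_lt(max(abs(p1 - 1)), 0.05)
  }
  # the drifting window fabricates an apparent decline in the seasonal
  # no-trend scenario, which the slope and median-runs tests then flag
  tr <- make_triplet(scenario_config("S1", seed = 19))
  tab <- rt_table(paired_day_series(tr$paired), B = 500, seed = 20)
  expect_lt(tab$p_value[tab$test == "RT1"], 0.01)
  expect_lt(tab$p_value[tab$test == "RT2"], 0.01)
})
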