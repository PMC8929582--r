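test_that("paired extraction matches days fully logged one cycle apart", {
  # two identical fully logged cycles -> every position pairs
  s <- make_days(rep(5, 730))
  p <- pair_extract(s)
  expect_equal(p$K, 365L)
  expect_equal(p$pairs$y1, p$pairs$y2)

  # complete multi-cycle data: K = (n_cycles - 1) * C exactly
  s4 <- make_days(rnorm(1460, 100, 1))
  expect_equal(pair_extract(s4)$K, 3L * 365L)

  # a day can serve as second member of one pair and first of the next
  p4 <- pair_extract(s4)
  expect_true(any(p4$pairs$k %in% (p4$pairs$k + 365L)))

  # disjoint day-of-cycle windows in successive cycles -> no pairs
  sd <- make_days(rep(1, 100), day_index = c(1:50, 416:465))
  expect_equal(suppressWarnings(pair_extract(sd))$K, 0L)

  # under-two-cycle span warns instead of failing
  expect_warning(p0 <- pair_extract(make_days(rep(1, 300))), "two cycles")
  expect_equal(p0$K, 0L)

  # partially logged days never pair
  lf <- rep(1, 730); lf[10] <- 0.8
  plf <- pair_extract(make_days(rep(1, 730), logged_fraction = lf))
  expect_equal(plf$K, 364L)
  expect_false(10 %in% plf$pairs$k)
})

test_that("pairing is invariant to record order and to unpaired days", {
  set.seed(11)
  idx <- sort(sample(1:1100, 600))
  val <- runif(600, 0, 50)
  s <- make_days(val, day_index = idx)
  p <- pair_extract(s)

  sh <- sample(600)
  p_sh <- pair_extract(make_days(val[sh], day_index = idx[sh]))
  expect_equal(p_sh$pairs, p$pairs)

  paired_days <- unique(c(p$pairs$k, p$pairs$k + 365L))
  keep <- idx %in% paired_days
  p_only <- pair_extract(make_days(val[keep], day_index = idx[keep]))
  expect_equal(p_only$pairs, p$pairs)
})

test_that("day positions logged in all cycles shrink with the window drift", {
  cfg <- scenario_config("S1", noise_sd = 0)
  inc <- apply_window_design(gen_complete(cfg), cfg)
  expect_equal(days_logged_in_all_cycles(inc, 2), 70L)
  expect_equal(days_logged_in_all_cycles(inc, 4), 10L)
  expect_error(days_logged_in_all_cycles(inc, 5), "fewer than")
  expect_equal(days_logged_in_all_cycles(gen_complete(cfg), 4), 365L)
})

test_that("pooling sites sums detections before the ratio", {
  a <- pair_extract(make_days(rep(c(10, 5), each = 365), site_id = "a"))
  b <- pair_extract(make_days(rep(c(30, 25), each = 365), site_id = "b"))
  pooled <- combine_sites(a, b)
  expect_equal(pooled$K, 730L)
  # (5 + 25) / (10 + 30), not the mean of per-site ratios
  expect_equal(pyra_summary(pooled)$P_T, 0.75)

  # identity on one site; an all-zero site leaves the ratio unchanged
  expect_equal(combine_sites(a)$pairs, a$pairs)
  z <- pair_extract(make_days(rep(0, 730), site_id = "z"))
  expect_equal(pyra_summary(combine_sites(a, b, z))$P_T, 0.75)

  expect_error(combine_sites(a, pair_extract(
    make_days(rep(1, 24), day_index = 1:24, site_id = "m",
              cycle = cycle_config(C = 12, unit = "month")))),
    "cycle configuration")
})

test_that("the paired day set rebuilds distinct days once each", {
  cfg <- scenario_config("S2", seed = 3)
  trip <- make_triplet(cfg)
  pd <- paired_day_series(trip$paired)
  expect_equal(nrow(pd$records), 340L)
  # values agree with the incomplete series they came from
  inc <- trip$incomplete$records
  m <- match(pd$records$day_index, inc$day_index)
  expect_equal(pd$records$value, inc$value[m])
})

test_that("paired data export round-trips through CSV", {
  p <- pair_extract(make_days(1:730))
  path <- withr::local_tempfile(fileext = ".csv")
  write_paired_csv(p, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 365L)
  expect_named(back, c("site_id", "pair_cycle", "day_of_cycle", "y1", "y2"))
  expect_equal(back$y2 - back$y1, rep(365L, 365L))
})
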