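test_that("the fitted model object carries estimate, intervals and methods", {
  trip <- make_triplet(scenario_config("S1", seed = 42))
  fit <- pyra(trip$paired, B = 300, seed = 1)
  expect_s3_class(fit, "pyra")
  expect_equal(unname(coef(fit)), fit$summary$P_T)
  ci <- confint(fit)
  expect_equal(dim(ci), c(1L, 2L))
  expect_lte(ci[1], coef(fit))
  expect_gte(ci[2], coef(fit))
  # the no-trend scenario: ratio near 1, interval covering 1
  expect_lt(abs(coef(fit) - 1), 0.05)
  expect_true(ci[1] <= 1 && 1 <= ci[2])
  # per-window bands bracket the trend curve where both exist
  ok <- !is.na(fit$trend$ratio) & !is.na(fit$trend$ci_low)
  expect_gt(sum(ok), 100)
  expect_true(all(fit$trend$ci_low[ok] <= fit$trend$ci_high[ok]))
  expect_output(print(fit), "P_T")
  expect_output(summary(fit), "trend series")

  # accepts raw series and lists of sites too
  fit2 <- pyra(trip$incomplete, B = 100, series_ci = FALSE, seed = 2)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-12)
})

test_that("fits are reproducible given a seed", {
  trip <- make_triplet(scenario_config("S2", seed = 5))
  f1 <- pyra(trip$paired, B = 200, seed = 9)
  f2 <- pyra(trip$paired, B = 200, seed = 9)
  expect_identical(f1$summary$ci, f2$summary$ci)
  expect_identical(f1$trend, f2$trend)
})

test_that("the population trend plot draws without error", {
  trip <- make_triplet(scenario_config("S2", seed = 3))
  fit <- pyra(trip$paired, B = 100, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(path)
  expect_no_error(plot(fit))
  grDevices::dev.off()
  expect_gt(file.size(path), 1000)
})

test_that("results serialise to CSV and JSON with everything the plot shows", {
  trip <- make_triplet(scenario_config("S2", seed = 6))
  fit <- pyra(trip$paired, B = 100, seed = 7)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trend_csv(fit, csv)
  back <- read.csv(csv)
  expect_named(back, c("time", "ratio", "ci_low", "ci_high", "n_pairs"))
  expect_equal(nrow(back), nrow(fit$trend))

  js <- withr::local_tempfile(fileext = ".json")
  write_summary_json(fit, js)
  got <- jsonlite::read_json(js)
  expect_equal(got$P_T, fit$summary$P_T)
  expect_equal(got$K, fit$summary$K)
  expect_equal(got$ci_low, fit$summary$ci[[1]])

  dir <- withr::local_tempdir()
  write_triplet_csv(trip, dir)
  expect_setequal(list.files(dir),
                  c("complete.csv", "incomplete.csv", "paired.csv"))
  inc <- read_detections(file.path(dir, "incomplete.csv"))
  expect_equal(nrow(inc$records), 400L)
})

test_that("period aggregation averages fully logged days per bin", {
  s <- make_days(rep(4, 60))
  agg <- aggregate_periods(s, 30)
  expect_equal(nrow(agg$records), 2L)
  expect_equal(agg$records$value, c(4, 4))
  expect_equal(agg$cycle$C, 12L)
  expect_equal(agg$cycle$unit, "period")

  # bins with no fully logged day are absent; partial bins keep their
  # fraction so the bin-level threshold can judge them
  lf <- rep(1, 90); lf[31:60] <- 0.3
  s2 <- make_days(c(rep(2, 30), rep(9, 30), rep(4, 30)),
                  logged_fraction = lf)
  agg2 <- aggregate_periods(s2, 30)
  expect_equal(agg2$records$day_index, c(1L, 3L))
  expect_equal(agg2$records$value, c(2, 4))

  half <- make_days(1:45, day_index = 1:45)
  agg3 <- aggregate_periods(half, 30)
  expect_equal(agg3$records$logged_fraction, c(1, 0.5))

  # a 64-period span with 9 missing periods leaves 55 usable ones, and
  # monthly pairing then works on the aggregate
  set.seed(2)
  miss <- sample(1:64, 9)
  days <- unlist(lapply(setdiff(1:64, miss), function(b)
    (b - 1) * 30 + 1:30))
  s3 <- make_days(rexp(length(days), 1 / 20), day_index = days)
  agg4 <- aggregate_periods(s3, 30)
  expect_equal(nrow(agg4$records), 55L)
  p <- pair_extract(agg4)
  expect_gt(p$K, 0)
})
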