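test_that("leap days are removed and day indices stay cycle-aligned", {
  # 1461 consecutive dates spanning one 29 February -> 4 x 365 days
  d <- data.frame(date = seq(as.Date("2015-03-01"), by = "day",
                             length.out = 1461),
                  value = 1)
  s <- strip_leap_days(d)
  expect_equal(nrow(s), 1460L)
  expect_equal(s$day_index, 1:1460)

  # leap-free input: identity up to renumbering
  d2 <- data.frame(date = seq(as.Date("2017-01-10"), by = "day",
                              length.out = 365),
                   value = rnorm(365))
  s2 <- strip_leap_days(d2)
  expect_equal(nrow(s2), 365L)
  expect_equal(s2$value, d2$value)
  expect_equal(s2$day_index, 1:365)

  # 366 consecutive dates including Feb 29: the day after Feb 29 takes the
  # index Feb 29 would have had, so cross-year day positions still match
  d3 <- data.frame(date = seq(as.Date("2016-01-01"), by = "day",
                              length.out = 366),
                   value = 0)
  s3 <- strip_leap_days(d3)
  expect_equal(nrow(s3), 365L)
  expect_equal(s3$day_index[s3$date == as.Date("2016-03-01")], 60L)
  expect_false(as.Date("2016-02-29") %in% s3$date)

  # same month-day one (non-leap-crossing) year apart differs by exactly C
  ds <- as_daily_series(d, cycle = cycle_config())
  r <- ds$records
  i1 <- which(r$date == as.Date("2016-06-15"))
  i2 <- which(r$date == as.Date("2017-06-15"))
  expect_equal(r$day_index[i2] - r$day_index[i1], 365L)
  expect_equal(r$day_of_cycle[i1], r$day_of_cycle[i2])
})

test_that("dated input is validated with informative rejections", {
  dup <- data.frame(site_id = "a",
                    date = c("2020-01-01", "2020-01-02", "2020-01-01"),
                    value = 1)
  expect_error(strip_leap_days(dup), "duplicate.*2020-01-01")
  expect_error(strip_leap_days(data.frame(date = "01/02/2020", value = 1)),
               "unparseable")
  expect_error(daily_series(c(3, 3), c(1, 2)), "duplicate.*day_index 3")
})

test_that("validation report counts logging completeness and gaps", {
  s <- make_days(rep(2, 1460))
  v <- validate_series(s)
  expect_equal(v$n_fully_logged, 1460L)
  expect_length(v$gap_runs, 0L)

  lf <- rep(1, 10); lf[4] <- 0.5
  s2 <- make_days(1:10, logged_fraction = lf)
  v2 <- validate_series(s2)
  expect_equal(v2$n_fully_logged, 9L)
  expect_equal(v2$n_partial, 1L)

  # gaps and bad values are reported, never fatal
  s3 <- make_days(c(1, -2, NA, 4), day_index = c(1, 2, 10, 12))
  v3 <- validate_series(s3)
  expect_equal(sort(v3$gap_runs), c(1L, 7L))
  expect_equal(v3$n_negative, 1L)
  expect_equal(v3$n_nonfinite, 1L)

  # a configurable threshold admits almost-complete sensor days
  s4 <- make_days(1:5, logged_fraction = 1439 / 1440,
                  cycle = cycle_config(full_log_threshold = 0.99))
  expect_equal(validate_series(s4)$n_fully_logged, 5L)
})

test_that("the CSV dialect reads dates, day indices and logged minutes", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(site_id = "siteA",
                   date = format(seq(as.Date("2019-01-01"), by = "day",
                                     length.out = 20)),
                   value = 1:20,
                   logged_minutes = c(rep(1440, 19), 720))
  write.csv(df, path, row.names = FALSE)
  s <- read_detections(path)
  expect_s3_class(s, "daily_series")
  expect_equal(s$site_id, "siteA")
  expect_equal(s$records$logged_fraction[20], 0.5)
  expect_equal(validate_series(s)$n_fully_logged, 19L)

  # day_index dialect (e.g. monthly data) needs no dates
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(site_id = "m", day_index = 1:24, value = 2,
                       logged_fraction = 1),
            path2, row.names = FALSE)
  m <- read_detections(path2, cycle = cycle_config(C = 12, unit = "month"))
  expect_equal(m$records$day_of_cycle, rep(1:12, 2))
  expect_equal(pair_extract(m)$K, 12L)

  expect_error(read_detections(withr::local_tempfile(lines = "site_id,date,value",
                                                     fileext = ".csv")),
               "no records")
})
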