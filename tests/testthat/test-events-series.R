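test_that("series CSV round-trips exactly and enforces the uniform grid", {
  x <- monitored_series(c(70.5, 71, 69.25, 72.125, 70), t0 = 3, dt = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(x, f)
  y <- read_series_csv(f)
  expect_equal(y$values, x$values)
  expect_equal(y$t0, x$t0)
  expect_equal(y$dt, x$dt)

  # 10 rows at 1-minute spacing -> length 10, dt 1
  write_series_csv(monitored_series(1:10), f)
  expect_equal(length(read_series_csv(f)$values), 10)
  expect_equal(read_series_csv(f)$dt, 1)

  # non-uniform grid that gap-filling cannot repair
  writeLines(c("time,value", "0,1", "1,2", "2.5,3"), f)
  expect_error(read_series_csv(f), "uniform")
  writeLines("time,value", f)
  expect_error(read_series_csv(f), "empty")
})

test_that("missing series values are forward-filled (back-filled head)", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,value", "0,5", "1,6", "2,NA", "3,8"), f)
  expect_equal(read_series_csv(f)$values, c(5, 6, 6, 8))
  # a missing interior row is a grid gap, filled the same way
  writeLines(c("time,value", "0,5", "1,6", "3,8"), f)
  expect_equal(read_series_csv(f)$values, c(5, 6, 6, 8))
  # missing head is back-filled from the first observation
  writeLines(c("time,value", "0,NA", "1,6", "2,7"), f)
  expect_equal(read_series_csv(f)$values, c(6, 6, 7))
  writeLines(c("time,value", "0,5", "1,NA", "2,7"), f)
  expect_error(read_series_csv(f, fill_missing = FALSE), "missing")
})

test_that("event CSV reading validates, sorts, and handles duplicates by policy", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(event_schedule(seq(2, 200, length.out = 63), 25), f)
  e <- read_events_csv(f)
  expect_s3_class(e, "event_schedule")
  expect_equal(nrow(e), 63)
  expect_true(all(e$dose == 25))

  # unsorted input comes back sorted ascending
  writeLines(c("time,dose", "30,25", "10,25", "20,25"), f)
  expect_equal(read_events_csv(f)$time, c(10, 20, 30))

  # empty schedule is valid (model reduces to baseline)
  writeLines("time,dose", f)
  expect_equal(nrow(read_events_csv(f)), 0)

  writeLines(c("time,dose", "10,0"), f)
  expect_error(read_events_csv(f), "dose")
  writeLines(c("time,dose", "10,25", "10,25"), f)
  expect_error(read_events_csv(f), "duplicate")
  expect_equal(read_events_csv(f, merge_duplicates = TRUE)$dose, 50)
})

test_that("schedule generation is a pure function of its arguments", {
  a <- generate_event_schedule(60, 13, 25, seed = 42)
  b <- generate_event_schedule(60, 13, 25, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 60)
  expect_true(all(a$dose == 25))
  expect_true(all(diff(a$time) > 0))
  expect_equal(nrow(generate_event_schedule(0, 13, 25, seed = 1)), 0)
  # session RNG state is untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_event_schedule(10, 13, 25, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("dose-mark series places doses on the grid and sums co-binned events", {
  tmpl <- monitored_series(rep(0, 20), t0 = 0, dt = 1)
  sched <- event_schedule(c(3, 3.4, 10), c(25, 25, 10), merge_duplicates = TRUE)
  dm <- dose_mark_series(sched, tmpl)
  expect_equal(sum(dm$values > 0), 2)
  expect_equal(dm$values[4], 50)   # both near-t=3 events land in bin 3
  expect_equal(dm$values[11], 10)
  ind <- dose_mark_series(sched, tmpl, encoding = "indicator")
  expect_equal(sort(unique(ind$values)), c(0, 1))
  expect_error(dose_mark_series(event_schedule(100, 25), tmpl), "outside")
})
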