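# Sighting-record IO, the season-year rule and occasion calendars.

test_that("season-year assignment follows the spring-year rule", {
  expect_identical(assign_season_year(as.Date("2012-10-09")), 2012L)
  expect_identical(assign_season_year(as.Date("2013-04-06")), 2012L)
  expect_identical(assign_season_year(as.Date("2021-11-17")), 2021L)
  # idempotent/total on October-April dates
  d <- seq(as.Date("2015-10-01"), as.Date("2016-04-30"), by = "7 days")
  sy <- assign_season_year(d)
  expect_false(anyNA(sy))
  expect_true(all(sy == 2015L))
  expect_warning(out <- assign_season_year(as.Date("2015-06-15")),
                 "outside any field season")
  expect_true(is.na(out))
})

test_that("reading sightings validates rows and preserves order", {
  df <- make_records(c("2013-01-05 10:00:00", "2013-01-05 10:05:00",
                       "2013-01-06 09:00:00"), id = c("A", "B", "A"))
  f <- tempfile(fileext = ".csv")
  write_sightings(df, f)
  back <- read_sightings(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$individual_id, c("A", "B", "A"))
  expect_equal(back$timestamp, df$timestamp)
  expect_equal(back$focus, df$focus)
  expect_equal(nrow(attr(back, "rejections")), 0L)

  # one bad timestamp: 2 records plus a reported rejection with line number
  raw <- utils::read.csv(f, colClasses = "character")
  raw$timestamp[2] <- "not-a-date"
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(raw, f2, row.names = FALSE)
  expect_warning(back2 <- read_sightings(f2), "rejected")
  expect_equal(nrow(back2), 2L)
  rej <- attr(back2, "rejections")
  expect_equal(rej$line, 3L)  # header + row 2
  expect_match(rej$reason, "timestamp")

  # empty file with header
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(df[0, setdiff(names(df), "date")], f3, row.names = FALSE)
  expect_equal(nrow(read_sightings(f3)), 0L)

  # missing mandatory column is a schema error
  raw$timestamp <- NULL
  f4 <- tempfile(fileext = ".csv")
  utils::write.csv(raw, f4, row.names = FALSE)
  expect_error(read_sightings(f4), "mandatory column")
})

test_that("occasion calendars validate and reproduce the study design", {
  cal <- default_calendar()
  expect_length(cal$years, 10L)
  # the published month lists give 5,5,5,5,3,4,5,5,4,5 secondaries
  occ <- utils::read.csv(extdata("portphillip_occasions.csv"),
                         stringsAsFactors = FALSE)
  months <- lapply(strsplit(occ$months, "-"), function(m) match(m, month.abb))
  names(months) <- occ$season_year
  cal2 <- occasion_calendar(months)
  expect_length(cal2$years, 10L)
  expect_equal(photopop:::n_secondaries(cal2), c(5, 5, 5, 5, 3, 4, 5, 5, 4, 5))
  # the January-April shifted season is representable and ordered
  expect_equal(cal2$primaries[[9]]$month, 1:4)
  expect_true(all(cal2$primaries[[9]]$cal_year == 2021L))
  # degenerate calendars are rejected
  expect_error(occasion_calendar(list(`2012` = integer(0))), "zero secondary")
  expect_error(occasion_calendar(list(`2012` = c(12L, 11L))), "increasing")
  expect_error(occasion_calendar(list(`2012` = c(6L))), "season window")
})

test_that("report writing is deterministic and shape-stable", {
  dir1 <- tempfile(); dir2 <- tempfile()
  abund <- data.frame(season_year = 2012:2013, N = c(40.1, 42.2))
  bundle <- list(abundance = abund, survival = 0.93)
  write_report(bundle, dir1)
  write_report(bundle, dir2)
  expect_true(file.exists(file.path(dir1, "abundance.csv")))
  expect_equal(nrow(utils::read.csv(file.path(dir1, "abundance.csv"))), 2L)
  expect_identical(readLines(file.path(dir1, "abundance.csv")),
                   readLines(file.path(dir2, "abundance.csv")))
  expect_identical(readLines(file.path(dir1, "summary.json")),
                   readLines(file.path(dir2, "summary.json")))
  expect_warning(write_report(list(), tempfile()), "empty")
})
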