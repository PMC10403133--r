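# Birth backdating, calving rate, inter-birth interval and effort models.

test_that("backdating maps size classes to birth years and deduplicates", {
  calves <- data.frame(season_year = c(2016L, 2016L, 2016L, 2015L),
                       mother_id = c("M1", "M2", "M2", "M3"),
                       size_class = c("older", "newborn", "newborn", NA),
                       stringsAsFactors = FALSE)
  expect_warning(b <- backdate_births(calves), "size class")
  expect_equal(b$birth_year[b$mother_id == "M1"], 2015L)
  expect_equal(b$birth_year[b$mother_id == "M2"], 2016L)
  expect_equal(sum(b$mother_id == "M2"), 1L)  # duplicates collapse
  expect_false("M3" %in% b$mother_id)
  # idempotent and shift-equivariant in the year axis
  shifted <- calves[1:3, ]
  shifted$season_year <- shifted$season_year + 3L
  b2 <- backdate_births(shifted)
  expect_equal(b2$birth_year, b$birth_year + 3L)
})

test_that("calving rate divides births by identified adults per year", {
  adults <- c(`2015` = 40, `2016` = 50, `2017` = 0)
  births <- data.frame(mother_id = c("M1", "M2", "M1", "M1"),
                       birth_year = c(2015L, 2015L, 2015L, 2016L),
                       in_study = TRUE, stringsAsFactors = FALSE)
  # the duplicated M1-2015 row mimics a duplicated sighting record
  births <- births[!duplicated(births[, c("mother_id", "birth_year")]), ]
  cr <- calving_rate(births, adults)
  expect_equal(cr$cr[cr$year == 2015], 2 / 40)
  expect_equal(cr$cr[cr$year == 2016], 1 / 50)
  expect_true(is.na(cr$cr[cr$year == 2017]))  # zero adults masked
  expect_equal(calving_rate(births[0, ], adults)$cr[1], 0)
})

test_that("IBI averages within mothers before across mothers", {
  b <- data.frame(mother_id = c("A", "A", "B", "B", "B", "C"),
                  birth_year = c(2013L, 2017L, 2012L, 2015L, 2019L, 2014L),
                  stringsAsFactors = FALSE)
  r <- inter_birth_interval(b)
  # A: 4; B: (3 + 4) / 2 = 3.5; C excluded (single birth)
  expect_equal(r$n_mothers, 2L)
  expect_equal(r$per_mother$mean_interval[r$per_mother$mother_id == "A"], 4)
  expect_equal(r$per_mother$mean_interval[r$per_mother$mother_id == "B"], 3.5)
  expect_equal(r$mean, 3.75)
  expect_equal(r$se, stats::sd(c(4, 3.5)) / sqrt(2))
  # two mothers with per-mother means 3 and 4: overall 3.5
  b2 <- data.frame(mother_id = c("A", "A", "B", "B"),
                   birth_year = c(2012L, 2015L, 2012L, 2016L))
  expect_equal(inter_birth_interval(b2)$mean, 3.5)
  expect_message(r0 <- inter_birth_interval(b2[c(1, 3), ]), "undefined")
  expect_true(is.na(r0$mean))
})

test_that("the effort GLM recovers a constructed Poisson relationship", {
  effort <- c(10, 20, 35, 50, 70, 90)
  beta <- 0.03
  counts <- round(exp(0.5 + beta * effort))
  r <- effort_trend(counts, effort)
  expect_lt(abs(r$coefficient - beta), 0.005)
  expect_lt(r$p_value, 0.01)
  # constant counts over varying effort: coefficient near zero
  r2 <- effort_trend(rep(5L, 6), effort)
  expect_lt(abs(r2$coefficient), 0.01)
  expect_lt(abs(r2$z), 1)
  expect_error(effort_trend(c(3L, 4L), c(10, 20)), "at least 3")
  expect_error(effort_trend(c(0L, 0L, 0L), c(1, 2, 3)), "degenerate")
})

test_that("the effort-weighted mean and its SE follow the stated formulas", {
  r <- effort_weighted_mean(c(2, 4, 6), c(1, 2, 1))
  expect_equal(r$mean, 4)
  expect_equal(r$se, sqrt(1 * 4 + 4 * 0 + 1 * 4) / 4)
  expect_equal(effort_weighted_mean(c(2, 4, 6), c(1, 1, 1))$mean, 4)
  expect_equal(effort_weighted_mean(c(2, 4, 6), c(0, 0, 5))$mean, 6)
  expect_error(effort_weighted_mean(c(1, 2), c(0, 0)), "zero")
})
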