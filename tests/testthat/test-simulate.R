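# The synthetic photo-ID generator: latent states, detection calibration,
# social coupling and reproducibility.

test_that("degenerate survival/emigration settings behave exactly", {
  cfg <- sim_config(n_initial = 30L, recruitment = FALSE,
                    survival = 1, emigration = list(mode = "none"),
                    n_preferred_dyads = 0L)
  tr <- simulate_population(cfg, seed = 2)
  expect_true(all(tr$states == 1L))
  cfg0 <- sim_config(n_initial = 30L, recruitment = FALSE, survival = 0,
                     emigration = list(mode = "none"),
                     n_preferred_dyads = 0L)
  tr0 <- simulate_population(cfg0, seed = 2)
  expect_true(all(tr0$states[, -1] == 3L))
})

test_that("survivorship matches the binomial expectation", {
  cfg <- sim_config(n_initial = 1000L, recruitment = FALSE, survival = 0.9,
                    emigration = list(mode = "none"),
                    n_preferred_dyads = 0L)
  tr <- simulate_population(cfg, seed = 6)
  alive10 <- mean(tr$states[, 10] != 3L)
  expected <- 0.9^9
  mc_sd <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(alive10 - expected), 3 * mc_sd)
})

test_that("pooled monthly detection matches the configured session p", {
  cfg <- sim_config(n_initial = 40L, recruitment = FALSE,
                    survival = 1, emigration = list(mode = "none"),
                    p_range = c(0.4, 0.4), n_preferred_dyads = 0L,
                    mother_fraction = 0, unidentified_image_prob = 0,
                    poor_image_rate = 0)
  tr <- simulate_population(cfg, seed = 3)
  sg <- simulate_sightings(tr, seed = 4)
  rec <- filter_for_analysis(grade_records(sg$records), "capture_recapture")
  h <- build_capture_histories(rec, cfg$calendar)
  # add back the all-zero animals: every individual is in-area throughout
  det_frac <- sum(h$det) / (cfg$n_initial * length(h$cell_primary))
  # group co-membership correlates detections within days; allow a loose
  # band around the binomial error
  n_cells <- cfg$n_initial * length(h$cell_primary)
  expect_lt(abs(det_frac - 0.4), 5 * sqrt(0.4 * 0.6 / n_cells))
})

test_that("capture probability 1 detects every in-area individual", {
  cfg <- sim_config(n_initial = 15L, recruitment = FALSE, survival = 1,
                    emigration = list(mode = "none"), p_range = c(1, 1),
                    n_preferred_dyads = 0L, mother_fraction = 0)
  tr <- simulate_population(cfg, seed = 5)
  sg <- simulate_sightings(tr, seed = 6)
  rec <- filter_for_analysis(grade_records(sg$records), "capture_recapture")
  h <- build_capture_histories(rec, cfg$calendar)
  d3 <- tr$individuals$id[tr$individuals$distinctiveness == "D3"]
  expect_equal(sort(rownames(h$det)), sort(setdiff(tr$individuals$id, d3)))
  expect_true(all(h$det[, ] == 1L))
  # capture probability 0 yields an empty table
  cfg0 <- sim_config(n_initial = 15L, recruitment = FALSE, survival = 1,
                     emigration = list(mode = "none"), p_range = c(0, 0),
                     n_preferred_dyads = 0L, mother_fraction = 0,
                     unidentified_image_prob = 0, poor_image_rate = 0)
  sg0 <- simulate_sightings(simulate_population(cfg0, seed = 5), seed = 6)
  expect_equal(nrow(sg0$records), 0L)
})

test_that("dead individuals never appear in later sightings", {
  cfg <- sim_config(n_initial = 60L, survival = 0.5,
                    emigration = list(mode = "none"),
                    n_preferred_dyads = 0L, recruitment = FALSE)
  tr <- simulate_population(cfg, seed = 8)
  sg <- simulate_sightings(tr, seed = 9)
  if (nrow(sg$records)) {
    sy <- assign_season_year(sg$records$date)
    prim <- match(sy, cfg$years)
    ok <- !is.na(sg$records$individual_id)
    idx <- match(sg$records$individual_id[ok], tr$individuals$id)
    states <- tr$states[cbind(idx, prim[ok])]
    expect_true(all(states == 1L))
  }
})

test_that("preferred dyads stand out of the association distribution", {
  cfg <- sim_config()
  tr <- simulate_population(cfg, seed = 10)
  sg <- simulate_sightings(tr, seed = 11)
  rec <- grade_records(sg$records)
  rec <- rec[rec$band != "poor" & !is.na(rec$individual_id), ]
  # apply the analysis inclusion rule (seen > 5 sampling days), as the
  # social workflow does; dyads broken by early death drop out with it
  ga <- restrict_individuals(assign_groups(rec), min_sightings = 6L)
  am <- half_weight_matrix(ga)
  med <- stats::median(am$hwi[upper.tri(am$hwi)])
  dy <- tr$dyads[tr$dyads[, 1] %in% am$ids & tr$dyads[, 2] %in% am$ids, ,
                 drop = FALSE]
  expect_gte(nrow(dy), 3L)
  vals <- am$hwi[dy]
  expect_true(all(vals > med))
})

test_that("benchmark suites are reproducible and seed-sensitive", {
  cfg <- sim_config(n_initial = 15L, tour_days_per_month = 3L,
                    n_preferred_dyads = 2L)
  s1 <- make_benchmark_suite(cfg, 2L, seed = 42)
  s2 <- make_benchmark_suite(cfg, 2L, seed = 42)
  expect_identical(s1$datasets[[1]]$sightings$records,
                   s2$datasets[[1]]$sightings$records)
  expect_identical(s1$manifest, s2$manifest)
  s3 <- make_benchmark_suite(cfg, 2L, seed = 43)
  expect_false(identical(s1$datasets[[1]]$sightings$records,
                         s3$datasets[[1]]$sightings$records))
  expect_equal(nrow(s1$manifest), 2L)
  # stochastic operations demand an explicit seed
  expect_error(simulate_population(cfg, seed = NA), "seed")
})
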