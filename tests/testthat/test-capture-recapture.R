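# Capture-history construction, the hidden-state likelihood, fitting,
# model selection and diagnostics.

two_by_two <- list(`2012` = c(11L, 12L), `2013` = c(11L, 12L))

test_that("histories pool daily recaptures into monthly cells", {
  ts <- c("2013-01-03 10:00:00", "2013-01-09 10:00:00", "2013-01-21 10:00:00",
          "2013-04-05 10:00:00")
  rec <- make_records(ts, id = "A")
  h <- build_capture_histories(rec, default_calendar(2012:2013))
  # three January days collapse to one detection in the 2012-season January
  expect_equal(sum(h$det), 1L)
  cell <- which(h$det[1, ] == 1L)
  expect_equal(h$cells$season_year[cell], 2012L)
  expect_equal(h$cells$month[cell], 1L)
  # the April image falls outside the Nov-Mar window: no detection cell
  h0 <- build_capture_histories(make_records("2013-04-05 10:00:00"),
                                default_calendar(2012:2013))
  expect_equal(nrow(h0$det), 0L)
  expect_equal(nrow(build_capture_histories(rec[0, ],
                                            default_calendar(2012:2013))$det), 0L)
})

test_that("history exports round-trip and carry the cell headers", {
  det <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L), 2, byrow = TRUE)
  h <- make_hist(det, two_by_two)
  f <- tempfile(fileext = ".csv")
  write_histories_csv(h, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(names(back), c("individual_id", "Y2012_11", "Y2012_12",
                              "Y2013_11", "Y2013_12"))
  expect_equal(unname(as.matrix(back[, -1])), unname(det))
  f2 <- tempfile(fileext = ".inp")
  write_inp(h, f2)
  expect_equal(readLines(f2), c("1010 1;", "1100 1;"))
})

test_that("the conditional likelihood matches hand-enumerated values", {
  # 1 primary, 2 secondaries, p = 0.5, history (1,0), conditioned on
  # >= 1 capture: 0.25 / 0.75 = 1/3
  h <- make_hist(matrix(c(1L, 0L), 1), list(`2012` = c(11L, 12L)))
  sp <- rd_model_spec("none", "constant", "constant")
  expect_equal(as.numeric(rd_loglik(h, sp, list(S = 0.9, p = 0.5))),
               log(1 / 3), tolerance = 1e-12)
  # transition rows are probability distributions
  Tr <- photopop:::rd_trans(0.9, 0.1, 0.3)
  expect_equal(unname(Tr[1, ]), c(0.81, 0.09, 0.10))
  for (S in c(0.3, 0.93)) for (g in c(0.05, 0.4)) {
    expect_equal(rowSums(photopop:::rd_trans(S, g, g / 2)), rep(1, 3))
  }
  # out-of-range parameters are a domain error
  expect_error(rd_loglik(h, sp, list(S = 1.2, p = 0.5)), "\\[0, 1\\]")
})

test_that("forward recursion equals brute-force hidden-state enumeration", {
  months3 <- list(`2012` = c(11L, 12L, 1L), `2013` = c(11L, 12L, 1L),
                  `2014` = c(11L, 12L, 1L))
  sp <- rd_model_spec("markovian", "constant", "primary_by_secondary",
                      "constant")
  set.seed(99)
  for (rep in 1:6) {
    det <- matrix(rbinom(9L * 3L, 1L, 0.5), 3)
    det[rowSums(det) == 0, 1] <- 1L
    h <- make_hist(det, months3)
    S <- runif(1, 0.4, 0.95); gpp <- runif(1, 0, 0.4); gp <- runif(1, 0, 0.4)
    p <- runif(9, 0.1, 0.9)
    ll <- as.numeric(rd_loglik(h, sp, list(S = S, p = p,
                                           gamma_pp = gpp, gamma_p = gp)))
    expect_equal(ll, oracle_rd_loglik(det, h$cell_primary, S, p, gpp, gp),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to individual ordering", {
  months3 <- list(`2012` = c(11L, 12L), `2013` = c(11L, 12L),
                  `2014` = c(11L, 12L))
  set.seed(5)
  det <- matrix(rbinom(6L * 8L, 1L, 0.4), 8)
  det[rowSums(det) == 0, 1] <- 1L
  sp <- rd_model_spec("random", "constant", "primary_varying", "constant")
  pars <- list(S = 0.9, p = c(0.3, 0.5, 0.4), gamma = 0.1)
  ll1 <- as.numeric(rd_loglik(make_hist(det, months3), sp, pars))
  ll2 <- as.numeric(rd_loglik(make_hist(det[8:1, ], months3), sp, pars))
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("with no emigration and one primary the fit is the closed MLE", {
  set.seed(31)
  det <- matrix(rbinom(60L, 1L, 0.45), 20)
  det <- det[rowSums(det) > 0, , drop = FALSE]
  h <- make_hist(det, list(`2012` = c(11L, 12L, 1L)))
  sp <- rd_model_spec("none", "constant", "constant")
  f <- fit_rd(h, sp, n_starts = 2L, seed = 1)
  # grid-search the closed conditional likelihood in p
  grid <- seq(0.01, 0.99, by = 1e-4)
  ll <- vapply(grid, function(p) {
    as.numeric(rd_loglik(h, sp, list(S = 0.9, p = p)))
  }, numeric(1))
  expect_equal(coef_rd(f, "p"), grid[which.max(ll)], tolerance = 2e-4)
})

test_that("derived abundance follows N = n / p*", {
  # 10 individuals seen, two secondaries at p = 0.5: p* = 0.75, N = 13.33
  det <- cbind(rep(1L, 10), rep(0L, 10))
  h <- make_hist(det, list(`2012` = c(11L, 12L)))
  sp <- rd_model_spec("none", "constant", "constant")
  dims <- photopop:::rd_dims(h)
  theta <- stats::qlogis(c(0.9, 0.5))  # (S, p) on the working scale
  ab <- photopop:::rd_derived_abundance(h, theta, NULL, sp, dims)
  expect_equal(ab$pstar, 0.75)
  expect_equal(ab$N, 10 / 0.75, tolerance = 1e-12)
  expect_equal(ab$n_detected, 10L)
  # complete detection: N equals the count of distinct individuals
  ab2 <- photopop:::rd_derived_abundance(h, stats::qlogis(c(0.9, 1 - 1e-12)),
                                         NULL, sp, dims)
  expect_equal(ab2$N, 10, tolerance = 1e-6)
})

test_that("fit_rd recovers generating values without emigration", {
  months <- list(`2012` = c(11L, 12L, 1L), `2013` = c(11L, 12L, 1L),
                 `2014` = c(11L, 12L, 1L), `2015` = c(11L, 12L, 1L))
  h <- sim_hist_direct(n = 250, months, S = 0.85, gpp = 0, gp = 0,
                       p = 0.45, seed = 77)
  f <- fit_rd(h, rd_model_spec("none", "constant", "constant"),
              n_starts = 2L, seed = 3)
  expect_lt(abs(coef_rd(f, "S") - 0.85), 0.05)
  expect_lt(abs(coef_rd(f, "p") - 0.45), 0.04)
  # SEs and CIs are well-formed
  est <- f$estimates
  expect_true(all(est$lcl <= est$estimate & est$estimate <= est$ucl))
  expect_true(all(f$abundance$lcl <= f$abundance$N + 1e-8))
  expect_true(all(f$abundance$N >= f$abundance$n_detected))
})

test_that("model selection ranks by AIC and survives failing specs", {
  # AIC definition: logL = -100, K = 5 gives 210
  months <- list(`2012` = c(11L, 12L), `2013` = c(11L, 12L),
                 `2014` = c(11L, 12L), `2015` = c(11L, 12L))
  h <- sim_hist_direct(n = 150, months, S = 0.9, gpp = 0.25, gp = 0.25,
                       p = 0.5, seed = 41)
  specs <- list(rd_model_spec("none", "constant", "constant"),
                rd_model_spec("random", "constant", "constant"))
  ms <- model_selection(h, specs, n_starts = 2L, seed = 1, hessian = FALSE)
  expect_equal(ms$table$AIC, -2 * ms$table$logLik + 2 * ms$table$K)
  expect_true(!is.unsorted(ms$table$AIC))
  # strong random emigration: the emigration model should win
  expect_equal(ms$table$emigration[1], "random")
  # single spec is trivially ranked first
  ms1 <- model_selection(h, specs[2], n_starts = 2L, seed = 1,
                         hessian = FALSE)
  expect_equal(nrow(ms1$table), 1L)
  expect_equal(ms1$table$dAIC, 0)
})

test_that("the model-set builder crosses the enumerated structures", {
  specs <- rd_model_set()
  expect_length(specs, 8L + 16L + 16L)
  expect_length(rd_model_set(emigration = "random",
                             survival = "constant",
                             capture = "primary_by_secondary",
                             emigration_structure = "constant"), 1L)
})

test_that("closure diagnostic is null on saturated data and flags arrivals", {
  months1 <- list(`2012` = c(11L, 12L, 1L, 2L))
  # every individual captured in every secondary: statistic 0, p = 1
  h_sat <- make_hist(matrix(1L, 15, 4), months1)
  r <- closure_test(h_sat, 1L)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # mid-primary arrivals: half the animals only appear from occasion 3
  set.seed(8)
  early <- cbind(matrix(rbinom(40, 1, 0.6), 20), matrix(0L, 20, 2))
  late <- cbind(matrix(0L, 20, 2), matrix(rbinom(40, 1, 0.6), 20))
  h_arr <- make_hist(rbind(early, late)[rowSums(rbind(early, late)) > 0, ],
                     months1)
  r2 <- closure_test(h_arr, 1L)
  expect_lt(r2$p_value, 0.05)
  # all single captures: inconclusive
  h_one <- make_hist(diag(1L, 4)[, 1:4], months1)
  expect_true(closure_test(h_one, 1L)$inconclusive)
  expect_error(closure_test(make_hist(matrix(1L, 2, 2),
                                      list(`2012` = c(11L, 12L))), 1L),
               ">= 3 secondaries")
})

test_that("parametric-bootstrap GOF behaves on its own data", {
  months <- list(`2012` = c(11L, 12L, 1L), `2013` = c(11L, 12L, 1L),
                 `2014` = c(11L, 12L, 1L))
  h <- sim_hist_direct(n = 60, months, S = 0.9, gpp = 0, gp = 0, p = 0.5,
                       seed = 13)
  f <- fit_rd(h, rd_model_spec("none", "constant", "primary_varying"),
              n_starts = 1L, seed = 1, hessian = FALSE)
  expect_error(bootstrap_gof(f, replicates = 0L, seed = 1), "at least 1")
  g <- bootstrap_gof(f, replicates = 60L, seed = 2)
  expect_gte(g$p_value, 0)
  expect_lte(g$p_value, 1)
  expect_gte(g$n_successful, 50L)
  # data simulated from the fitted model itself should not be extreme
  expect_gt(g$p_value, 0.01)
})
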