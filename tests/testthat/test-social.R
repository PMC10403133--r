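# Group assignment, half-weight indices, clustering and network metrics.

test_that("groups split at photograph gaps greater than 15 minutes", {
  rec <- make_records(c("2019-01-05 10:00:00", "2019-01-05 10:10:00",
                        "2019-01-05 10:30:00"), id = c("A", "B", "C"))
  ga <- assign_groups(rec)
  expect_equal(nrow(ga$groups), 2L)   # 20-min gap opens a new group
  g1 <- ga$members$group_id[ga$members$individual_id %in% c("A", "B")]
  expect_equal(length(unique(g1)), 1L)
  # a gap of exactly 15 minutes stays in the same group (strict rule)
  ga2 <- assign_groups(make_records(c("2019-01-05 10:00:00",
                                      "2019-01-05 10:15:00"),
                                    id = c("A", "B")))
  expect_equal(nrow(ga2$groups), 1L)
  # single photo day: one singleton group
  ga3 <- assign_groups(make_records("2019-01-05 10:00:00"))
  expect_equal(ga3$groups$n_members, 1L)
  # an individual photographed twice in a group appears once
  ga4 <- assign_groups(make_records(c("2019-01-05 10:00:00",
                                      "2019-01-05 10:02:00"), id = "A"))
  expect_equal(nrow(ga4$members), 1L)
})

test_that("the sighting-frequency filter is strictly more-than-five", {
  days6 <- sprintf("2019-01-%02d 10:00:00", 1:6)
  rec <- rbind(make_records(days6, id = "A"),
               make_records(days6[1:5], id = "B"))
  ga <- assign_groups(rec)
  r <- restrict_individuals(ga, min_sightings = 6L)
  expect_setequal(unique(r$members$individual_id), "A")
  expect_warning(restrict_individuals(ga, min_sightings = 10L), "threshold")
  # year restriction drops out-of-range periods
  rec2 <- rbind(rec, make_records("2012-12-01 10:00:00", id = "B"))
  r2 <- restrict_individuals(assign_groups(rec2), min_sightings = 1L,
                             years = 2018:2021)
  expect_false(any(format(r2$members$date, "%Y") == "2012"))
})

test_that("half-weight indices match the printed formula and the oracle", {
  # X = 2, Ya = 3, Yb = 1: 2 / (2 + 2) = 0.5
  mk_day <- function(d, ...) {
    ids <- list(...)
    do.call(rbind, lapply(seq_along(ids), function(g) {
      data.frame(group_id = d * 100 + g, date = as.Date("2019-01-01") + d,
                 individual_id = ids[[g]], stringsAsFactors = FALSE)
    }))
  }
  m <- rbind(mk_day(1, c("a", "b")), mk_day(2, c("a", "b")),
             mk_day(3, "a"), mk_day(4, "a"), mk_day(5, "a"),
             mk_day(6, "b"))
  am <- half_weight_matrix(make_groups(m))
  expect_equal(am$X["a", "b"], 2L)
  expect_equal(am$Ya["a", "b"], 3L)
  expect_equal(am$Yb["a", "b"], 1L)
  expect_equal(am$hwi["a", "b"], 0.5)
  # never together -> 0; always together -> 1
  m2 <- rbind(mk_day(1, "a", "b"), mk_day(2, "a"), mk_day(3, "b"))
  expect_equal(half_weight_matrix(make_groups(m2))$hwi["a", "b"], 0)
  m3 <- rbind(mk_day(1, c("a", "b")), mk_day(2, c("a", "b")))
  expect_equal(half_weight_matrix(make_groups(m3))$hwi["a", "b"], 1)
  expect_error(half_weight_matrix(make_groups(mk_day(1, "a"))),
               "at least 2")

  # exhaustive-tally oracle on random small instances
  set.seed(21)
  for (rep in 1:5) {
    ids <- letters[1:5]
    rows <- list()
    for (d in 1:4) for (g in 1:2) {
      mem <- sample(ids, sample(0:3, 1))
      if (length(mem)) {
        rows[[length(rows) + 1L]] <-
          data.frame(group_id = d * 10 + g, date = as.Date("2019-02-01") + d,
                     individual_id = mem, stringsAsFactors = FALSE)
      }
    }
    m <- do.call(rbind, rows)
    if (length(unique(m$individual_id)) < 2) next
    am <- half_weight_matrix(make_groups(m))
    or <- oracle_hwi(m)
    expect_equal(am$hwi[rownames(or), colnames(or)], or, tolerance = 1e-12)
  }
})

test_that("multi-encounter days count once toward association", {
  # same pair in two groups on one day: X = 1, not 2
  m <- data.frame(group_id = c(1, 1, 2, 2),
                  date = as.Date("2019-01-05"),
                  individual_id = c("a", "b", "a", "b"),
                  stringsAsFactors = FALSE)
  m2 <- data.frame(group_id = c(3, 3), date = as.Date("2019-01-06"),
                   individual_id = c("a", "b"), stringsAsFactors = FALSE)
  am <- half_weight_matrix(make_groups(rbind(m, m2)))
  expect_equal(am$X["a", "b"], 2L)
  expect_equal(am$hwi["a", "b"], 1)
})

test_that("cophenetic validation and modularity follow their definitions", {
  # perfect two-block matrix is ultrametric: CCC = 1
  h <- matrix(0.1, 6, 6)
  h[1:3, 1:3] <- 0.8
  h[4:6, 4:6] <- 0.8
  diag(h) <- NA
  rownames(h) <- colnames(h) <- letters[1:6]
  cl <- cluster_analysis(h)
  expect_equal(unname(cl$ccc[cl$best_linkage]), 1, tolerance = 1e-12)
  expect_equal(cl$n_communities, 2L)
  expect_equal(length(unique(cl$membership[1:3])), 1L)
  expect_false(cl$membership[1] == cl$membership[4])
  # one-community division has Q = 0 by identity
  a <- h; diag(a) <- 0
  expect_equal(modularity_q(a, rep(1L, 6)), 0)
  # two disjoint unit-weight dyads cut apart: Q = 0.5
  d4 <- matrix(0, 4, 4)
  d4[1, 2] <- d4[2, 1] <- 1
  d4[3, 4] <- d4[4, 3] <- 1
  expect_equal(modularity_q(d4, c(1, 1, 2, 2)), 0.5)
  expect_error(cluster_analysis(h[1:2, 1:2]), "at least 3")
  # constant matrix: CCC undefined, reported not fatal
  hc <- matrix(0.4, 4, 4); diag(hc) <- NA
  expect_warning(cl2 <- cluster_analysis(hc), "constant")
  expect_true(all(is.na(cl2$ccc)))
})

test_that("network metrics evaluate the stated formulas", {
  h <- matrix(0.5, 3, 3); diag(h) <- 0
  rownames(h) <- colnames(h) <- c("a", "b", "c")
  nm <- network_metrics(h)
  expect_equal(nm$strength, rep(1, 3))
  expect_equal(nm$reach, rep(1, 3))
  expect_equal(nm$affinity, rep(1, 3))
  expect_equal(nm$clustering, rep(0.5, 3))
  # symmetric equal matrix: centralities equal with unit Euclidean norm
  expect_equal(nm$eigenvector, rep(1 / sqrt(3), 3), tolerance = 1e-9)
  # zero matrix: strengths 0, centrality undefined
  z <- matrix(0, 3, 3)
  nmz <- network_metrics(z)
  expect_equal(nmz$strength, rep(0, 3))
  expect_true(all(is.na(nmz$eigenvector)))
  expect_true(all(is.na(nmz$affinity)))
})

test_that("bootstrap SEs attach to every metric and respond to data", {
  set.seed(4)
  rows <- list()
  for (d in 1:12) {
    mem <- split(sample(letters[1:8]), rep(1:2, each = 4))
    for (g in 1:2) {
      rows[[length(rows) + 1L]] <-
        data.frame(group_id = d * 10 + g, date = as.Date("2019-03-01") + d,
                   individual_id = mem[[g]], stringsAsFactors = FALSE)
    }
  }
  ga <- make_groups(do.call(rbind, rows))
  am <- half_weight_matrix(ga)
  nm <- network_metrics(am, ga, replicates = 50L, seed = 9)
  expect_true(all(c("strength_se", "eigenvector_se", "reach_se",
                    "clustering_se", "affinity_se") %in% names(nm)))
  expect_true(all(nm$strength_se >= 0))
})
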