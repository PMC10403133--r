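# Independent oracles and fixture builders shared by the test files.

# Brute-force robust-design likelihood: enumerate every hidden-state
# sequence (in-area / emigrant / dead) from each individual's first-capture
# primary, conditional on >= 1 detection there. Deliberately slow and
# independent of the package's forward recursion.
oracle_rd_loglik <- function(det, cell_primary, S, p, gpp, gp) {
  Tn <- max(cell_primary)
  first <- apply(t(rowsum(t(det), cell_primary) > 0), 1L,
                 function(r) which(r)[1])
  total <- 0
  for (i in seq_len(nrow(det))) {
    f <- first[i]
    nlat <- Tn - f
    grid <- if (nlat > 0) as.matrix(expand.grid(rep(list(1:3), nlat))) else
      matrix(0, 1, 0)
    pr <- 0
    for (g in seq_len(nrow(grid))) {
      path <- c(1L, grid[g, ])
      pp <- 1
      for (tt in seq_len(nlat)) {
        Tr <- rbind(c(S * (1 - gpp), S * gpp, 1 - S),
                    c(S * (1 - gp), S * gp, 1 - S),
                    c(0, 0, 1))
        pp <- pp * Tr[path[tt], path[tt + 1L]]
      }
      for (tt in f:Tn) {
        st <- path[tt - f + 1L]
        cells <- which(cell_primary == tt)
        y <- det[i, cells]
        em <- if (st == 1L) prod(ifelse(y == 1, p[cells], 1 - p[cells])) else
          as.numeric(all(y == 0))
        pp <- pp * em
      }
      pr <- pr + pp
    }
    pstar <- 1 - prod(1 - p[cell_primary == f])
    total <- total + log(pr / pstar)
  }
  total
}

# Exhaustive half-weight tally by explicit loops over days and pairs.
oracle_hwi <- function(members) {
  ids <- sort(unique(members$individual_id))
  n <- length(ids)
  hwi <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  days <- unique(members$date)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    X <- Ya <- Yb <- 0
    for (d in days) {
      md <- members[members$date == d, ]
      ga <- md$group_id[md$individual_id == ids[a]]
      gb <- md$group_id[md$individual_id == ids[b]]
      together <- length(intersect(ga, gb)) > 0
      if (together) X <- X + 1
      else {
        if (length(ga)) Ya <- Ya + 1
        if (length(gb)) Yb <- Yb + 1
      }
    }
    den <- X + (Ya + Yb) / 2
    hwi[a, b] <- if (den > 0) X / den else 0
  }
  hwi
}

# Capture-history set built straight from a detection matrix (one row per
# individual) and a list of months per season-year.
make_hist <- function(det, months) {
  cal <- occasion_calendar(months)
  cells <- do.call(rbind, lapply(seq_along(cal$primaries), function(i) {
    p <- cal$primaries[[i]]
    data.frame(primary = i, season_year = p$season_year, month = p$month,
               cal_year = p$cal_year)
  }))
  stopifnot(ncol(det) == nrow(cells))
  dimnames(det) <- list(sprintf("i%03d", seq_len(nrow(det))),
                        paste0("Y", cells$season_year, "_",
                               sprintf("%02d", cells$month)))
  structure(list(individual_ids = rownames(det), det = det,
                 cell_primary = cells$primary, cell_month = cells$month,
                 cells = cells, calendar = cal),
            class = "capture_history_set")
}

# Simulate detection histories directly at the history level (fast path
# for fit-recovery tests; independent of the day-level generator).
sim_hist_direct <- function(n, months, S, gpp, gp, p, seed) {
  cal <- occasion_calendar(months)
  ks <- vapply(cal$primaries, nrow, integer(1))
  Tn <- length(ks)
  cp <- rep(seq_len(Tn), ks)
  C <- sum(ks)
  p <- rep_len(p, C)
  withr::with_seed(seed, {
    det <- matrix(0L, n, C)
    for (i in seq_len(n)) {
      st <- if (runif(1) < gpp / max(gpp + 1 - gp, 1e-12)) 2L else 1L
      for (t in seq_len(Tn)) {
        if (t > 1L) {
          if (st == 3L) next
          if (runif(1) > S) { st <- 3L; next }
          stay <- if (st == 1L) 1 - gpp else 1 - gp
          st <- if (runif(1) < stay) 1L else 2L
        }
        if (st == 1L) {
          cc <- which(cp == t)
          det[i, cc] <- rbinom(length(cc), 1L, p[cc])
        }
      }
    }
    det <- det[rowSums(det) > 0, , drop = FALSE]
    make_hist(det, months)
  })
}

# Minimal sighting-record data.frame builder.
make_records <- function(ts, id = "A", focus = 2L, contrast = 1L, angle = 1L,
                         partial = 1L, frame = 1L, dist = "D1",
                         age = "adult", mother = NA_character_) {
  n <- length(ts)
  ts <- as.POSIXct(ts, tz = "UTC")
  data.frame(image_id = sprintf("IMG%04d", seq_len(n)),
             timestamp = ts,
             individual_id = rep_len(id, n),
             side = "left",
             focus = rep_len(focus, n), contrast = rep_len(contrast, n),
             angle = rep_len(angle, n), partial = rep_len(partial, n),
             frame = rep_len(frame, n),
             distinctiveness = rep_len(dist, n),
             age_class = rep_len(age, n),
             mother_id = rep_len(mother, n),
             photographer = "ph", vessel = "v",
             latitude = NA_real_, longitude = NA_real_,
             date = as.Date(ts, tz = "UTC"),
             stringsAsFactors = FALSE)
}

# Group-assignment object built directly from a members table.
make_groups <- function(members) {
  members$date <- as.Date(members$date)
  structure(list(groups = photopop:::group_table(members), members = members),
            class = "group_assignment")
}

study_months <- function() {
  m <- lapply(2012:2021, function(y) {
    if (y == 2016) c(11L, 1L, 3L)
    else if (y == 2017) c(11L, 12L, 1L, 3L)
    else if (y == 2020) c(1L, 2L, 3L, 4L)
    else c(11L, 12L, 1L, 2L, 3L)
  })
  names(m) <- 2012:2021
  m
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "photopop")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", f)
  p
}
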