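# Synthetic photo-ID data generator: a marked dolphin population with
# constant adult survival, temporary emigration, session-varying capture
# probabilities realised through a day-level ecotour encounter process,
# preferred-companion social structure, and renewal calving -- plus the
# ground-truth tables against which the estimators are validated.

#' Simulation configuration
#'
#' Defaults mirror a decade-long ecotour photo-ID study of a small coastal
#' dolphin population: ten season-year primaries of (up to) five monthly
#' secondaries, a stationary marked adult pool of ~52 animals (kept
#' stationary by low-rate recruitment balancing mortality), apparent
#' survival 0.93 per year, random temporary emigration 0.09,
#' session capture probabilities drawn uniformly in 0.02--0.65, a
#' fission-fusion grouping process with a handful of preferred dyads, a
#' D1/D2/D3 fin-distinctiveness split of 36:51:4, and calving intervals
#' on 2--5 years with mean 3.7.
#'
#' @param ... named overrides of any default listed above (see the source
#'   for the full field list).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    years = 2012:2021,
    shifted_years = 2020L,              # season collected Jan-Apr instead
    n_initial = 52L,
    recruitment = TRUE,
    survival = 0.93,
    emigration = list(mode = "random", gamma = 0.09),
    p_range = c(0.02, 0.65),
    tour_days_per_month = 10L,
    encounters_per_day_mean = 2,
    join_prob = 0.15,
    n_preferred_dyads = 6L,
    preferred_join_prob = 0.9,
    dist_probs = c(D1 = 36, D2 = 51, D3 = 4) / 91,
    mother_fraction = 0.25,
    ibi_probs = c(`2` = 0.05, `3` = 0.30, `4` = 0.55, `5` = 0.10),
    newborn_obs_prob = 0.7,
    quality_probs = list(
      focus    = c(`2` = 0.35, `4` = 0.35, `9` = 0.30),
      contrast = c(`1` = 0.70, `3` = 0.30),
      angle    = c(`1` = 0.50, `2` = 0.30, `8` = 0.20),
      partial  = c(`1` = 0.80, `8` = 0.20),
      frame    = c(`1` = 0.40, `5` = 0.60)),
    poor_image_rate = 1.4,   # poor images per usable image (~58% poor overall)
    unidentified_image_prob = 0.1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$calendar <- default_calendar(cfg$years, cfg$shifted_years)
  stopifnot_prob(cfg$survival, "survival")
  stopifnot_prob(cfg$p_range, "p_range")
  stopifnot_prob(cfg$join_prob, "join_prob")
  stopifnot_prob(cfg$preferred_join_prob, "preferred_join_prob")
  if (abs(sum(cfg$dist_probs) - 1) > 1e-8) stop("dist_probs must sum to 1")
  if (abs(sum(cfg$ibi_probs) - 1) > 1e-8) stop("ibi_probs must sum to 1")
  if (cfg$emigration$mode == "none") {
    cfg$emigration$gamma_pp <- 0; cfg$emigration$gamma_p <- 0
  } else if (cfg$emigration$mode == "random") {
    stopifnot_prob(cfg$emigration$gamma, "gamma")
    cfg$emigration$gamma_pp <- cfg$emigration$gamma
    cfg$emigration$gamma_p <- cfg$emigration$gamma
  } else {
    stopifnot_prob(cfg$emigration$gamma_pp, "gamma_pp")
    stopifnot_prob(cfg$emigration$gamma_p, "gamma_p")
  }
  structure(cfg, class = "sim_config")
}

# stationary probability of being outside the study area
emigration_stationary_out <- function(em) {
  if (em$mode == "none") return(0)
  gpp <- em$gamma_pp; gp <- em$gamma_p
  denom <- gpp + (1 - gp)
  if (denom <= 0) return(0)
  gpp / denom
}

#' Simulate the latent population truth
#'
#' Draws each individual's latent state trajectory (in-area, temporary
#' emigrant, dead; dead absorbing) across primaries under the configured
#' survival and emigration probabilities, with recruits entering at a
#' Poisson rate balancing expected mortality so the marked adult pool is
#' stationary. Session capture probabilities are drawn per
#' primary-by-secondary cell. Births per mother follow a renewal process
#' with the configured interval distribution, anchored at each mother's
#' first calf.
#'
#' @param config a `sim_config`.
#' @param seed integer seed (required).
#' @return object of class `sim_truth`: `individuals`, `states` (N x T;
#'   0 = not yet recruited, 1 = in-area, 2 = emigrant, 3 = dead),
#'   `p_cells`, `births`, `config`.
#' @export
simulate_population <- function(config, seed) {
  Tn <- length(config$years)
  em <- config$emigration
  p_out <- emigration_stationary_out(em)
  S <- config$survival
  with_seed(seed, {
    draw_state <- function(n) ifelse(stats::runif(n) < p_out, 2L, 1L)
    states_rows <- list()
    entry <- integer(0)
    n0 <- config$n_initial
    states <- matrix(0L, n0, Tn)
    states[, 1L] <- draw_state(n0)
    entry <- rep(1L, n0)
    for (t in seq_len(Tn - 1L)) {
      # transitions for everyone already recruited
      for (i in seq_len(nrow(states))) {
        st <- states[i, t]
        if (st == 0L || st == 3L) { states[i, t + 1L] <- st; next }
        if (stats::runif(1) > S) { states[i, t + 1L] <- 3L; next }
        stay_prob <- if (st == 1L) 1 - em$gamma_pp else 1 - em$gamma_p
        states[i, t + 1L] <- if (stats::runif(1) < stay_prob) 1L else 2L
      }
      if (config$recruitment) {
        n_new <- stats::rpois(1L, config$n_initial * (1 - S))
        if (n_new > 0L) {
          add <- matrix(0L, n_new, Tn)
          add[, t + 1L] <- draw_state(n_new)
          states <- rbind(states, add)
          entry <- c(entry, rep(t + 1L, n_new))
        }
      }
    }
    N <- nrow(states)
    ids <- sprintf("D%03d", seq_len(N))
    rownames(states) <- ids
    individuals <- data.frame(
      id = ids,
      distinctiveness = sample(names(config$dist_probs), N, replace = TRUE,
                               prob = config$dist_probs),
      entry_primary = entry,
      is_mother = stats::runif(N) < config$mother_fraction,
      stringsAsFactors = FALSE)
    # preferred dyads among initial individuals
    dyads <- NULL
    if (config$n_preferred_dyads > 0L && n0 >= 2L * config$n_preferred_dyads) {
      picked <- sample.int(n0, 2L * config$n_preferred_dyads)
      dyads <- matrix(ids[picked], ncol = 2L, byrow = TRUE)
    }
    # session capture probabilities
    cells <- do.call(rbind, lapply(seq_along(config$calendar$primaries),
                                   function(i) {
      p <- config$calendar$primaries[[i]]
      data.frame(primary = i, season_year = p$season_year, month = p$month,
                 cal_year = p$cal_year)
    }))
    cells$p <- stats::runif(nrow(cells), config$p_range[1], config$p_range[2])
    # renewal calving anchored at the first calf
    births <- list()
    iv_vals <- as.integer(names(config$ibi_probs))
    for (i in which(individuals$is_mother)) {
      first_alive <- config$years[entry[i]]
      dead_at <- which(states[i, ] == 3L)
      last_alive <- if (length(dead_at)) config$years[min(dead_at) - 1L] else
        config$years[Tn]
      if (last_alive < first_alive) next
      # uniform phase offset so mothers' calving cycles are out of step
      yrs <- first_alive + sample.int(4L, 1L) - 1L
      if (yrs > last_alive) next
      while (TRUE) {
        nxt <- yrs[length(yrs)] +
          sample(iv_vals, 1L, prob = config$ibi_probs)
        if (nxt > last_alive) break
        yrs <- c(yrs, nxt)
      }
      births[[ids[i]]] <- data.frame(mother_id = ids[i], birth_year = yrs,
                                     stringsAsFactors = FALSE)
    }
    births <- if (length(births)) do.call(rbind, births) else
      data.frame(mother_id = character(0), birth_year = integer(0))
    rownames(births) <- NULL
    structure(list(individuals = individuals, states = states,
                   p_cells = cells, births = births, dyads = dyads,
                   config = config, seed = seed),
              class = "sim_truth")
  })
}

# batch rejection sampler for quality components
draw_quality <- function(n, qp, usable = TRUE) {
  draw1 <- function(k) {
    out <- matrix(0L, k, 5L,
                  dimnames = list(NULL, c("focus", "contrast", "angle",
                                          "partial", "frame")))
    for (comp in colnames(out)) {
      out[, comp] <- as.integer(sample(names(qp[[comp]]), k, replace = TRUE,
                                       prob = qp[[comp]]))
    }
    out
  }
  res <- draw1(n)
  for (round in seq_len(100L)) {
    tot <- rowSums(res)
    bad <- if (usable) tot > 12L else tot <= 12L
    if (!any(bad)) break
    res[bad, ] <- draw1(sum(bad))
  }
  tot <- rowSums(res)
  bad <- if (usable) tot > 12L else tot <= 12L
  if (any(bad)) {  # force the focus component if rejection stalls
    res[bad, "focus"] <- if (usable) 2L else 9L
    res[bad, "frame"] <- if (usable) 1L else 5L
  }
  res
}

#' Simulate sighting records from the latent truth
#'
#' Runs the day-level observation process: for each tour day within each
#' secondary month a Poisson number of dolphin groups is encountered; each
#' group forms around a uniformly chosen in-area seed individual which
#' others join independently (preferred dyad partners of the seed join
#' with elevated probability); each group member is photographed at a rate
#' calibrated so that, pooled over the month's tour days, the probability
#' of at least one usable image equals the cell's session capture
#' probability. Usable images draw quality components conditional on an
#' excellent/average total; additional poor and unidentified images are
#' generated for bookkeeping realism. Dependent calves are recorded
#' alongside their photographed mothers (newborn in the birth season,
#' older the following season).
#'
#' @param truth a `sim_truth`.
#' @param seed integer seed (required).
#' @return object of class `sim_sightings`: `records` (sighting-record
#'   data.frame), `calf_obs` (season_year, mother_id, calf_id,
#'   size_class), `groups` (true group compositions per day).
#' @export
simulate_sightings <- function(truth, seed) {
  config <- truth$config
  cells <- truth$p_cells
  states <- truth$states
  ids <- truth$individuals$id
  lambda <- config$encounters_per_day_mean
  Ddays <- config$tour_days_per_month
  partner <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(truth$dyads)) {
    partner[truth$dyads[, 1L]] <- truth$dyads[, 2L]
    partner[truth$dyads[, 2L]] <- truth$dyads[, 1L]
  }
  births <- truth$births
  with_seed(seed, {
    rec <- list(); calf <- list(); grp <- list()
    img <- 0L; gidx <- 0L
    emit_image <- function(who, tstamp, qc_row, ci) {
      img <<- img + 1L
      widx <- match(who, ids)
      rec[[img]] <<- data.frame(
        image_id = sprintf("IMG%06d", img),
        timestamp = tstamp,
        individual_id = if (is.na(widx)) NA_character_ else who,
        side = if (is.na(widx)) "unknown" else sample(c("left", "right"), 1L),
        focus = qc_row[["focus"]], contrast = qc_row[["contrast"]],
        angle = qc_row[["angle"]], partial = qc_row[["partial"]],
        frame = qc_row[["frame"]],
        distinctiveness = if (is.na(widx)) "unknown" else
          truth$individuals$distinctiveness[widx],
        age_class = "adult", mother_id = NA_character_,
        photographer = "sim", vessel = "tour1",
        latitude = -38.3 + stats::rnorm(1, 0, 0.02),
        longitude = 144.7 + stats::rnorm(1, 0, 0.02),
        stringsAsFactors = FALSE)
      # dependent calves recorded alongside their photographed mother
      if (!is.na(widx) && nrow(births) && truth$individuals$is_mother[widx]) {
        sy <- cells$season_year[ci]
        bys <- births$birth_year[births$mother_id == who]
        for (b in bys[bys == sy | bys == sy - 1L]) {
          calf[[length(calf) + 1L]] <<- data.frame(
            season_year = sy, mother_id = who,
            calf_id = paste0(who, "c", b),
            size_class = if (b == sy) "newborn" else "older",
            stringsAsFactors = FALSE)
        }
      }
    }
    for (ci in seq_len(nrow(cells))) {
      t <- cells$primary[ci]
      in_area <- ids[states[, t] == 1L]
      n_in <- length(in_area)
      if (n_in == 0L) next
      first <- as.Date(sprintf("%d-%02d-01", cells$cal_year[ci], cells$month[ci]))
      ndays <- as.integer(seq(first, by = "1 month", length.out = 2L)[2L] - first)
      days <- first + sort(sample.int(ndays, min(Ddays, ndays))) - 1L
      Deff <- length(days)
      # calibrate the per-encounter photo probability to the session p
      m <- 1 / n_in + (1 - 1 / n_in) * config$join_prob
      r_day <- 1 - (1 - cells$p[ci])^(1 / Deff)
      q_raw <- -log(max(1 - r_day, 1e-300)) / (lambda * m)
      q <- min(q_raw, 1)
      captured <- character(0)
      for (d in days) {
        d <- as.Date(d, origin = "1970-01-01")
        n_enc <- stats::rpois(1L, lambda)
        if (n_enc == 0L) next
        for (e in seq_len(n_enc)) {
          seed_id <- in_area[sample.int(n_in, 1L)]
          others <- setdiff(in_area, seed_id)
          pj <- ifelse(!is.na(partner[others]) & partner[others] == seed_id,
                       config$preferred_join_prob, config$join_prob)
          members <- c(seed_id, others[stats::runif(length(others)) < pj])
          # preferred companions follow their partner into the group
          stragglers <- setdiff(in_area, members)
          follow <- stragglers[!is.na(partner[stragglers]) &
                                 partner[stragglers] %in% members]
          if (length(follow)) {
            members <- c(members,
                         follow[stats::runif(length(follow)) <
                                  config$preferred_join_prob])
          }
          gidx <- gidx + 1L
          grp[[gidx]] <- data.frame(date = d, group_id = gidx,
                                    individual_id = members,
                                    stringsAsFactors = FALSE)
          t0 <- as.POSIXct(paste(d, "10:00:00"), tz = "UTC") + (e - 1L) * 2400
          photographed <- members[stats::runif(length(members)) < q]
          n_ph <- length(photographed)
          if (n_ph) {
            captured <- union(captured, photographed)
            qc <- draw_quality(n_ph, config$quality_probs, usable = TRUE)
            for (k in seq_len(n_ph)) {
              emit_image(photographed[k], t0 + stats::runif(1, 0, 600),
                         qc[k, ], ci)
            }
          }
          # extra poor (unidentifiable) images and unmarked animals
          n_poor <- if (n_ph) stats::rpois(1L, n_ph * config$poor_image_rate) else 0L
          if (n_poor) {
            qc <- draw_quality(n_poor, config$quality_probs, usable = FALSE)
            for (k in seq_len(n_poor)) {
              emit_image(NA_character_, t0 + stats::runif(1, 0, 600), qc[k, ], ci)
            }
          }
          if (n_ph && stats::runif(1) < config$unidentified_image_prob) {
            qc <- draw_quality(1L, config$quality_probs, usable = TRUE)
            emit_image(NA_character_, t0 + stats::runif(1, 0, 600), qc[1, ], ci)
          }
        }
      }
      # when the encounter process cannot reach the configured session p
      # (q capped at 1), top up with independent protocol photographs so
      # the pooled monthly detection probability stays exactly p
      if (q_raw > 1) {
        r_ach <- 1 - exp(-lambda * m * q)
        reach_month <- 1 - (1 - r_ach)^Deff
        p_extra <- 1 - (1 - cells$p[ci]) / max((1 - r_ach)^Deff, 1e-300)
        p_extra <- min(max(p_extra, 0), 1)
        if (p_extra > 0) {
          for (who in in_area[stats::runif(n_in) < p_extra]) {
            d <- as.Date(days[sample.int(Deff, 1L)], origin = "1970-01-01")
            gidx <- gidx + 1L
            grp[[gidx]] <- data.frame(date = d, group_id = gidx,
                                      individual_id = who,
                                      stringsAsFactors = FALSE)
            t0 <- as.POSIXct(paste(d, "16:00:00"), tz = "UTC")
            qc <- draw_quality(1L, config$quality_probs, usable = TRUE)
            emit_image(who, t0 + stats::runif(1, 0, 600), qc[1, ], ci)
          }
        }
      }
    }
    records <- if (length(rec)) do.call(rbind, rec) else
      data.frame(image_id = character(0))
    if (nrow(records)) records$date <- as.Date(records$timestamp, tz = "UTC")
    calf_obs <- if (length(calf)) unique(do.call(rbind, calf)) else
      data.frame(season_year = integer(0), mother_id = character(0),
                 calf_id = character(0), size_class = character(0))
    groups <- if (length(grp)) do.call(rbind, grp) else
      data.frame(date = as.Date(character(0)), group_id = integer(0),
                 individual_id = character(0))
    rownames(records) <- rownames(calf_obs) <- rownames(groups) <- NULL
    structure(list(records = records, calf_obs = calf_obs, groups = groups,
                   truth = truth, seed = seed),
              class = "sim_sightings")
  })
}

#' Simulate a renewal calving history for estimator validation
#'
#' Stand-alone calving simulator: each mother's first calf anchors a
#' renewal process whose intervals are drawn from `ibi_probs`; every birth
#' inside the year window is observed, classed newborn in its birth season
#' with probability `newborn_obs_prob` and otherwise recorded as an older
#' calf the following season (or newborn if the window ends first).
#'
#' @param n_mothers number of mothers (default 20).
#' @param years study year window (default 2012--2021).
#' @param ibi_probs named probability vector over integer intervals in
#'   years (default: support 2--5 with mean 3.7).
#' @param newborn_obs_prob probability a birth is recorded in its own
#'   season rather than backdated from the next (default 0.7).
#' @param seed integer seed (required).
#' @return calf-observation data.frame: `season_year`, `mother_id`,
#'   `calf_id`, `size_class`.
#' @export
simulate_calving <- function(n_mothers = 20L, years = 2012:2021,
                             ibi_probs = c(`2` = 0.05, `3` = 0.30,
                                           `4` = 0.55, `5` = 0.10),
                             newborn_obs_prob = 0.7, seed) {
  iv <- as.integer(names(ibi_probs))
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n_mothers)) {
      mid <- sprintf("M%02d", i)
      yrs <- years[1]
      while (TRUE) {
        nxt <- yrs[length(yrs)] + sample(iv, 1L, prob = ibi_probs)
        if (nxt > years[length(years)]) break
        yrs <- c(yrs, nxt)
      }
      for (b in yrs) {
        as_newborn <- stats::runif(1) < newborn_obs_prob ||
          b + 1L > years[length(years)]
        out[[length(out) + 1L]] <- data.frame(
          season_year = if (as_newborn) b else b + 1L,
          mother_id = mid, calf_id = paste0(mid, "c", b),
          size_class = if (as_newborn) "newborn" else "older",
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Generate a reproducible suite of replicate benchmark datasets
#'
#' @param config a `sim_config`.
#' @param replicates number of replicate datasets (>= 1).
#' @param seed master seed; per-replicate seeds are derived from it and
#'   recorded in the manifest.
#' @return list: `datasets` (each with `truth` and `sightings`) and
#'   `manifest` (replicate, seed, config fingerprint).
#' @export
make_benchmark_suite <- function(config, replicates, seed) {
  if (replicates < 1L) stop("`replicates` must be >= 1")
  seeds <- matrix(derive_seeds(seed, 2L * replicates), ncol = 2L)
  fp <- config_fingerprint(config)
  datasets <- lapply(seq_len(replicates), function(r) {
    truth <- simulate_population(config, seed = seeds[r, 1L])
    sightings <- simulate_sightings(truth, seed = seeds[r, 2L])
    list(truth = truth, sightings = sightings)
  })
  list(datasets = datasets,
       manifest = data.frame(replicate = seq_len(replicates),
                             seed_population = seeds[, 1L],
                             seed_sightings = seeds[, 2L],
                             config = fp))
}

# stable fingerprint of a config (md5 of its deparsed form)
config_fingerprint <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(unclass(config)))]), tf)
  unname(tools::md5sum(tf))
}
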