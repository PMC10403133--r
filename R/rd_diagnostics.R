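# Closure diagnostic and parametric-bootstrap goodness of fit.
#
# Both are self-contained substitutes for external diagnostic software: the
# closure check is a likelihood-ratio comparison against a staggered-
# availability alternative, and the GOF test is a parametric bootstrap of
# the fitted model's deviance. Reports label them as such.

#' Likelihood-ratio closure diagnostic for one primary occasion
#'
#' Within a primary the robust design assumes a closed population. This
#' diagnostic compares the closed model (every detected individual available
#' at all secondaries, time-varying capture probability) against a relaxed
#' alternative in which an individual may arrive before its first capture
#' (multinomial entry over secondaries) and depart after its last (per-
#' occasion departure hazards), both conditioned on at least one capture.
#' Twice the log-likelihood difference is referred to a chi-squared
#' distribution with 2(K-1) degrees of freedom (K secondaries).
#'
#' @param hist a `capture_history_set`.
#' @param primary primary-occasion index.
#' @return list: `statistic`, `df`, `p_value`, `n`, `inconclusive` flag.
#' @export
closure_test <- function(hist, primary) {
  cells <- which(hist$cell_primary == primary)
  K <- length(cells)
  if (K < 3L) stop("closure test requires >= 3 secondaries in the primary")
  y <- hist$det[, cells, drop = FALSE]
  y <- y[rowSums(y) > 0, , drop = FALSE]
  n <- nrow(y)
  out <- list(primary = primary, n = n, K = K, statistic = NA_real_,
              df = 2L * (K - 1L), p_value = NA_real_, inconclusive = FALSE)
  if (n == 0L) { out$inconclusive <- TRUE; return(out) }
  if (all(rowSums(y) == 1L)) {           # no recaptures: nothing to test
    out$inconclusive <- TRUE
    return(out)
  }
  first <- apply(y, 1L, function(r) which(r == 1L)[1])
  last <- apply(y, 1L, function(r) max(which(r == 1L)))

  ll_closed <- function(th) {
    p <- stats::plogis(th)
    pstar <- 1 - prod(1 - p)
    sum(y %*% log(p) + (1 - y) %*% log(1 - p)) - n * log(pstar)
  }
  fitC <- stats::optim(rep(0, K), function(th) -ll_closed(th), method = "BFGS",
                       control = list(maxit = 500L, reltol = 1e-10))

  # staggered availability: entry softmax pi_e, departure hazards delta_s
  ll_alt <- function(th) {
    p <- stats::plogis(th[seq_len(K)])
    ent <- th[K + seq_len(K)]
    pi_e <- exp(ent - max(ent)); pi_e <- pi_e / sum(pi_e)
    delta <- stats::plogis(th[2L * K + seq_len(K - 1L)])
    ret <- matrix(0, K, K)  # ret[e, d]: present exactly e..d
    for (e in seq_len(K)) for (d in e:K) {
      stay <- if (d > e) prod(1 - delta[e:(d - 1L)]) else 1
      ret[e, d] <- stay * if (d < K) delta[d] else 1
    }
    cap <- matrix(0, K, K)
    for (e in seq_len(K)) for (d in e:K) {
      cap[e, d] <- 1 - prod(1 - p[e:d])
    }
    denom <- sum(pi_e * ret * cap)
    if (denom <= 0) return(-Inf)
    ll <- 0
    for (i in seq_len(n)) {
      tot <- 0
      for (e in seq_len(first[i])) for (d in last[i]:K) {
        if (d < e) next
        obs <- prod(ifelse(y[i, e:d] == 1L, p[e:d], 1 - p[e:d]))
        tot <- tot + pi_e[e] * ret[e, d] * obs
      }
      ll <- ll + log(tot / denom)
    }
    ll
  }
  startA <- c(fitC$par, rep(0, K), rep(stats::qlogis(0.1), K - 1L))
  fitA <- stats::optim(startA, function(th) -ll_alt(th), method = "BFGS",
                       control = list(maxit = 1000L, reltol = 1e-10))
  stat <- max(0, 2 * (-fitA$value - (-fitC$value)))
  if (stat < 1e-8) stat <- 0
  out$statistic <- stat
  out$p_value <- stats::pchisq(stat, out$df, lower.tail = FALSE)
  out
}

#' Closure diagnostics for every primary with enough secondaries
#'
#' @param hist a `capture_history_set`.
#' @return data.frame with one row per testable primary.
#' @export
closure_test_all <- function(hist) {
  Tn <- n_primaries(hist)
  ks <- n_secondaries(hist$calendar)
  rows <- lapply(which(ks >= 3L), function(t) {
    r <- closure_test(hist, t)
    data.frame(primary = t, season_year = hist$calendar$years[t],
               n = r$n, statistic = r$statistic, df = r$df,
               p_value = r$p_value, inconclusive = r$inconclusive)
  })
  do.call(rbind, rows)
}

#' Parametric-bootstrap goodness of fit for a robust-design model
#'
#' Simulates replicate capture-history sets from the fitted model
#' (holding each individual's first-capture primary fixed and conditioning
#' on detection there, exactly as the likelihood does), refits the model to
#' each, and reports the proportion of simulated deviances at least as
#' large as the observed deviance.
#'
#' @param fit an `rd_fit`.
#' @param replicates number of bootstrap replicates (>= 50 must succeed).
#' @param seed integer seed.
#' @return list: `p_value`, `observed_deviance`, `simulated_deviances`.
#' @export
bootstrap_gof <- function(fit, replicates = 100L, seed = 1L) {
  if (replicates < 1L) stop("`replicates` must be at least 1")
  hist <- fit$hist
  dims <- fit$dims
  pars <- rd_expand(fit$theta, fit$spec, dims)
  obs_dev <- -2 * fit$loglik
  seeds <- derive_seeds(seed, replicates)
  devs <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    sim_hist <- with_seed(seeds[r], rd_simulate_from(hist, fit$first, pars))
    f <- tryCatch(fit_rd(sim_hist, fit$spec, n_starts = 1L, seed = seeds[r],
                         hessian = FALSE),
                  error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(f)) devs[r] <- -2 * f$loglik
  }
  ok <- !is.na(devs)
  if (sum(ok) < min(50L, replicates)) {
    stop("bootstrap_gof: only ", sum(ok), " of ", replicates,
         " replicates refit successfully")
  }
  list(p_value = mean(devs[ok] >= obs_dev),
       observed_deviance = obs_dev,
       simulated_deviances = devs[ok],
       n_successful = sum(ok))
}

# simulate one capture-history set from expanded RD parameters, holding
# first-capture primaries fixed
rd_simulate_from <- function(hist, first, pars) {
  det <- hist$det
  N <- nrow(det)
  Tn <- max(hist$cell_primary)
  new_det <- matrix(0L, N, ncol(det), dimnames = dimnames(det))
  for (i in seq_len(N)) {
    state <- 1L  # in-area at first capture
    for (t in first[i]:Tn) {
      cc <- which(hist$cell_primary == t)
      if (t > first[i]) {
        Tr <- rd_trans(pars$S[t - 1L], pars$gamma_pp[t - 1L], pars$gamma_p[t - 1L])
        state <- sample.int(3L, 1L, prob = Tr[state, ])
      }
      if (state == 1L) {
        y <- stats::rbinom(length(cc), 1L, pars$p[cc])
        if (t == first[i]) {
          tries <- 0L
          while (sum(y) == 0L && tries < 1000L) {
            y <- stats::rbinom(length(cc), 1L, pars$p[cc])
            tries <- tries + 1L
          }
          if (sum(y) == 0L) y[which.max(pars$p[cc])] <- 1L
        }
        new_det[i, cc] <- y
      }
    }
  }
  out <- hist
  out$det <- new_det
  out
}
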