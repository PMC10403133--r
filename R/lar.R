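# Lagged association rates with jackknife precision, and exponential
# decay-model selection for the temporal stability of associations.

#' Lagged association rates
#'
#' The lagged association rate g(tau) estimates the probability that two
#' individuals associated in one sampling period are associated again a
#' lag of tau days later. Over all ordered pairs of sampling periods whose
#' lag falls in a bin, and all ordered pairs of individuals,
#' g = sum A_ij(t1) A_ij(t2) / sum A_ij(t1) I_i(t2), where A_ij(t) = 1 if
#' i and j shared a group in period t and I_i(t) = 1 if i was identified
#' in period t. The null rate replaces A_ij(t2) in the numerator by the
#' chance expectation a_i(t2) / (n(t2) - 1) (a_i = number of associates of
#' i that period, n = number identified). Precision is a jackknife over
#' consecutive time blocks: SE = sqrt(((J-1)/J) sum (theta_j - theta_bar)^2).
#' Bins with a zero denominator are returned as NA.
#'
#' @param ga a `group_assignment` spanning >= 2 sampling periods.
#' @param bins numeric vector of lag-bin right edges in days (default:
#'   logarithmically spaced powers of two up to the maximum observed lag).
#' @param jackknife_block_days block length for the jackknife (default 30).
#' @return object of class `lar_curve`: data.frame `curve` with columns
#'   `lag_min`, `lag_max`, `lag_mid`, `g`, `null`, `se`, `n_pairs`.
#' @export
lagged_association_rates <- function(ga, bins = NULL,
                                     jackknife_block_days = 30) {
  da <- day_association(ga)
  nd <- length(da$dates)
  if (nd < 2L) stop("lagged association rates require >= 2 sampling periods")
  dnum <- as.numeric(da$dates)
  max_lag <- max(dnum) - min(dnum)
  if (is.null(bins)) {
    bins <- 2^(0:ceiling(log2(max(2, max_lag))))
    bins <- bins[bins <= max_lag * 2]
  }
  edges <- c(0, bins)
  # per-period associate counts and identified counts
  a_cnt <- t(vapply(da$together, rowSums, numeric(ncol(da$seen))))
  n_t <- rowSums(da$seen)
  # accumulate per date-pair contributions
  pair_rows <- list()
  k <- 0L
  for (t1 in seq_len(nd - 1L)) {
    A1 <- da$together[[t1]]
    if (!any(A1)) next
    a1 <- a_cnt[t1, ]
    for (t2 in (t1 + 1L):nd) {
      lag <- dnum[t2] - dnum[t1]
      bin <- findInterval(lag, edges, left.open = TRUE)
      if (bin < 1L || bin > length(bins)) next
      I2 <- da$seen[t2, ]
      den <- sum(a1 * I2)          # sum_ij A_ij(t1) I_i(t2), ordered pairs
      if (den == 0) next
      num <- sum(A1 & da$together[[t2]])
      chance <- ifelse(n_t[t2] > 1L, a_cnt[t2, ] / (n_t[t2] - 1L), 0)
      nul <- sum(a1 * I2 * chance)
      k <- k + 1L
      pair_rows[[k]] <- c(bin = bin, t1 = t1, t2 = t2,
                          num = num, den = den, nul = nul)
    }
  }
  if (!k) stop("no associated pairs at any lag")
  tab <- do.call(rbind, pair_rows)
  nb <- length(bins)
  agg <- function(rows) {
    g <- nullr <- rep(NA_real_, nb)
    for (b in seq_len(nb)) {
      sel <- rows[, "bin"] == b
      if (any(sel) && sum(rows[sel, "den"]) > 0) {
        g[b] <- sum(rows[sel, "num"]) / sum(rows[sel, "den"])
        nullr[b] <- sum(rows[sel, "nul"]) / sum(rows[sel, "den"])
      }
    }
    list(g = g, null = nullr)
  }
  full <- agg(tab)
  # jackknife over consecutive calendar blocks
  block_of_date <- floor((dnum - min(dnum)) / jackknife_block_days)
  blocks <- sort(unique(block_of_date))
  J <- length(blocks)
  se <- rep(NA_real_, nb)
  if (J > 1L) {
    theta <- matrix(NA_real_, J, nb)
    for (j in seq_len(J)) {
      drop_dates <- which(block_of_date == blocks[j])
      keep <- !(tab[, "t1"] %in% drop_dates | tab[, "t2"] %in% drop_dates)
      theta[j, ] <- agg(tab[keep, , drop = FALSE])$g
    }
    for (b in seq_len(nb)) {
      tj <- theta[, b]
      ok <- !is.na(tj)
      Jb <- sum(ok)
      if (Jb > 1L) {
        se[b] <- sqrt(((Jb - 1) / Jb) * sum((tj[ok] - mean(tj[ok]))^2))
      }
    }
  }
  n_pairs <- vapply(seq_len(nb), function(b) sum(tab[, "bin"] == b), numeric(1))
  curve <- data.frame(lag_min = edges[-length(edges)], lag_max = bins,
                      lag_mid = (edges[-length(edges)] + bins) / 2,
                      g = full$g, null = full$null, se = se,
                      n_pairs = n_pairs)
  structure(list(curve = curve, jackknife_blocks = J), class = "lar_curve")
}

#' @export
print.lar_curve <- function(x, ...) {
  cat("Lagged association rates (", sum(!is.na(x$curve$g)), " defined bins, ",
      x$jackknife_blocks, " jackknife blocks)\n", sep = "")
  print(format(x$curve, digits = 3), row.names = FALSE)
  invisible(x)
}

# the decay-model family: prediction functions of (params, tau)
lar_model_family <- function() {
  list(
    constant = list(
      npar = 1L, label = "rapid disassociations and preferred companions",
      init = function(g, tau) stats::qlogis(min(max(mean(g), 0.01), 0.99)),
      pred = function(th, tau) rep(stats::plogis(th[1]), length(tau))),
    exponential = list(
      npar = 2L, label = "rapid disassociations and casual acquaintances",
      init = function(g, tau) c(stats::qlogis(min(max(g[1], 0.01), 0.99)),
                                log(1 / max(tau) + 1e-4)),
      pred = function(th, tau) stats::plogis(th[1]) * exp(-exp(th[2]) * tau)),
    exp_plus_constant = list(
      npar = 3L, label = "preferred companions and casual acquaintances",
      init = function(g, tau) c(stats::qlogis(0.2),
                                log(1 / max(tau) + 1e-4),
                                stats::qlogis(min(max(min(g), 0.01), 0.99))),
      pred = function(th, tau) stats::plogis(th[3]) +
        stats::plogis(th[1]) * exp(-exp(th[2]) * tau)),
    double_exponential = list(
      npar = 4L, label = "two levels of casual acquaintances",
      init = function(g, tau) c(stats::qlogis(0.3), log(10 / max(tau)),
                                stats::qlogis(0.1), log(0.1 / max(tau))),
      pred = function(th, tau) stats::plogis(th[1]) * exp(-exp(th[2]) * tau) +
        stats::plogis(th[3]) * exp(-exp(th[4]) * tau))
  )
}

#' Fit and rank exponential decay models to a LAR curve
#'
#' The family covers a constant rate (associations persist at a plateau:
#' rapid disassociation followed by preferred companions when the plateau
#' is below 1), a pure exponential decay to zero (casual acquaintances),
#' exponential decay to a nonzero asymptote (preferred companions plus
#' casual acquaintances) and a double exponential (two timescales of
#' casual acquaintance). Fitting is weighted least squares with weights
#' 1/SE^2 (unit weights where the SE is unavailable); ranking is by AIC of
#' the Gaussian pseudo-likelihood of the weighted residuals. Models with
#' more parameters than defined bins are excluded with a warning.
#'
#' @param lar a `lar_curve` (or its `curve` data.frame) with >= 2 defined
#'   bins; >= 3 are needed for any non-constant model.
#' @return data.frame ranked by AIC: model, social interpretation, K,
#'   AIC, dAIC, RSS and fitted parameters (list column `pars`).
#' @export
fit_lar_models <- function(lar) {
  curve <- if (inherits(lar, "lar_curve")) lar$curve else lar
  ok <- !is.na(curve$g)
  tau <- curve$lag_mid[ok]
  g <- curve$g[ok]
  se <- curve$se[ok]
  nb <- length(g)
  if (nb < 2L) stop("at least 2 defined bins are required")
  w <- ifelse(is.na(se) | se <= 0, 1, 1 / se^2)
  fam <- lar_model_family()
  rows <- list()
  for (nm in names(fam)) {
    mod <- fam[[nm]]
    if (mod$npar >= nb) {
      warning(sprintf("model '%s' needs more bins (%d params, %d bins): skipped",
                      nm, mod$npar, nb))
      next
    }
    obj <- function(th) sum(w * (g - mod$pred(th, tau))^2)
    fit <- tryCatch(
      stats::optim(mod$init(g, tau), obj, method = "BFGS",
                   control = list(maxit = 2000L, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) {
      message(sprintf("LAR model '%s' did not converge: excluded", nm))
      next
    }
    rss <- fit$value
    K <- mod$npar + 1L  # + residual variance
    aic <- nb * log(max(rss, 1e-12) / nb) + 2 * K
    rows[[nm]] <- data.frame(model = nm, interpretation = mod$label,
                             K = mod$npar, AIC = aic, RSS = rss,
                             stringsAsFactors = FALSE)
    rows[[nm]]$pars <- list(fit$par)
    rows[[nm]]$fitted <- list(mod$pred(fit$par, tau))
  }
  if (!length(rows)) stop("no LAR model could be fitted")
  out <- do.call(rbind, rows)
  out <- out[order(out$AIC, out$K), , drop = FALSE]
  out$dAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}
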