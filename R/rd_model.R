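# Robust-design model structures and the hidden-state conditional likelihood.
#
# Latent demographic states between primaries: in-area, temporary emigrant,
# dead. Between consecutive primaries an in-area animal survives with
# probability S and, given survival, emigrates with probability gamma''
# (gamma_pp); an emigrant survives with S and stays out with gamma'
# (gamma_p). Dead is absorbing. Within a primary the population is closed:
# an in-area animal is detected in secondary s with probability p; an
# emigrant (or dead) animal yields an all-zero primary with certainty.
# Each individual's likelihood is conditional on its first capture: the
# first-capture primary contributes P(observed secondaries | in-area)
# divided by p* (the probability of >=1 detection in that primary), and
# the forward recursion starts from the in-area state there.

#' Specify a robust-design model structure
#'
#' @param emigration temporary-emigration scenario: `"none"` (both
#'   emigration probabilities fixed at 0), `"random"` (gamma'' = gamma',
#'   one shared vector) or `"markovian"` (two distinct vectors; gamma' of
#'   the first interval is tied to gamma'' there, where it is not
#'   identifiable).
#' @param survival `"constant"` or `"primary_varying"` apparent survival.
#' @param capture capture-probability structure: `"constant"`,
#'   `"primary_varying"` (one per primary), `"secondary_varying"` (one per
#'   within-season month position, shared across primaries) or
#'   `"primary_by_secondary"` (one per cell).
#' @param emigration_structure `"constant"` or `"primary_varying"`.
#' @return an object of class `rd_model_spec`.
#' @export
rd_model_spec <- function(emigration = c("random", "none", "markovian"),
                          survival = c("constant", "primary_varying"),
                          capture = c("primary_by_secondary", "constant",
                                      "primary_varying", "secondary_varying"),
                          emigration_structure = c("constant", "primary_varying")) {
  structure(list(emigration = match.arg(emigration),
                 survival = match.arg(survival),
                 capture = match.arg(capture),
                 emigration_structure = match.arg(emigration_structure)),
            class = "rd_model_spec")
}

#' @export
print.rd_model_spec <- function(x, ...) {
  cat(sprintf("RD model: emigration=%s(%s), S=%s, p=%s\n", x$emigration,
              if (x$emigration == "none") "-" else x$emigration_structure,
              x$survival, x$capture))
  invisible(x)
}

#' Enumerate a cross-product robust-design model set
#'
#' All combinations of the enumerated emigration scenarios, survival,
#' capture and emigration time structures (the emigration structure is
#' dropped for the no-emigration scenario). The set can be extended or
#' restricted by subsetting the returned list.
#'
#' @param emigration,survival,capture,emigration_structure character vectors
#'   of structure levels to cross.
#' @return list of `rd_model_spec`.
#' @export
rd_model_set <- function(emigration = c("none", "random", "markovian"),
                         survival = c("constant", "primary_varying"),
                         capture = c("constant", "primary_varying",
                                     "secondary_varying", "primary_by_secondary"),
                         emigration_structure = c("constant", "primary_varying")) {
  specs <- list()
  for (e in emigration) for (s in survival) for (p in capture) {
    es_levels <- if (e == "none") "constant" else emigration_structure
    for (es in es_levels) {
      specs[[length(specs) + 1L]] <- rd_model_spec(e, s, p, es)
    }
  }
  specs
}

# --- parameter packing ------------------------------------------------------

rd_dims <- function(hist) {
  Tn <- n_primaries(hist)
  ks <- n_secondaries(hist$calendar)
  # position of each cell within its primary (for secondary_varying)
  pos <- unlist(lapply(ks, seq_len))
  list(T = Tn, K = ks, C = length(hist$cell_primary),
       cell_primary = hist$cell_primary, cell_pos = pos)
}

# slot sizes for the working-parameter vector, in packing order
# (S, p, gamma_pp, gamma_p)
rd_param_slots <- function(spec, dims) {
  nS <- if (spec$survival == "constant") 1L else dims$T - 1L
  nP <- switch(spec$capture,
               constant = 1L,
               primary_varying = dims$T,
               secondary_varying = max(dims$K),
               primary_by_secondary = dims$C)
  if (spec$emigration == "none") {
    nGpp <- 0L; nGp <- 0L
  } else {
    nGpp <- if (spec$emigration_structure == "constant") 1L else dims$T - 1L
    nGp <- if (spec$emigration == "random") 0L
           else if (spec$emigration_structure == "constant") 1L
           else dims$T - 2L  # first-interval gamma' tied to gamma''
  }
  c(S = nS, p = nP, gamma_pp = nGpp, gamma_p = nGp)
}

# expand a working-scale vector theta (logit probabilities) to per-interval
# S, per-cell p, per-interval gamma'' and gamma'
rd_expand <- function(theta, spec, dims) {
  slots <- rd_param_slots(spec, dims)
  stopifnot(length(theta) == sum(slots))
  parts <- split(theta, rep(seq_along(slots), slots))
  names(parts) <- names(slots)[slots > 0]
  pr <- lapply(parts, stats::plogis)
  nI <- dims$T - 1L
  S_t <- if (spec$survival == "constant") rep(pr$S, nI) else pr$S
  p_c <- switch(spec$capture,
                constant = rep(pr$p, dims$C),
                primary_varying = pr$p[dims$cell_primary],
                secondary_varying = pr$p[dims$cell_pos],
                primary_by_secondary = pr$p)
  if (spec$emigration == "none") {
    gpp_t <- rep(0, nI); gp_t <- rep(0, nI)
  } else {
    gpp_t <- if (length(pr$gamma_pp) == 1L) rep(pr$gamma_pp, nI) else pr$gamma_pp
    gp_t <- if (spec$emigration == "random") {
      gpp_t
    } else if (is.null(pr$gamma_p)) {       # primary_varying with T == 2
      gpp_t
    } else if (length(parts$gamma_p) == 1L && spec$emigration_structure == "constant") {
      rep(pr$gamma_p, nI)
    } else {
      c(gpp_t[1L], pr$gamma_p)              # tie first interval to gamma''
    }
  }
  list(S = S_t, p = p_c, gamma_pp = gpp_t, gamma_p = gp_t)
}

# --- likelihood -------------------------------------------------------------

# per-individual-per-primary emission probabilities given in-area, the
# all-zero indicator and per-primary p*
rd_emissions <- function(det, cell_primary, p) {
  Tn <- max(cell_primary)
  Z <- outer(cell_primary, seq_len(Tn), `==`) * 1
  if (all(p > 0 & p < 1)) {
    u <- log(p) - log1p(-p)
    base <- as.vector(log1p(-p) %*% Z)
    logem <- det %*% (u * Z) + matrix(base, nrow(det), Tn, byrow = TRUE)
    em_in <- exp(logem)
  } else {
    if (any(p < 0 | p > 1)) stop("capture probabilities must lie in [0, 1]")
    em_in <- matrix(1, nrow(det), Tn)
    for (t in seq_len(Tn)) {
      cc <- which(cell_primary == t)
      for (c0 in cc) {
        em_in[, t] <- em_in[, t] * ifelse(det[, c0] == 1L, p[c0], 1 - p[c0])
      }
    }
  }
  pstar <- vapply(seq_len(Tn), function(t) {
    1 - prod(1 - p[cell_primary == t])
  }, numeric(1))
  allzero <- t(rowsum(t(det), cell_primary) == 0) * 1
  list(em_in = em_in, allzero = allzero, pstar = pstar)
}

rd_trans <- function(S, gpp, gp) {
  rbind(c(S * (1 - gpp), S * gpp, 1 - S),
        c(S * (1 - gp),  S * gp,  1 - S),
        c(0, 0, 1))
}

# core forward recursion; pars as returned by rd_expand
rd_loglik_core <- function(det, cell_primary, first, pars,
                           per_individual = FALSE) {
  N <- nrow(det)
  Tn <- max(cell_primary)
  em <- rd_emissions(det, cell_primary, pars$p)
  alpha <- matrix(0, N, 3L)
  for (t in seq_len(Tn)) {
    if (t > 1L) {
      Tr <- rd_trans(pars$S[t - 1L], pars$gamma_pp[t - 1L], pars$gamma_p[t - 1L])
      alpha <- alpha %*% Tr
      alpha[, 1L] <- alpha[, 1L] * em$em_in[, t]
      alpha[, 2L] <- alpha[, 2L] * em$allzero[, t]
      alpha[, 3L] <- alpha[, 3L] * em$allzero[, t]
    }
    nw <- first == t
    if (any(nw)) {
      alpha[nw, 1L] <- em$em_in[nw, t] / em$pstar[t]
      alpha[nw, 2L] <- 0
      alpha[nw, 3L] <- 0
    }
  }
  li <- rowSums(alpha)
  if (per_individual) log(li) else sum(log(li))
}

#' Robust-design conditional log-likelihood
#'
#' Sum over individuals of the log of a hidden-state (in-area / temporary
#' emigrant / dead) forward recursion, conditional on first capture. See
#' the file header for the exact transition and emission structure; the
#' first-capture primary contributes its secondaries' detection pattern
#' divided by the probability of at least one detection in that primary.
#'
#' @param hist a `capture_history_set`.
#' @param spec an `rd_model_spec`.
#' @param params named list of probability-scale parameters matching the
#'   spec's structures: `S` (length 1 or T-1), `p` (length 1, T, max
#'   secondaries, or number of cells), and `gamma` (random emigration) or
#'   `gamma_pp`/`gamma_p` (Markovian).
#' @return the log-likelihood (scalar); per-individual values in attribute
#'   `"per_individual"`.
#' @export
rd_loglik <- function(hist, spec, params) {
  if (nrow(hist$det) == 0L) stop("at least one individual is required")
  dims <- rd_dims(hist)
  pars <- rd_params_natural(params, spec, dims)
  first <- first_capture_primary(hist)
  ll_i <- rd_loglik_core(hist$det, dims$cell_primary, first, pars,
                         per_individual = TRUE)
  structure(sum(ll_i), per_individual = ll_i)
}

# validate and expand natural-scale parameter lists
rd_params_natural <- function(params, spec, dims) {
  nI <- dims$T - 1L
  rep_to <- function(x, n, nm) {
    stopifnot_prob(x, nm)
    if (length(x) == 1L) rep(x, n)
    else if (length(x) == n) x
    else stop(sprintf("`%s` must have length 1 or %d", nm, n))
  }
  S_t <- rep_to(params$S, max(nI, 1L), "S")
  p_c <- switch(spec$capture,
    constant = rep_to(params$p, 1L, "p") |> rep(dims$C),
    primary_varying = rep_to(params$p, dims$T, "p")[dims$cell_primary],
    secondary_varying = rep_to(params$p, max(dims$K), "p")[dims$cell_pos],
    primary_by_secondary = rep_to(params$p, dims$C, "p"))
  if (spec$emigration == "none") {
    gpp <- rep(0, max(nI, 1L)); gp <- gpp
  } else if (spec$emigration == "random") {
    g <- params$gamma %||% params$gamma_pp
    gpp <- rep_to(g, max(nI, 1L), "gamma"); gp <- gpp
  } else {
    gpp <- rep_to(params$gamma_pp, max(nI, 1L), "gamma_pp")
    gp <- rep_to(params$gamma_p, max(nI, 1L), "gamma_p")
    if (length(params$gamma_p) > 1L) gp[1L] <- gpp[1L]  # first-interval tie
  }
  list(S = S_t, p = p_c, gamma_pp = gpp, gamma_p = gp)
}
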