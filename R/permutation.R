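# Monte Carlo permutation test for preferred/avoided companions:
# Markov-chain checkerboard swaps of the group x individual incidence
# matrix, restricted to pairs of groups within the same sampling period,
# preserving all group sizes and individual sighting frequencies.

# build the group x individual incidence matrix and group->period index
incidence_matrix <- function(ga, ids = NULL) {
  m <- ga$members
  ids <- ids %||% sort(unique(m$individual_id))
  gids <- sort(unique(m$group_id))
  M <- matrix(0L, length(gids), length(ids),
              dimnames = list(gids, ids))
  M[cbind(match(m$group_id, gids), match(m$individual_id, ids))] <- 1L
  period <- as.character(m$date[match(gids, m$group_id)])
  list(M = M, period = period, ids = ids, gids = gids)
}

# one batch of attempted checkerboard swaps (in place semantics via return)
swap_batch <- function(M, rows_by_period, n_flips) {
  eligible <- rows_by_period[lengths(rows_by_period) >= 2L]
  if (!length(eligible)) return(list(M = M, swaps = 0L))
  swaps <- 0L
  nC <- ncol(M)
  for (k in seq_len(n_flips)) {
    per <- eligible[[sample.int(length(eligible), 1L)]]
    rs <- per[sample.int(length(per), 2L)]
    cs <- sample.int(nC, 2L)
    a <- M[rs[1L], cs[1L]]; b <- M[rs[1L], cs[2L]]
    c_ <- M[rs[2L], cs[1L]]; d <- M[rs[2L], cs[2L]]
    # checkerboard: 1 0 / 0 1  or  0 1 / 1 0
    if (a + d == 2L && b + c_ == 0L) {
      M[rs[1L], cs[1L]] <- 0L; M[rs[2L], cs[2L]] <- 0L
      M[rs[1L], cs[2L]] <- 1L; M[rs[2L], cs[1L]] <- 1L
      swaps <- swaps + 1L
    } else if (a + d == 0L && b + c_ == 2L) {
      M[rs[1L], cs[1L]] <- 1L; M[rs[2L], cs[2L]] <- 1L
      M[rs[1L], cs[2L]] <- 0L; M[rs[2L], cs[1L]] <- 0L
      swaps <- swaps + 1L
    }
  }
  list(M = M, swaps = swaps)
}

# HWI off-diagonal statistics from an incidence matrix with daily collapsing
hwi_stats_from_incidence <- function(M, period) {
  hwi <- hwi_from_incidence(M, period)
  v <- hwi[upper.tri(hwi)]
  m <- mean(v)
  c(mean = m, sd = stats::sd(v), cv = if (m > 0) stats::sd(v) / m else NA_real_)
}

#' Permutation test for preferred and avoided companions
#'
#' Sequential Markov-chain swaps of 2x2 checkerboard submatrices of the
#' group x individual incidence matrix, restricted to group pairs within
#' the same sampling period (calendar day), preserve every group size and
#' every individual's sighting frequency. After a burn-in, each permuted
#' matrix is separated from the previous by `flips` attempted swaps, and
#' the half-weight index mean/SD/CV are recomputed. Permutations run in
#' batches (default 1000) up to `max_permutations`, stopping early once
#' both p-values move by less than 0.01 between batches. A significantly
#' high SD signals long-term preferred companions; a significantly low
#' mean signals short-term preferences.
#'
#' @param ga a `group_assignment`.
#' @param max_permutations maximum number of permuted matrices (default 4000).
#' @param batch batch size between convergence checks (default 1000).
#' @param flips attempted swaps between consecutive permuted matrices
#'   (default 100).
#' @param burn_in attempted swaps before the first permuted matrix
#'   (default 1000).
#' @param seed integer seed (required).
#' @return object of class `permutation_result`: observed statistics,
#'   permuted distributions, one-sided p-values `p_high_sd` and
#'   `p_low_mean`, and the number of permutations used.
#' @export
permutation_test <- function(ga, max_permutations = 4000L, batch = 1000L,
                             flips = 100L, burn_in = 1000L, seed) {
  inc <- incidence_matrix(ga)
  M <- inc$M
  rows_by_period <- split(seq_len(nrow(M)), inc$period)
  obs <- hwi_stats_from_incidence(M, inc$period)
  row0 <- rowSums(M); col0 <- colSums(M)

  perm_stats <- matrix(NA_real_, 0L, 3L)
  p_prev <- c(NA_real_, NA_real_)
  used <- 0L
  degenerate <- FALSE
  with_seed(seed, {
    bb <- swap_batch(M, rows_by_period, burn_in)
    M <- bb$M
    if (bb$swaps == 0L) degenerate <- TRUE
    total_swaps <- bb$swaps
    while (used < max_permutations) {
      nb <- min(batch, max_permutations - used)
      stats_b <- matrix(NA_real_, nb, 3L)
      for (k in seq_len(nb)) {
        sb <- swap_batch(M, rows_by_period, flips)
        M <- sb$M
        total_swaps <- total_swaps + sb$swaps
        stats_b[k, ] <- hwi_stats_from_incidence(M, inc$period)
      }
      # margin invariants, asserted every batch
      stopifnot(identical(rowSums(M), row0), identical(colSums(M), col0))
      perm_stats <- rbind(perm_stats, stats_b)
      used <- used + nb
      p_hi <- (sum(perm_stats[, 2L] >= obs["sd"]) + 1) / (used + 1)
      p_lo <- (sum(perm_stats[, 1L] <= obs["mean"]) + 1) / (used + 1)
      if (!any(is.na(p_prev)) &&
          abs(p_hi - p_prev[1L]) < 0.01 && abs(p_lo - p_prev[2L]) < 0.01) {
        p_prev <- c(p_hi, p_lo)
        break
      }
      p_prev <- c(p_hi, p_lo)
    }
    if (total_swaps == 0L) degenerate <- TRUE
  })
  colnames(perm_stats) <- c("mean", "sd", "cv")
  if (degenerate) {
    warning("no swappable checkerboard submatrix: permutation distribution is degenerate")
    p_prev <- c(1, 1)
  }
  structure(list(observed = obs, permuted = perm_stats,
                 p_high_sd = p_prev[1L], p_low_mean = p_prev[2L],
                 n_permutations = used, degenerate = degenerate),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations%s)\n", x$n_permutations,
              if (x$degenerate) ", degenerate" else ""))
  cat(sprintf("  observed mean %.4f sd %.4f cv %.4f\n", x$observed["mean"],
              x$observed["sd"], x$observed["cv"]))
  if (nrow(x$permuted)) {
    cat(sprintf("  permuted mean %.4f sd %.4f\n", mean(x$permuted[, "mean"]),
                mean(x$permuted[, "sd"])))
  }
  cat(sprintf("  P(high SD, long-term preference) = %.4f\n", x$p_high_sd))
  cat(sprintf("  P(low mean, short-term preference) = %.4f\n", x$p_low_mean))
  invisible(x)
}
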