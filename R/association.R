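# Half-weight association indices at daily sampling-period granularity.

# per-day association summaries used by the HWI tally, the permutation
# engine and the lagged association rates:
#   seen[d, i]     -- individual i identified on day d
#   together[[d]]  -- i and j shared >= 1 group on day d (n x n logical)
day_association <- function(ga, ids = NULL) {
  m <- ga$members
  ids <- ids %||% sort(unique(m$individual_id))
  dates <- sort(unique(m$date))
  n <- length(ids)
  seen <- matrix(FALSE, length(dates), n, dimnames = list(as.character(dates), ids))
  together <- vector("list", length(dates))
  for (d in seq_along(dates)) {
    md <- m[m$date == dates[d], , drop = FALSE]
    tog <- matrix(FALSE, n, n)
    for (g in unique(md$group_id)) {
      idx <- match(unique(md$individual_id[md$group_id == g]), ids)
      idx <- idx[!is.na(idx)]
      if (length(idx)) seen[d, idx] <- TRUE
      if (length(idx) > 1L) tog[idx, idx] <- TRUE
    }
    diag(tog) <- FALSE
    together[[d]] <- tog
  }
  list(ids = ids, dates = dates, seen = seen, together = together)
}

#' Half-weight association matrix
#'
#' Tallies, for every pair of individuals and at daily sampling-period
#' granularity, the number of days on which the pair shared at least one
#' group (X) and the number of days on which each was identified without
#' being associated with the other (Ya, Yb), then forms the half-weight
#' index HWI = X / (X + (Ya + Yb) / 2). Sharing several groups on one day
#' counts as a single associated day, so multi-encounter days are not
#' double counted. Pairs whose denominator is zero (neither ever seen) get
#' index 0 and are flagged in `undefined`.
#'
#' @param ga a `group_assignment` with at least two identified individuals.
#' @return object of class `assoc_matrix`: list with `ids`, `X`, `Ya`,
#'   `Yb`, `hwi` (symmetric, diagonal NA), `undefined` flags and `n_days`
#'   seen per individual.
#' @export
half_weight_matrix <- function(ga) {
  da <- day_association(ga)
  n <- length(da$ids)
  if (n < 2L) stop("half_weight_matrix requires at least 2 individuals")
  X <- matrix(0L, n, n, dimnames = list(da$ids, da$ids))
  Yonly <- matrix(0L, n, n, dimnames = list(da$ids, da$ids))  # Yonly[a,b]: days a seen, not with b
  for (d in seq_along(da$dates)) {
    tog <- da$together[[d]]
    sn <- da$seen[d, ]
    X <- X + tog
    Yonly <- Yonly + (sn & !tog)  # row a: a seen that day and not associated with b
  }
  denom <- X + (Yonly + t(Yonly)) / 2
  hwi <- ifelse(denom > 0, X / denom, 0)
  undefined <- denom == 0
  diag(hwi) <- NA_real_
  diag(undefined) <- NA
  structure(list(ids = da$ids, X = X, Ya = Yonly, Yb = t(Yonly), hwi = hwi,
                 undefined = undefined, n_days = colSums(da$seen)),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  v <- x$hwi[upper.tri(x$hwi)]
  cat(sprintf("HWI matrix: %d individuals; mean %.3f, SD %.3f, max %.3f\n",
              length(x$ids), mean(v), stats::sd(v), max(v)))
  invisible(x)
}

#' Summary statistics of an association matrix
#'
#' Mean, standard deviation and coefficient of variation of the
#' off-diagonal half-weight indices (each pair counted once).
#'
#' @param assoc an `assoc_matrix` (or plain symmetric matrix).
#' @return named numeric vector: mean, sd, cv.
#' @export
assoc_stats <- function(assoc) {
  h <- if (inherits(assoc, "assoc_matrix")) assoc$hwi else assoc
  v <- h[upper.tri(h)]
  m <- mean(v)
  s <- stats::sd(v)
  c(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_)
}

#' Export an association matrix as square CSV
#'
#' @param assoc an `assoc_matrix`.
#' @param path output path (id header row and column).
#' @export
write_assoc_csv <- function(assoc, path) {
  h <- assoc$hwi
  diag(h) <- 1
  utils::write.csv(data.frame(id = assoc$ids, h, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
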