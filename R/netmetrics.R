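# Individual-level weighted network statistics with bootstrap precision.

# metrics from a plain HWI matrix; returns a data.frame
network_metrics_once <- function(h) {
  diag(h) <- 0
  n <- nrow(h)
  strength <- rowSums(h)
  # eigenvector centrality by power iteration, nonnegative, unit 2-norm
  cent <- rep(NA_real_, n)
  if (any(h > 0)) {
    v <- rep(1 / sqrt(n), n)
    for (it in seq_len(10000L)) {
      w <- as.vector(h %*% v)
      nw <- sqrt(sum(w^2))
      if (nw == 0) { v <- rep(NA_real_, n); break }
      w <- w / nw
      if (max(abs(w - v)) < 1e-10) { v <- w; break }
      v <- w
    }
    cent <- abs(v)
  }
  reach <- as.vector(h %*% strength)
  num <- diag(h %*% h %*% h)
  den <- strength^2 - rowSums(h^2)
  clustering <- ifelse(den > 0, num / den, NA_real_)
  affinity <- ifelse(strength > 0, reach / strength, NA_real_)
  data.frame(id = rownames(h) %||% as.character(seq_len(n)),
             strength = strength, eigenvector = cent, reach = reach,
             clustering = clustering, affinity = affinity,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Individual network statistics with bootstrap standard errors
#'
#' For each individual: strength (sum of its half-weight indices),
#' eigenvector centrality (principal eigenvector of the HWI matrix,
#' nonnegative, unit Euclidean norm), reach (sum of associates' strengths
#' weighted by the index), weighted clustering coefficient
#' (sum_jk a_ij a_jk a_ki / sum_jk a_ij a_ki over distinct j, k) and
#' affinity (reach / strength). Standard errors are obtained by resampling
#' groups with replacement and recomputing the association matrix and
#' metrics. Isolated individuals get undefined clustering and affinity.
#'
#' @param assoc an `assoc_matrix`.
#' @param ga the `group_assignment` the matrix was built from (needed for
#'   the bootstrap; omit to skip SEs).
#' @param replicates bootstrap replicates (default 1000).
#' @param seed integer seed (required when bootstrapping).
#' @return data.frame of metrics, with `<metric>_se` columns when
#'   bootstrapped.
#' @export
network_metrics <- function(assoc, ga = NULL, replicates = 1000L, seed = NULL) {
  h <- if (inherits(assoc, "assoc_matrix")) assoc$hwi else as.matrix(assoc)
  out <- network_metrics_once(h)
  if (is.null(ga) || replicates < 1L) return(out)
  inc <- incidence_matrix(ga, ids = rownames(h))
  G <- nrow(inc$M)
  metr <- c("strength", "eigenvector", "reach", "clustering", "affinity")
  acc <- array(NA_real_, c(replicates, nrow(out), length(metr)))
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      take <- sample.int(G, G, replace = TRUE)
      Mb <- inc$M[take, , drop = FALSE]
      st <- hwi_from_incidence(Mb, inc$period[take])
      mb <- network_metrics_once(st)
      for (j in seq_along(metr)) acc[r, , j] <- mb[[metr[j]]]
    }
  })
  for (j in seq_along(metr)) {
    out[[paste0(metr[j], "_se")]] <- apply(acc[, , j, drop = FALSE], 2L,
                                           stats::sd, na.rm = TRUE)
  }
  out
}

# full HWI matrix (not just summary stats) from an incidence matrix
hwi_from_incidence <- function(M, period) {
  n <- ncol(M)
  X <- matrix(0, n, n)
  Yonly <- matrix(0, n, n)
  for (p in unique(period)) {
    Mp <- M[period == p, , drop = FALSE]
    tog <- crossprod(Mp) > 0
    diag(tog) <- FALSE
    sn <- colSums(Mp) > 0
    X <- X + tog
    Yonly <- Yonly + (sn & !tog)
  }
  denom <- X + (Yonly + t(Yonly)) / 2
  h <- ifelse(denom > 0, X / denom, 0)
  rownames(h) <- colnames(h) <- colnames(M)
  h
}

#' Export the weighted association network as GraphML
#'
#' Minimal GraphML (nodes with id, edges with the half-weight index as a
#' `weight` attribute) for external network viewers.
#'
#' @param assoc an `assoc_matrix`.
#' @param path output path.
#' @param threshold drop edges with index below this value (default 0).
#' @export
write_graphml <- function(assoc, path, threshold = 0) {
  h <- assoc$hwi
  ids <- assoc$ids
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             '<key id="w" for="edge" attr.name="weight" attr.type="double"/>',
             '<graph edgedefault="undirected">')
  lines <- c(lines, sprintf('<node id="%s"/>', ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j > i && !is.na(h[i, j]) && h[i, j] > threshold) {
      lines <- c(lines, sprintf(
        '<edge source="%s" target="%s"><data key="w">%g</data></edge>',
        ids[i], ids[j], h[i, j]))
    }
  }
  writeLines(c(lines, "</graph>", "</graphml>"), path)
  invisible(path)
}
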