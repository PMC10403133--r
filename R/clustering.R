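# Hierarchical clustering of the association matrix with cophenetic
# validation and Newman modularity of the best dendrogram cut.

#' Weighted Newman modularity of a community division
#'
#' Q = (1/2m) * sum_ij (a_ij - s_i s_j / 2m) delta(c_i, c_j), summed over
#' all ordered pairs including i = j, with a_ii = 0, s_i the node
#' strengths and 2m the total weight. Q is 0 for the single-community
#' division.
#'
#' @param a symmetric weight matrix (diagonal ignored).
#' @param membership community label per node.
#' @return modularity Q (scalar).
#' @export
modularity_q <- function(a, membership) {
  a <- as.matrix(a)
  diag(a) <- 0
  s <- rowSums(a)
  m2 <- sum(s)
  if (m2 <= 0) return(0)
  same <- outer(membership, membership, `==`)
  sum((a - outer(s, s) / m2)[same]) / m2
}

#' Hierarchical cluster analysis of an association matrix
#'
#' Agglomerates on dissimilarity 1 - HWI with the four standard linkages
#' (single, complete, average, Ward). Each dendrogram is scored by the
#' cophenetic correlation coefficient (CCC): the Pearson correlation
#' between the pairwise association indices and the cophenetic similarity
#' at which pairs first merge. The linkage with the highest CCC is
#' selected, and its community division is the dendrogram cut maximizing
#' weighted Newman modularity Q over all cut sizes. The conventional
#' reliability thresholds are flagged: CCC >= 0.8 for the dendrogram and
#' Q >= 0.3 for a meaningful division.
#'
#' @param assoc an `assoc_matrix` (or symmetric HWI matrix) with >= 3
#'   individuals.
#' @return object of class `cluster_result`: per-linkage CCC, the best
#'   linkage's `hclust` tree, best-cut membership, Q, and reliability
#'   flags.
#' @export
cluster_analysis <- function(assoc) {
  h <- if (inherits(assoc, "assoc_matrix")) assoc$hwi else as.matrix(assoc)
  ids <- rownames(h) %||% as.character(seq_len(nrow(h)))
  n <- nrow(h)
  if (n < 3L) stop("cluster analysis requires at least 3 individuals")
  diag(h) <- 0
  d <- stats::as.dist(1 - h)
  methods <- c(single = "single", complete = "complete",
               average = "average", ward = "ward.D2")
  trees <- lapply(methods, function(m) stats::hclust(d, method = m))
  sim <- h[lower.tri(h)]
  ccc <- vapply(trees, function(tr) {
    cop <- as.vector(stats::cophenetic(tr))
    if (stats::sd(sim) == 0 || stats::sd(cop) == 0) return(NA_real_)
    stats::cor(sim, 1 - cop)
  }, numeric(1))
  if (all(is.na(ccc))) {
    warning("association matrix is constant: CCC undefined")
    best <- "average"
  } else {
    best <- names(which.max(ccc))
  }
  tree <- trees[[best]]
  qs <- vapply(seq_len(n), function(k) {
    modularity_q(h, stats::cutree(tree, k))
  }, numeric(1))
  k_best <- which.max(qs)
  membership <- stats::cutree(tree, k_best)
  names(membership) <- ids
  structure(list(ccc = ccc, best_linkage = best, tree = tree,
                 membership = membership, n_communities = k_best,
                 modularity = qs[k_best], modularity_by_k = qs,
                 reliable_dendrogram = !is.na(ccc[best]) && ccc[best] >= 0.8,
                 meaningful_division = qs[k_best] >= 0.3),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Hierarchical cluster analysis\n  CCC by linkage: ",
      paste(sprintf("%s=%.3f", names(x$ccc), x$ccc), collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  best linkage: %s (CCC %.3f, %s)\n", x$best_linkage,
              x$ccc[x$best_linkage],
              if (x$reliable_dendrogram) "reliable" else "below 0.8 threshold"))
  cat(sprintf("  best cut: %d communities, Q = %.3f (%s)\n", x$n_communities,
              x$modularity,
              if (x$meaningful_division) "meaningful" else "below 0.3 threshold"))
  invisible(x)
}
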