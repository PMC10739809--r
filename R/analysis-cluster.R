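# Conformational clustering by greedy neighbor counting (the GROMOS
# algorithm): the member with the most neighbors within an RMSD cutoff
# becomes a cluster centroid, it and its neighbors are removed, repeat.

#' Neighbor-counting (GROMOS) conformational clustering
#'
#' Pairwise RMSD over the analysis selection (after optional least-squares
#' fitting over the fit selection) defines the neighborhood graph at the
#' cutoff; clusters are carved off greedily around the neighbor-richest
#' member. Deterministic: ties in neighbor count and in cluster size are
#' broken by the lowest member index.
#'
#' @param ensemble an [ensemble3d()].
#' @param analysis_indices atoms over which RMSD is measured.
#' @param fit_indices atoms for the superposition before each RMSD
#'   (`NULL` = no fitting).
#' @param cutoff RMSD cutoff in nm (default 0.3).
#' @return List of class `cluster_result`: `labels` (per member, clusters
#'   numbered 1.. by descending population), `clusters` (data.frame
#'   `label`, `size`, `representative` = centroid member index),
#'   `cutoff`.
#' @export
cluster_gromos <- function(ensemble, analysis_indices, fit_indices = NULL,
                           cutoff = 0.3) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  n <- length(ensemble$members)
  # precompute pairwise RMSD (symmetric)
  D <- matrix(0, n, n)
  cs <- lapply(ensemble$members, function(s) s$xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- rmsd(cs[[i]], cs[[j]],
                               analysis_indices = analysis_indices,
                               fit_indices = fit_indices)
  }
  adj <- D <= cutoff
  alive <- rep(TRUE, n)
  labels <- integer(n)
  reps <- integer(0)
  lab <- 0L
  while (any(alive)) {
    counts <- colSums(adj[alive, , drop = FALSE]) * alive
    centroid <- which.max(counts)  # ties -> lowest index
    memb <- which(adj[centroid, ] & alive)
    lab <- lab + 1L
    labels[memb] <- lab
    reps[lab] <- centroid
    alive[memb] <- FALSE
  }
  sizes <- tabulate(labels, nbins = lab)
  ord <- order(-sizes, reps)  # by population, tie -> lowest centroid index
  relabel <- integer(lab)
  relabel[ord] <- seq_len(lab)
  out <- list(labels = relabel[labels],
              clusters = data.frame(label = seq_len(lab),
                                    size = sizes[ord],
                                    representative = reps[ord]),
              cutoff = cutoff)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d members (cutoff %.3g nm); top sizes: %s\n",
              nrow(x$clusters), length(x$labels), x$cutoff,
              paste(utils::head(x$clusters$size, 5), collapse = ", ")))
  invisible(x)
}

#' Cumulative fraction of conformers in the top-k clusters
#'
#' The heterogeneity summary: what fraction of the ensemble the k most
#' populated clusters encompass, non-decreasing in k and reaching 1 at
#' the total number of clusters.
#'
#' @param result a [cluster_result] from [cluster_gromos()].
#' @param ks sorted ascending positive integers; values beyond the number
#'   of clusters count all of them.
#' @return Numeric vector of fractions, named by k.
#' @export
cumulative_cluster_fraction <- function(result, ks) {
  if (any(ks < 1)) stopf("k must be >= 1")
  if (is.unsorted(ks)) stopf("ks must be sorted ascending")
  csum <- cumsum(result$clusters$size)
  total <- length(result$labels)
  out <- csum[pmin(ks, length(csum))] / total
  names(out) <- paste0("k", ks)
  out
}

#' Representative conformers of the top-k clusters
#'
#' @param result a [cluster_result].
#' @param ensemble the clustered [ensemble3d()].
#' @param k number of clusters (default all).
#' @return An [ensemble3d()] of centroid structures, ordered by cluster
#'   population and weighted by it.
#' @export
cluster_representatives <- function(result, ensemble, k = NULL) {
  k <- min(k %||% nrow(result$clusters), nrow(result$clusters))
  idx <- result$clusters$representative[seq_len(k)]
  ensemble3d(ensemble$members[idx],
             weights = result$clusters$size[seq_len(k)])
}
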