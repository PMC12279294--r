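LINKAGES <- c("complete", "single", "average")

#' Agglomerative clustering of a distance matrix
#'
#' Bottom-up merging from singletons: at each step the pair of clusters with
#' the smallest inter-cluster distance under the chosen linkage is merged
#' (single = minimum pairwise member distance, complete = maximum, average =
#' unweighted mean, i.e. UPGMA), stopping when `k` clusters remain.
#' Inter-cluster distances are maintained by Lance-Williams updates.
#'
#' Determinism: merge ties (two candidate pairs at exactly equal distance)
#' are broken by the smallest pair of cluster labels, where a cluster's label
#' is the smallest original member index it contains. Final cluster indices
#' are ordered by decreasing size, ties by smallest member label.
#'
#' @param dist a [dist_matrix()].
#' @param k target number of clusters, `1 <= k <= N`.
#' @param linkage one of `"complete"` (default), `"single"`, `"average"`.
#' @return object of class `cluster_assignment`: list with `n_clusters`,
#'   `membership` (named integer vector, member label -> cluster index),
#'   `centers` (cluster index -> medoid member label), `sizes`, `linkage`.
#' @export
agglomerative_cluster <- function(dist, k, linkage = "complete") {
  linkage <- match.arg(linkage, LINKAGES)
  if (!inherits(dist, "dist_matrix")) {
    dist <- dist_matrix(dist)   # validates symmetry etc.
  }
  n <- length(dist$labels)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)

  clusters <- as.list(seq_len(n))     # member indices per active cluster
  labs <- seq_len(n)                  # smallest member index per cluster
  sizes <- rep(1L, n)
  W <- dist$values
  diag(W) <- Inf
  active <- rep(TRUE, n)

  n_active <- n
  while (n_active > k) {
    Wa <- W
    Wa[!active, ] <- Inf
    Wa[, !active] <- Inf
    Wa[lower.tri(Wa, diag = TRUE)] <- Inf
    m <- min(Wa)
    cand <- which(Wa == m, arr.ind = TRUE)
    # tie-break: smallest (label_i, label_j) pair, labels sorted within pair
    a <- pmin(labs[cand[, 1]], labs[cand[, 2]])
    b <- pmax(labs[cand[, 1]], labs[cand[, 2]])
    pick <- order(a, b)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]

    others <- which(active); others <- others[others != i & others != j]
    new_d <- switch(linkage,
      single   = pmin(W[i, others], W[j, others]),
      complete = pmax(W[i, others], W[j, others]),
      average  = (sizes[i] * W[i, others] + sizes[j] * W[j, others]) /
                 (sizes[i] + sizes[j])
    )
    W[i, others] <- new_d
    W[others, i] <- new_d
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    labs[i] <- min(labs[i], labs[j])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    W[j, ] <- Inf; W[, j] <- Inf
    n_active <- n_active - 1L
  }

  final <- clusters[active]
  ord <- order(-vapply(final, length, integer(1)),
               vapply(final, min, integer(1)))
  final <- final[ord]
  membership <- integer(n)
  for (ci in seq_along(final)) membership[final[[ci]]] <- ci
  names(membership) <- dist$labels
  out <- structure(
    list(n_clusters = k, membership = membership, centers = NULL,
         sizes = vapply(final, length, integer(1)), linkage = linkage),
    class = "cluster_assignment"
  )
  out$centers <- cluster_centers(dist, out)
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", x$n_clusters, "clusters (", x$linkage,
      "linkage ); sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Medoid centers of a clustering
#'
#' The center of a cluster is its medoid: the member minimising the sum of
#' distances to all other members of the same cluster. Ties go to the member
#' earliest in ensemble order; singletons return their only member.
#'
#' @param dist the [dist_matrix()] the assignment was computed from.
#' @param assignment a `cluster_assignment` over the same labels.
#' @return character vector, cluster index -> member label.
#' @export
cluster_centers <- function(dist, assignment) {
  if (!identical(names(assignment$membership), dist$labels)) {
    stop("assignment labels do not match distance matrix labels")
  }
  vapply(seq_len(assignment$n_clusters), function(ci) {
    idx <- which(assignment$membership == ci)   # ascending = ensemble order
    if (!length(idx)) stop("cluster ", ci, " is empty")
    sums <- rowSums(dist$values[idx, idx, drop = FALSE])
    dist$labels[idx[which.min(sums)]]           # which.min: first on ties
  }, character(1))
}

#' Reduce an ensemble to k diverse representatives
#'
#' The core ensemble-reduction step: computes pairwise framework-aligned loop
#' backbone RMSDs, clusters them agglomeratively, and returns the medoid
#' center of each cluster as a new ensemble (ordered by cluster index, i.e.
#' by decreasing cluster size). With the defaults (k = 20, complete linkage,
#' H3) a 100-model generative ensemble is reduced five-fold while preserving
#' its conformational diversity.
#'
#' @inheritParams pairwise_loop_distances
#' @param k number of clusters / output models (default 20).
#' @param linkage linkage strategy (default `"complete"`).
#' @return an `ab_ensemble` of the k cluster centers, with attributes
#'   `assignment` (the `cluster_assignment`) and `cluster_sizes`.
#' @export
reduce_ensemble <- function(ensemble, regions, loop = "H3", k = 20,
                            linkage = "complete", atom_set = BACKBONE_ATOMS) {
  n <- length(ensemble$members)
  if (n < k) stop("ensemble size ", n, " is smaller than k = ", k)
  dm <- pairwise_loop_distances(ensemble, regions, loop, atom_set)
  asg <- agglomerative_cluster(dm, k, linkage)
  center_idx <- match(asg$centers, ensemble$labels)
  out <- new_ensemble(ensemble$members[center_idx],
                      labels = ensemble$labels[center_idx])
  attr(out, "assignment") <- asg
  attr(out, "cluster_sizes") <- asg$sizes
  out
}

#' Sweep ensemble size, cluster count and linkage
#'
#' For each combination of `n` (first-n truncation of the ensemble, in
#' ensemble order), `k` and linkage, reduces the truncated ensemble to `k`
#' centers and reports the minimum loop RMSD to `reference` over those
#' centers (`best_center_rmsd`), alongside the pre-clustering minimum over
#' all first-n members (`all_min_rmsd`). Combinations with `k > n` are
#' dropped.
#'
#' @inheritParams reduce_ensemble
#' @param n_values ensemble truncation sizes.
#' @param k_values cluster counts.
#' @param linkages linkage strategies to try.
#' @param reference `ab_structure` containing the loop, e.g. the
#'   experimental structure.
#' @return data.frame with columns `n`, `k`, `linkage`, `best_center_rmsd`,
#'   `all_min_rmsd`.
#' @export
sweep_reduction <- function(ensemble, regions, loop = "H3",
                            n_values, k_values, linkages = LINKAGES,
                            reference, atom_set = BACKBONE_ATOMS) {
  n_values <- sort(unique(as.integer(n_values)))
  k_values <- sort(unique(as.integer(k_values)))
  linkages <- match.arg(linkages, LINKAGES, several.ok = TRUE)
  n_max <- max(n_values)
  if (n_max > length(ensemble$members)) {
    stop("max(n_values) exceeds ensemble size")
  }
  sub <- ensemble[seq_len(n_max)]
  dm_full <- pairwise_loop_distances(sub, regions, loop, atom_set)
  ref_rmsd <- vapply(sub$members, function(m) {
    loop_rmsd(m, reference, regions, loop, atom_set)
  }, numeric(1))

  rows <- list()
  for (n in n_values) {
    dmn <- dist_matrix(dm_full$values[seq_len(n), seq_len(n), drop = FALSE],
                       dm_full$labels[seq_len(n)])
    all_min <- min(ref_rmsd[seq_len(n)])
    for (lk in linkages) {
      for (k in k_values[k_values <= n]) {
        asg <- agglomerative_cluster(dmn, k, lk)
        best <- min(ref_rmsd[match(asg$centers, sub$labels)])
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, k = k, linkage = lk,
          best_center_rmsd = best, all_min_rmsd = all_min,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
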