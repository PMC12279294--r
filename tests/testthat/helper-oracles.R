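# Independent oracles used across the suite. Each is deliberately naive and
# shares no code path with the package implementation it checks.

# ---- partitions ------------------------------------------------------------

# canonical form of a partition for comparison: clusters sorted by
# (-size, smallest member), members sorted within clusters
canonical_partition <- function(membership) {
  cl <- split(seq_along(membership), membership)
  cl <- lapply(cl, sort)
  ord <- order(-vapply(cl, length, integer(1)),
               vapply(cl, min, integer(1)))
  unname(cl[ord])
}

# naive O(N^3) agglomerative clustering: recomputes every inter-cluster
# distance from the raw pairwise matrix at every merge step (no
# Lance-Williams updates). Same tie-break contract as the package: smallest
# (min-label, min-label) pair.
naive_agglomerative <- function(D, k, linkage) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        sub <- D[clusters[[i]], clusters[[j]], drop = FALSE]
        d <- switch(linkage,
                    single = min(sub),
                    complete = max(sub),
                    average = mean(sub))
        la <- min(min(clusters[[i]]), min(clusters[[j]]))
        lb <- max(min(clusters[[i]]), min(clusters[[j]]))
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (la < best$la || (la == best$la && lb < best$lb)))) {
          best <- list(d = d, i = i, j = j, la = la, lb = lb)
        }
      }
    }
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  membership <- integer(n)
  for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
  membership
}

random_dist_values <- function(n) {
  # random symmetric matrix with zero diagonal; continuous entries so merge
  # ties have probability zero
  pts <- matrix(stats::runif(n * 4), n, 4)
  as.matrix(stats::dist(pts))
}

# ---- superposition ---------------------------------------------------------

euler_rotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# hierarchical rotation-grid search for the minimum RMSD between two point
# clouds (translation handled by centroid alignment); independent of SVD
grid_search_min_rmsd <- function(mobile, reference) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R0 <- sweep(reference, 2, colMeans(reference))
  obj <- function(a, b, c) {
    sqrt(mean(rowSums((M %*% t(euler_rotation(a, b, c)) - R0)^2)))
  }
  best <- c(0, 0, 0); best_v <- obj(0, 0, 0)
  steps <- c(pi / 9, pi / 45, pi / 225, pi / 1125)
  grids <- list(
    expand.grid(a = seq(0, 2 * pi, by = steps[1]),
                b = seq(0, pi, by = steps[1]),
                c = seq(0, 2 * pi, by = steps[1]))
  )
  for (lvl in seq_along(steps)) {
    g <- if (lvl == 1) grids[[1]] else {
      s <- steps[lvl]
      expand.grid(a = best[1] + seq(-5, 5) * s,
                  b = best[2] + seq(-5, 5) * s,
                  c = best[3] + seq(-5, 5) * s)
    }
    vals <- mapply(obj, g$a, g$b, g$c)
    w <- which.min(vals)
    if (vals[w] < best_v) {
      best_v <- vals[w]
      best <- as.numeric(g[w, ])
    }
  }
  best_v
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3, byrow = TRUE)
}

# rigidly transform every atom of a structure
transform_structure <- function(x, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, t, "+")
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

# ---- clashes ---------------------------------------------------------------

# all-pairs O(n^2) clash recount over backbone atoms, explicit double loop
oracle_clash_count <- function(x, radii, fraction, chain_pair) {
  a <- x$atoms[x$atoms$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  a1 <- a[a$chain == chain_pair[1], , drop = FALSE]
  a2 <- a[a$chain == chain_pair[2], , drop = FALSE]
  count <- 0L
  for (i in seq_len(nrow(a1))) {
    for (j in seq_len(nrow(a2))) {
      d <- sqrt((a1$x[i] - a2$x[j])^2 + (a1$y[i] - a2$y[j])^2 +
                  (a1$z[i] - a2$z[j])^2)
      if (d < fraction * (radii[[a1$elesy[i]]] + radii[[a2$elesy[j]]])) {
        count <- count + 1L
      }
    }
  }
  count
}

# ---- CAPRI -----------------------------------------------------------------

# independently coded decision table: evaluates all class predicates as a
# boolean vector and picks the best satisfied class
oracle_capri_class <- function(fn, lr, ir) {
  ok <- c(
    high = (fn >= 0.5) && (lr <= 1 || ir <= 1),
    medium = (fn >= 0.3) && (lr <= 5 || ir <= 2),
    acceptable = (fn >= 0.1) && (lr <= 10 || ir <= 4)
  )
  if (any(ok)) names(ok)[which(ok)[1]] else "incorrect"
}

quality_rank <- function(q) {
  match(q, c("incorrect", "acceptable", "medium", "high"))
}

# residue keys of one chain of a structure
reskey_of <- function(x, chain) {
  a <- x$atoms[x$atoms$chain == chain, , drop = FALSE]
  unique(paste(a$chain, a$resno, a$insert, sep = ":"))
}

# residue-number range membership (local copy for oracle computations)
in_ranges <- function(resno, ranges) {
  hit <- rep(FALSE, length(resno))
  for (r in ranges) hit <- hit | (resno >= r[1] & resno <= r[2])
  hit
}

# ---- fixtures shared by tests ----------------------------------------------

toy_regions_pair <- function(seed = 11, sigma = 0.15) {
  spec <- fixture_spec(seed = seed, n_conformations = 2,
                       members_per_conformation = c(1L, 1L),
                       intra_noise_sigma = sigma,
                       inter_conformation_shift = 4)
  a <- make_toy_chain(spec, 0L, member_id = 1L)
  b <- make_toy_chain(spec, 1L, member_id = 1L)
  list(model = b$structure, reference = a$structure, regions = a$regions,
       spec = spec)
}
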