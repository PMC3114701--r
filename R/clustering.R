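# Outlier weeding and K-means++ seeded medoid clustering of surface patches
# under the (non-metric) patch distance, producing a centroid library.

#' Weed out outlier patches
#'
#' An outlier is a patch whose distance to strictly more than `frac` of the
#' OTHER patches exceeds `d_out` (an infinite distance always counts as
#' exceeding).  Outliers would otherwise form non-informative singleton
#' clusters.
#'
#' @param patches List of `surface_patch` objects.
#' @param dmatrix All-vs-all distance matrix from
#'   [pairwise_patch_distances()].
#' @param d_out Distance cutoff in Angstrom (default 2.5).
#' @param frac Fraction of other patches that must be farther than `d_out`
#'   for removal (default 0.9, strict inequality).
#' @return List with `kept` and `removed` patch lists plus `kept_idx` and
#'   `removed_idx` (original order preserved).
#' @export
weed_outliers <- function(patches, dmatrix, d_out = 2.5, frac = 0.9) {
  n <- length(patches)
  stopifnot(nrow(dmatrix) == n, ncol(dmatrix) == n)
  if (n < 2L)
    return(list(kept = patches, removed = list(),
                kept_idx = seq_len(n), removed_idx = integer(0)))
  far_share <- vapply(seq_len(n), function(i) {
    mean(dmatrix[i, -i] > d_out)
  }, numeric(1))
  removed_idx <- which(far_share > frac)
  kept_idx <- setdiff(seq_len(n), removed_idx)
  list(kept = patches[kept_idx], removed = patches[removed_idx],
       kept_idx = kept_idx, removed_idx = removed_idx)
}

# Replace infinities by a finite cap (2x the largest finite distance) so
# that D^2 sampling weights and assignment comparisons stay finite while
# preserving "far" semantics.
cap_infinities <- function(dmatrix) {
  finite <- dmatrix[is.finite(dmatrix)]
  cap <- if (length(finite) > 0 && max(finite) > 0) 2 * max(finite) else 1
  dmatrix[!is.finite(dmatrix)] <- cap
  dmatrix
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' K-means++ seeding over a precomputed distance matrix
#'
#' The first centroid is drawn uniformly at random; each subsequent centroid
#' is drawn with probability proportional to D(x)^2, where D(x) is the
#' distance from x to its nearest already-chosen centroid.  Infinite
#' distances are capped at twice the largest finite distance.
#'
#' @param dmatrix Square distance matrix.
#' @param k Number of seeds (<= number of patches).
#' @param rng_seed Integer seed; the draw is deterministic given the seed.
#' @return Integer vector of k centroid indices.
#' @export
kmeanspp_seed <- function(dmatrix, k, rng_seed = 1L) {
  n <- nrow(dmatrix)
  if (k > n) stop("k (", k, ") exceeds number of patches (", n, ")",
                  call. = FALSE)
  d <- cap_infinities(dmatrix)
  with_rng_seed(rng_seed, {
    centers <- integer(k)
    centers[1] <- sample.int(n, 1)
    if (k > 1) {
      dmin <- d[, centers[1]]
      for (c_i in seq(2, k)) {
        w <- dmin^2
        if (sum(w) <= 0) {
          # all remaining points coincide with a centre: pick any unchosen
          cand <- setdiff(seq_len(n), centers[seq_len(c_i - 1)])
          centers[c_i] <- cand[sample.int(length(cand), 1)]
        } else {
          centers[c_i] <- sample.int(n, 1, prob = w)
        }
        dmin <- pmin(dmin, d[, centers[c_i]])
      }
    }
    centers
  })
}

#' Cluster surface patches into a centroid library
#'
#' Lloyd-style alternation with medoid updates under the patch distance:
#' patches are assigned to the nearest centroid (ties to the lowest centroid
#' index; infinities capped), and each cluster's centroid is replaced by the
#' member minimising the summed distance to its co-members.  Iteration stops
#' when assignments stabilise or after `max_iter` rounds.  Medoid centroids
#' keep every library element a real surface patch that can later serve as a
#' superposition target.
#'
#' @param patches List of (weeded) `surface_patch` objects.
#' @param dmatrix Matching all-vs-all distance matrix.
#' @param k Number of clusters (the published library uses 350).
#' @param max_iter Iteration cap (default 100).
#' @param rng_seed Seed for the K-means++ initialisation.
#' @param nstart Number of K-means++ restarts; the run with the lowest
#'   total within-cluster distance to the medoids wins (ties: first run).
#'   Restart s uses seed `rng_seed + 1000 * (s - 1)`.
#' @return A `patch_library`: list with `centroids` (k patches),
#'   `medoid_idx`, `assignments`, `cluster_sizes`, `training_fractions`,
#'   `k`, `rng_seed`, `iterations` and `params`.
#' @export
cluster_patches <- function(patches, dmatrix, k = 350, max_iter = 100,
                            rng_seed = 1L, nstart = 5L) {
  n <- length(patches)
  stopifnot(nrow(dmatrix) == n, k >= 1, nstart >= 1)
  if (k > n) stop("k (", k, ") exceeds number of patches (", n, ")",
                  call. = FALSE)
  d <- cap_infinities(dmatrix)
  best <- NULL
  for (s in seq_len(nstart)) {
    run <- lloyd_medoids(d, k, rng_seed + 1000L * (s - 1L), max_iter,
                         dmatrix)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  medoids <- best$medoids
  assignments <- best$assignments
  sizes <- tabulate(assignments, nbins = k)
  lib <- structure(
    list(centroids = patches[medoids],
         medoid_idx = medoids,
         assignments = assignments,
         cluster_sizes = sizes,
         training_fractions = sizes / n,
         k = as.integer(k),
         rng_seed = as.integer(rng_seed),
         iterations = best$iterations,
         params = list(max_iter = max_iter, nstart = nstart)),
    class = "patch_library")
  lib
}

# one Lloyd run: k-means++ seeding, assignment / medoid-update alternation
lloyd_medoids <- function(d, k, seed, max_iter, dmatrix) {
  n <- nrow(d)
  medoids <- sort(kmeanspp_seed(dmatrix, k, seed))
  assign_old <- rep(NA_integer_, n)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    # assignment: nearest medoid, ties to the lowest cluster index
    dc <- d[, medoids, drop = FALSE]
    assignments <- apply(dc, 1, which.min)
    # guard against empty clusters: re-seed with the worst-fitting patch
    for (c_i in seq_len(k)) {
      if (!any(assignments == c_i)) {
        resid <- dc[cbind(seq_len(n), assignments)]
        resid[medoids] <- -Inf
        far <- which.max(resid)
        message("re-seeding empty cluster ", c_i, " with patch ", far)
        medoids[c_i] <- far
        assignments[far] <- c_i
        dc <- d[, medoids, drop = FALSE]
      }
    }
    if (identical(assignments, assign_old) || iterations > max_iter) break
    assign_old <- assignments
    # medoid update: member minimising summed distance to co-members
    for (c_i in seq_len(k)) {
      members <- which(assignments == c_i)
      if (length(members) == 1L) { medoids[c_i] <- members; next }
      sums <- rowSums(d[members, members, drop = FALSE])
      medoids[c_i] <- members[which.min(sums)]
    }
  }
  objective <- sum(d[cbind(seq_len(n), medoids[assignments])])
  list(medoids = medoids, assignments = assignments,
       iterations = iterations, objective = objective)
}

#' @export
print.patch_library <- function(x, ...) {
  cat("patch_library: k =", x$k, "centroids over",
      sum(x$cluster_sizes), "patches;",
      x$iterations, "iterations, seed", x$rng_seed, "\n")
  cat("cluster sizes:", paste(utils::head(x$cluster_sizes, 10),
                              collapse = " "),
      if (x$k > 10) "...\n" else "\n")
  invisible(x)
}
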