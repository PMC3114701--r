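# Library compatibility scoring: DCLE assignment, structure profiles,
# preference vectors, rank-sum tests, and model ranking.

make_tiny_library <- function(rng_seed = 2) {
  pl <- make_planted_patches(k_groups = 3, per_group = 4, intra_noise = 0.2,
                             rng_seed = rng_seed)
  dm <- pairwise_patch_distances(pl$patches)
  list(lib = cluster_patches(pl$patches, dm, k = 3, rng_seed = 1),
       planted = pl)
}

test_that("patch assignment finds the closest library element", {
  tl <- make_tiny_library()
  lib <- tl$lib
  # each centroid assigns to itself with DCLE 0
  for (ci in seq_along(lib$centroids)) {
    asg <- assign_patch(lib$centroids[[ci]], lib)
    expect_equal(asg$cluster, ci)
    expect_lt(asg$dcle, 1e-9)
  }
  # argmin agrees with an independent linear scan
  q <- tl$planted$patches[[7]]
  d_all <- vapply(lib$centroids, function(ct) patch_distance(q, ct)$value,
                  numeric(1))
  asg <- assign_patch(q, lib)
  expect_equal(asg$dcle, min(d_all))
  expect_equal(asg$cluster, which.min(d_all))
  # incompatible with every centroid: no cluster, infinite DCLE
  alien <- typed_patch(rep("TRP:CD1", 7),
                       patch_coords(make_random_patch(7, rng_seed = 4)))
  asg_a <- assign_patch(alien, lib)
  expect_true(is.na(asg_a$cluster))
  expect_identical(asg_a$dcle, Inf)
})

test_that("a structure profiled against its own-patch library has zero DCLE", {
  s <- make_structure(12, "sheet", rng_seed = 3,
                      sequence = rep(c("VAL", "SER"), 6))
  sasa <- compute_sasa(s)
  thr <- fit_thresholds(list(list(structure = s, sasa = sasa)))
  surf <- select_surface_atoms(s, sasa, thr)
  patches <- extract_patches(s, surf)
  dm <- pairwise_patch_distances(patches)
  lib <- cluster_patches(patches, dm, k = length(patches), rng_seed = 1)
  prof <- profile_structure(s, lib, thr)
  expect_equal(prof$n_patches, length(patches))
  expect_true(all(prof$patches$dcle < 1e-9))
  expect_equal(prof$mean_finite_dcle, 0, tolerance = 1e-9)
  expect_equal(sum(prof$preference), 1, tolerance = 1e-9)
  # rigid motion leaves the profile unchanged
  prof_t <- profile_structure(transform_coords(s, random_rigid_transform(8)),
                              lib, thr)
  expect_equal(prof_t$patches$dcle, prof$patches$dcle, tolerance = 1e-6)
  # assignments agree except where centroids tie at zero distance
  moved <- which(prof_t$patches$cluster != prof$patches$cluster)
  for (i in moved) {
    d_tie <- patch_distance(lib$centroids[[prof$patches$cluster[i]]],
                            lib$centroids[[prof_t$patches$cluster[i]]])$value
    expect_lt(d_tie, 1e-6)
  }
})

test_that("structures with no patches yield a flagged empty profile", {
  tl <- make_tiny_library()
  s <- make_structure(6, "helix", rng_seed = 1, palette = "GLY")
  sasa <- compute_sasa(s)
  thr <- fit_thresholds(list(list(structure = s, sasa = sasa)))
  prof <- profile_structure(s, tl$lib, thr)
  expect_true(prof$empty)
  expect_equal(prof$n_patches, 0L)
})

test_that("Delta preferences are absolute differences with the TV bound", {
  expect_equal(delta_preferences(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)),
               c(0, 0, 0))
  expect_equal(delta_preferences(c(0.5, 0.5), c(1, 0)), c(0.5, 0.5))
  expect_error(delta_preferences(c(0.5, 0.5), c(1, 0, 0)), "length")
  set.seed(13)
  for (i in 1:20) {
    f0 <- stats::runif(10); f0 <- f0 / sum(f0)
    fq <- stats::runif(10); fq <- fq / sum(fq)
    expect_lte(sum(delta_preferences(f0, fq)), 2)
  }
})

# exact two-sided permutation p-value for the rank-sum statistic
perm_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

test_that("rank-sum test matches the exact permutation distribution", {
  # identical samples: no evidence against the null
  expect_gte(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p.value, 0.9)
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2))$p.value, 1)
  # fully separated 3+3: statistic at the permutation extreme (W = 0)
  rs <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(rs$statistic), 0)
  # normal approximation tracks exact enumeration at 8+8
  set.seed(21)
  for (i in 1:5) {
    x <- stats::rnorm(8); y <- stats::rnorm(8, mean = i / 4)
    expect_lt(abs(rank_sum_test(x, y)$p.value - perm_rank_sum_p(x, y)),
              0.02)
  }
  # infinities rank above all finite values
  rs_inf <- rank_sum_test(c(1, 2, 3, 4), c(5, Inf, Inf, Inf))
  expect_lt(rs_inf$p.value, 0.1)
})

test_that("model ranking is lexicographic and handles ties and empties", {
  s <- make_structure(12, "sheet", rng_seed = 3,
                      sequence = rep(c("VAL", "SER"), 6))
  sasa <- compute_sasa(s)
  thr <- fit_thresholds(list(list(structure = s, sasa = sasa)))
  surf <- select_surface_atoms(s, sasa, thr)
  patches <- extract_patches(s, surf)
  lib <- cluster_patches(patches, pairwise_patch_distances(patches),
                         k = length(patches), rng_seed = 1)
  dup1 <- s; attr(dup1, "identifier") <- "copy-1"
  dup2 <- s; attr(dup2, "identifier") <- "copy-2"
  rk <- rank_models(list(dup1, dup2), lib, thr)
  expect_equal(rk$model, c("copy-1", "copy-2"))   # ties keep input order
  expect_equal(rk$rank, 1:2)
  # a model with zero patches ranks last
  gly <- make_structure(6, "helix", rng_seed = 1, palette = "GLY",
                        identifier = "no-patches")
  rk2 <- suppressWarnings(rank_models(list(gly, dup1), lib, thr))
  expect_equal(rk2$model, c("copy-1", "no-patches"))
  expect_setequal(rk2$model, c("copy-1", "no-patches"))
  # scores never decrease down the ranking
  expect_true(!is.unsorted(rk2$frac_infinite))
})
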