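# The chemically constrained minimum-RMSD patch distance: compatibility
# pre-filter, Kabsch superposition, exact enumeration oracle, and the
# inner-sphere seeding heuristic.

test_that("compatibility tests size, composition and rg differences", {
  a <- make_random_patch(7, rng_seed = 1)
  expect_true(patch_compatible(a, a))
  # relative size difference: 10 vs 13 fails at phi1 = 0.2
  t10 <- rep(c("ALA:CB", "SER:OG"), length.out = 10)
  t13 <- rep(c("ALA:CB", "SER:OG"), length.out = 13)
  set.seed(2)
  p10 <- typed_patch(t10, rbind(c(0, 0, 0), matrix(runif(27, -4, 4), 9)))
  p13 <- typed_patch(t13, rbind(c(0, 0, 0), matrix(runif(36, -4, 4), 12)))
  expect_false(patch_compatible(p10, p13))
  # rg difference 2 vs 8 exceeds phi3 = 5
  near <- typed_patch(rep("ALA:CB", 5),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
                            c(-2, 0, 0), c(0, -2, 0)))
  far <- typed_patch(rep("ALA:CB", 5),
                     rbind(c(0, 0, 0), c(9, 0, 0), c(0, 9, 0),
                           c(-9, 0, 0), c(0, -9, 0)))
  expect_gt(abs(near$rg - far$rg), 5)
  expect_false(patch_compatible(near, far))
  expect_true(patch_compatible(near, far, phi3 = 20))
})

test_that("Kabsch superposition recovers rigid motions and the two-point case", {
  set.seed(7)
  a <- matrix(rnorm(24), ncol = 3)
  expect_equal(kabsch_superpose(a, a)$rmsd, 0, tolerance = 1e-12)
  tf <- random_rigid_transform(3)
  b <- sweep(a %*% t(tf$rotation), 2, tf$translation, "+")
  fit <- kabsch_superpose(a, b)
  expect_lt(fit$rmsd, 1e-9)
  # recovered transform maps b back onto a
  back <- sweep(b %*% t(fit$rotation), 2, fit$translation, "+")
  expect_equal(back, a, tolerance = 1e-9)
  # rotation is proper
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # worked two-point case: deviations of 1 each side after centring
  two <- kabsch_superpose(rbind(c(0, 0, 0), c(1, 0, 0)),
                          rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(two$rmsd, 1.0, tolerance = 1e-12)
})

test_that("exact distance enumerates proper mappings exhaustively", {
  a <- make_random_patch(6, rng_seed = 4)
  expect_equal(exact_patch_distance(a, a)$value, 0, tolerance = 1e-9)
  # permuted rigid copy of same-type atoms is found among all bijections
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(1, 1, 2))
  a3 <- typed_patch(c("ALA:CB", "SER:OG", "SER:OG", "SER:OG"), xyz)
  tf <- random_rigid_transform(5)
  xyz_b <- sweep(xyz[c(1, 4, 2, 3), ] %*% t(tf$rotation), 2,
                 tf$translation, "+")
  b3 <- typed_patch(c("ALA:CB", "SER:OG", "SER:OG", "SER:OG"), xyz_b)
  expect_lt(exact_patch_distance(a3, b3)$value, 1e-9)
  # incompatible pairs are infinitely distant regardless of geometry
  other <- typed_patch(rep("PHE:CG", 6), patch_coords(make_random_patch(6, 9)))
  res <- exact_patch_distance(a, other)
  expect_identical(res$value, Inf)
  expect_null(res$mapping)
  # oracle refuses large patches
  big <- typed_patch(rep(c("ALA:CB", "SER:OG", "VAL:CG1"), 4),
                     rbind(c(0, 0, 0), matrix(runif(33, -5, 5), 11)))
  expect_error(exact_patch_distance(big, big), "oracle")
})

test_that("heuristic agrees with the exact oracle on small compatible pairs", {
  n_pairs <- 60
  agree <- 0
  for (i in seq_len(n_pairs)) {
    pr <- make_patch_pair(n_atoms = 5 + (i %% 4), noise_sigma = 0.25,
                          rng_seed = 100 + i)
    e <- exact_patch_distance(pr$a, pr$b)$value
    h <- patch_distance(pr$a, pr$b)$value
    # the heuristic searches a subset of mappings: it can never undercut
    if (is.finite(e) && is.finite(h))
      expect_gte(h, e - 1e-6)
    if ((is.infinite(e) && is.infinite(h)) ||
        (is.finite(e) && is.finite(h) && abs(e - h) <= 0.1))
      agree <- agree + 1
  }
  expect_gte(agree / n_pairs, 0.95)
})

test_that("no inner-sphere seed below 2 A means infinite distance", {
  # two compatible patches whose best superposition is far beyond the seed
  # threshold: same composition, very different geometry (line vs cross)
  types <- c("ALA:CB", "SER:OG", "VAL:CG1", "LEU:CD1", "ASP:OD1")
  line <- typed_patch(types, cbind(c(0, 2.2, 4.4, 6.6, 8.8), 0, 0))
  cross <- typed_patch(types, rbind(c(0, 0, 0), c(4, 0, 0), c(-4, 0, 0),
                                    c(0, 4, 0), c(0, -4, 0)))
  expect_true(patch_compatible(line, cross))
  e <- exact_patch_distance(line, cross)
  expect_gte(e$value, 2)
  h <- patch_distance(line, cross)
  expect_identical(h$value, Inf)
  expect_identical(h$seed_count, 0L)
})

test_that("the distance is zero on self, symmetric, and rigid-invariant", {
  for (i in 1:25) {
    p <- make_random_patch(4 + (i %% 5), rng_seed = 500 + i)
    expect_lt(patch_distance(p, p)$value, 1e-9)
  }
  for (i in 1:15) {
    pr <- make_patch_pair(7, noise_sigma = 0.3, rng_seed = 700 + i)
    d_ab <- patch_distance(pr$a, pr$b)$value
    d_ba <- patch_distance(pr$b, pr$a)$value
    expect_identical(d_ab, d_ba)
    tf <- random_rigid_transform(800 + i)
    d_t <- patch_distance(pr$a, transform_coords(pr$b, tf))$value
    if (is.finite(d_ab)) expect_lt(abs(d_t - d_ab), 1e-6)
    else expect_identical(d_t, Inf)
  }
})

test_that("pairwise distance matrices are symmetric with zero diagonal", {
  p <- make_random_patch(6, rng_seed = 3)
  m2 <- pairwise_patch_distances(list(p, p))
  expect_equal(unname(m2), matrix(0, 2, 2), tolerance = 1e-12)
  # planted near-duplicates plus a composition-disjoint outsider
  pl <- make_planted_patches(k_groups = 2, per_group = 3, intra_noise = 0.1,
                             rng_seed = 6)
  outsider <- typed_patch(rep("TRP:CD1", 7),
                          patch_coords(make_random_patch(7, 11)))
  pats <- c(pl$patches[1:3], list(outsider))
  m <- pairwise_patch_distances(pats)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_true(all(is.finite(m[1:3, 1:3])))
  expect_true(all(is.infinite(m[4, 1:3])))
})
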