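# Percentile thresholds, surface selection, and patch extraction.

fake_corpus <- function(sasa_values, resname = "ALA", atom = "CB") {
  list(list(structure = tiny_structure(cbind(seq_along(sasa_values) * 10,
                                             0, 0),
                                       resname = resname, atom = atom),
            sasa = sasa_values))
}

test_that("thresholds are the 99th percentile with linear interpolation", {
  thr <- fit_thresholds(fake_corpus(0:100))
  expect_equal(unname(thr["ALA:CB"]), 99.0)
  # single observation: degenerate percentile
  thr1 <- fit_thresholds(fake_corpus(7.5))
  expect_equal(unname(thr1["ALA:CB"]), 7.5)
  expect_error(fit_thresholds(list()), "empty corpus")
})

test_that("surface selection boundary is inclusive and type-aware", {
  corpus <- fake_corpus(0:100)
  thr <- fit_thresholds(corpus)  # ALA:CB -> 99, alpha 0.9
  s3 <- tiny_structure(cbind(c(0, 10, 20), 0, 0))
  # exactly alpha * threshold is included; below excluded
  idx <- select_surface_atoms(s3, c(0.9 * 99, 0.9 * 99 - 1e-9, 0), thr)
  expect_equal(idx, 1L)
  # all-zero SASA for a type: threshold 0, zero-SASA atoms are surface
  thr0 <- fit_thresholds(fake_corpus(rep(0, 5)))
  expect_equal(select_surface_atoms(s3, c(0, 0, 0), thr0), 1:3)
  # unseen types are never surface, with a warning
  sv <- tiny_structure(cbind(c(0, 10), 0, 0), resname = "VAL", atom = "CG1")
  expect_warning(idx2 <- select_surface_atoms(sv, c(50, 50), thr),
                 "absent from the threshold table")
  expect_length(idx2, 0)
})

test_that("surface set is invariant under rigid motion", {
  s <- make_structure(8, "sheet", rng_seed = 4)
  corpus <- list(list(structure = s, sasa = compute_sasa(s)))
  thr <- fit_thresholds(corpus)
  surf <- select_surface_atoms(s, corpus[[1]]$sasa, thr)
  st <- transform_coords(s, random_rigid_transform(2))
  surf_t <- select_surface_atoms(st, compute_sasa(st), thr)
  expect_equal(surf_t, surf)
})

test_that("patches contain exactly the surface atoms within the radius", {
  s <- make_structure(10, "sheet", rng_seed = 6)
  sasa <- compute_sasa(s)
  thr <- fit_thresholds(list(list(structure = s, sasa = sasa)))
  surf <- select_surface_atoms(s, sasa, thr)
  patches <- extract_patches(s, surf, radius = 7)
  cbs <- sum(s$atom[surf] == "CB")
  expect_length(patches, cbs)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  for (p in patches) {
    pv_xyz <- unlist(p$atoms[p$pivot_index, c("x", "y", "z")])
    # brute-force membership check against all surface atoms
    d <- sqrt(colSums((t(xyz[surf, ]) - pv_xyz)^2))
    expect_equal(nrow(p$atoms), sum(d <= 7))
    expect_true(all(sqrt(rowSums(sweep(as.matrix(p$atoms[, c("x", "y", "z")]),
                                       2, pv_xyz)^2)) <= 7))
    expect_equal(sum(p$composition), nrow(p$atoms))
    expect_equal(p$atoms$atom[p$pivot_index], "CB")
  }
})

test_that("glycine-only structures yield no pivots", {
  s <- make_structure(6, "helix", rng_seed = 1, palette = "GLY")
  sasa <- compute_sasa(s)
  thr <- fit_thresholds(list(list(structure = s, sasa = sasa)))
  surf <- select_surface_atoms(s, sasa, thr)
  expect_length(extract_patches(s, surf), 0)
})

test_that("patch extraction is order-independent", {
  s <- make_structure(10, "sheet", rng_seed = 8)
  sasa <- compute_sasa(s)
  thr <- fit_thresholds(list(list(structure = s, sasa = sasa)))
  surf <- select_surface_atoms(s, sasa, thr)
  p1 <- extract_patches(s, surf)
  p2 <- extract_patches(s, rev(surf))
  expect_equal(lapply(p2, `[[`, "atoms"), lapply(p1, `[[`, "atoms"))
})

test_that("inner spheres hold 4-9 atoms when the patch allows it", {
  # big dense patch: atoms sprinkled through the sphere
  set.seed(31)
  xyz <- rbind(c(0, 0, 0),
               t(replicate(24, runif(3, -4, 4))))
  p <- typed_patch(rep(c("ALA:CB", "SER:OG", "VAL:CG1", "LEU:CD1",
                         "ASP:OD1"), 5), xyz)
  expect_gte(length(p$inner), 4)
  expect_lte(length(p$inner), 9)
  expect_false(p$small)
  # <= 9 atoms: the whole patch is the inner sphere
  p6 <- make_random_patch(6, rng_seed = 2)
  expect_equal(p6$inner, 1:6)
  expect_false(p6$small)
  # 3 atoms: flagged small
  p3 <- typed_patch(c("ALA:CB", "SER:OG", "VAL:CG1"),
                    rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  expect_equal(p3$inner, 1:3)
  expect_true(p3$small)
})

test_that("radius of gyration follows its closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  set.seed(5)
  pts <- matrix(rnorm(30), ncol = 3)
  tf <- random_rigid_transform(3)
  rot <- sweep(pts %*% t(tf$rotation), 2, tf$translation, "+")
  expect_equal(radius_of_gyration(rot), radius_of_gyration(pts),
               tolerance = 1e-12)
})

test_that("ensemble patches average 10-45 atoms at the default radius", {
  ens <- make_native_ensemble(rng_seed = 42)
  corpus <- lapply(ens$structures, function(s)
    list(structure = s, sasa = compute_sasa(s)))
  thr <- fit_thresholds(corpus)
  sizes <- unlist(lapply(corpus, function(el) {
    surf <- select_surface_atoms(el$structure, el$sasa, thr)
    vapply(extract_patches(el$structure, surf), function(p) nrow(p$atoms),
           integer(1))
  }))
  expect_gte(mean(sizes), 10)
  expect_lte(mean(sizes), 45)
})
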