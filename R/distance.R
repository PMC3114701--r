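# Chemically constrained minimum-RMSD distance between surface patches.
#
# Two patches are first screened for compatibility (size, chemical
# composition, radius of gyration).  Incompatible pairs are infinitely
# distant.  For compatible pairs the distance is the minimum RMSD over
# "proper" mappings -- type-preserving one-to-one correspondences -- either
# by exhaustive enumeration (oracle, small patches only) or by the
# inner-sphere seeding heuristic.

#' Compatibility pre-filter for a pair of patches
#'
#' Patches A (n atoms) and B (m atoms) are compatible iff all of:
#' \itemize{
#'   \item relative size difference  |n - m| / max(n, m) <= phi1,
#'   \item relative chemical difference
#'         sum_i |T_iA - T_iB| / max(n, m) <= phi2, where T_iA counts atoms
#'         of type i in A,
#'   \item |rg(A) - rg(B)| <= phi3 (Angstrom).
#' }
#' Failing any test makes the patch distance infinite.
#'
#' @param a,b `surface_patch` objects.
#' @param phi1,phi2 Dimensionless thresholds (default 0.2 each).
#' @param phi3 Radius-of-gyration threshold in Angstrom (default 5).
#' @return `TRUE` or `FALSE`.
#' @export
patch_compatible <- function(a, b, phi1 = 0.2, phi2 = 0.2, phi3 = 5) {
  n <- length(a$types)
  m <- length(b$types)
  mx <- max(n, m)
  if (abs(n - m) / mx > phi1) return(FALSE)
  all_types <- union(names(a$composition), names(b$composition))
  ta <- rep(0L, length(all_types)); names(ta) <- all_types
  tb <- ta
  ta[names(a$composition)] <- as.integer(a$composition)
  tb[names(b$composition)] <- as.integer(b$composition)
  if (sum(abs(ta - tb)) / mx > phi2) return(FALSE)
  abs(a$rg - b$rg) <= phi3
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of point set `b` onto point set `a` under a
#' proper rotation (no reflection) and translation, via SVD of the
#' covariance matrix.
#'
#' @param a,b Numeric matrices of matched points, one row per point, 3
#'   columns; equal row counts.
#' @return A list with `rmsd` (Angstrom), `rotation` (3x3 matrix `R`) and
#'   `translation` (length-3 `t`), such that `x %*% t(R) + t` maps b-frame
#'   coordinates into a's frame.
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), nrow(a) >= 1, ncol(a) == 3, ncol(b) == 3)
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  h <- crossprod(bc, ac)                      # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  brot <- bc %*% t(r)
  rmsd <- sqrt(mean(rowSums((ac - brot)^2)))
  list(rmsd = rmsd, rotation = r, translation = as.numeric(ca - r %*% cb))
}

apply_transform <- function(xyz, tf) {
  sweep(xyz %*% t(tf$rotation), 2, tf$translation, "+")
}

invert_transform <- function(tf) {
  list(rotation = t(tf$rotation),
       translation = as.numeric(-t(tf$rotation) %*% tf$translation))
}

# All ordered arrangements of k elements drawn from v (k <= length(v)),
# returned as a matrix with one arrangement per row.
arrangements <- function(v, k) {
  if (k == 0L) return(matrix(v[0], nrow = 1, ncol = 0))
  if (length(v) == 1L) return(matrix(v, nrow = 1))
  out <- vector("list", length(v))
  for (i in seq_along(v)) {
    rest <- arrangements(v[-i], k - 1L)
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}

# Enumerate every maximal proper mapping between two typed atom sets: per
# shared type the smaller group is fully mapped into the larger, all
# injections enumerated, and the per-type choices combined.  Returns a list
# of 2-column integer matrices (index in a, index in b).
proper_mappings <- function(types_a, types_b, max_mappings = 1e5) {
  shared <- intersect(unique(types_a), unique(types_b))
  if (length(shared) == 0L) return(list())
  per_type <- lapply(shared, function(tt) {
    ia <- which(types_a == tt)
    ib <- which(types_b == tt)
    if (length(ia) <= length(ib)) {
      sel <- arrangements(ib, length(ia))
      lapply(seq_len(nrow(sel)), function(r) cbind(ia, sel[r, ]))
    } else {
      sel <- arrangements(ia, length(ib))
      lapply(seq_len(nrow(sel)), function(r) cbind(sel[r, ], ib))
    }
  })
  n_total <- prod(vapply(per_type, length, numeric(1)))
  if (n_total > max_mappings)
    stop("proper-mapping enumeration too large (", n_total, " > ",
         max_mappings, ")", call. = FALSE)
  combos <- list(matrix(integer(0), 0, 2))
  for (tp in per_type) {
    combos <- unlist(lapply(combos, function(base) {
      lapply(tp, function(blk) rbind(base, blk))
    }), recursive = FALSE)
  }
  combos
}

distance_result <- function(value, mapping = NULL, transform = NULL,
                            seed_count = 0L, method = "heuristic") {
  structure(list(value = value, mapping = mapping, transform = transform,
                 seed_count = as.integer(seed_count), method = method),
            class = "patch_distance_result")
}

#' @export
print.patch_distance_result <- function(x, ...) {
  cat("patch distance (", x$method, "): ",
      if (is.finite(x$value)) paste0(format(round(x$value, 4)), " A")
      else "infinite",
      ", ", if (is.null(x$mapping)) 0 else nrow(x$mapping),
      " mapped pairs, ", x$seed_count, " seeds\n", sep = "")
  invisible(x)
}

#' Exact patch distance by exhaustive mapping enumeration
#'
#' The oracle form of the patch distance: enumerates every maximal proper
#' mapping between the two patches, superposes each, and returns the minimal
#' RMSD.  The search is factorial per atom type, so the operation refuses
#' patches above `max_atoms` atoms; use [patch_distance()] for real patches.
#'
#' @param a,b `surface_patch` objects.
#' @param phi1,phi2,phi3 Compatibility thresholds, see [patch_compatible()].
#' @param max_atoms Size guard for the enumeration.
#' @param max_mappings Guard on the number of enumerated mappings.
#' @return A `patch_distance_result`; `value` is `Inf` for incompatible
#'   pairs.
#' @export
exact_patch_distance <- function(a, b, phi1 = 0.2, phi2 = 0.2, phi3 = 5,
                                 max_atoms = 8, max_mappings = 1e5) {
  n <- length(a$types); m <- length(b$types)
  if (max(n, m) > max_atoms)
    stop("exact_patch_distance is an oracle for patches of <= ", max_atoms,
         " atoms; got ", max(n, m), call. = FALSE)
  if (!patch_compatible(a, b, phi1, phi2, phi3))
    return(distance_result(Inf, method = "exact"))
  maps <- proper_mappings(a$types, b$types, max_mappings)
  xa <- patch_coords(a); xb <- patch_coords(b)
  best <- Inf; best_map <- NULL; best_tf <- NULL
  for (mp in maps) {
    if (nrow(mp) == 0L) next
    fit <- kabsch_superpose(xa[mp[, 1], , drop = FALSE],
                            xb[mp[, 2], , drop = FALSE])
    if (fit$rmsd < best) {
      best <- fit$rmsd
      best_map <- mp
      best_tf <- fit[c("rotation", "translation")]
    }
  }
  if (!is.finite(best)) return(distance_result(Inf, method = "exact"))
  distance_result(best, best_map, best_tf,
                  seed_count = length(maps), method = "exact")
}

# Greedy type-preserving matching of full patches after a seed transform:
# candidate same-type pairs within `cutoff` are accepted by ascending
# distance, each atom used at most once.  Symmetric in the two patches.
greedy_match <- function(xa, types_a, xb_tr, types_b, cutoff) {
  shared <- intersect(unique(types_a), unique(types_b))
  if (length(shared) == 0L) return(matrix(integer(0), 0, 2))
  cand_i <- integer(0); cand_j <- integer(0); cand_d <- numeric(0)
  for (tt in shared) {
    ia <- which(types_a == tt); ib <- which(types_b == tt)
    pa <- xa[ia, , drop = FALSE]; pb <- xb_tr[ib, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
    d2[d2 < 0] <- 0
    keep <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(keep) > 0L) {
      cand_i <- c(cand_i, ia[keep[, 1]])
      cand_j <- c(cand_j, ib[keep[, 2]])
      cand_d <- c(cand_d, sqrt(d2[keep]))
    }
  }
  if (length(cand_i) == 0L) return(matrix(integer(0), 0, 2))
  ord <- order(cand_d, cand_i, cand_j)
  used_a <- logical(nrow(xa)); used_b <- logical(nrow(xb_tr))
  sel_i <- integer(0); sel_j <- integer(0)
  for (r in ord) {
    i <- cand_i[r]; j <- cand_j[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      sel_i <- c(sel_i, i); sel_j <- c(sel_j, j)
    }
  }
  cbind(sel_i, sel_j, deparse.level = 0)
}

# Deterministic, geometry-based ordering key so that the heuristic evaluates
# a pair of patches in a canonical order (exact symmetry by construction).
patch_order_key <- function(p) {
  paste(length(p$types),
        sprintf("%.9f", p$rg),
        sprintf("%.6f", mean(stats::dist(patch_coords(p)))),
        paste(names(p$composition), as.integer(p$composition),
              collapse = ","),
        sep = "|")
}

#' Heuristic patch distance with inner-sphere seeding
#'
#' The production form of the chemically constrained minimum-RMSD patch
#' distance.  Incompatible pairs (see [patch_compatible()]) are infinitely
#' distant.  Otherwise all proper mappings between the two inner spheres are
#' enumerated and superposed; every mapping whose inner RMSD is below
#' `seed_rmsd_max` seeds a full-patch alignment (no seed found means the
#' distance is infinite).  Each seed's rigid transform is applied to the
#' whole of B, full-patch atoms are matched greedily by ascending distance
#' among same-type pairs within `match_cutoff`, the matched pairs are
#' re-superposed, and the smallest resulting RMSD over all seeds is
#' returned.  A minimum matched fraction of the smaller patch (and at least
#' 3 pairs) is required for a finite value.
#'
#' @param a,b `surface_patch` objects with inner spheres computed.
#' @param phi1,phi2,phi3 Compatibility thresholds.
#' @param seed_rmsd_max Inner-sphere RMSD below which a mapping seeds the
#'   full alignment (Angstrom, default 2).
#' @param match_cutoff Greedy matching distance cutoff (Angstrom, default 3).
#' @param min_match_frac Minimum fraction of the smaller patch that must be
#'   matched for a finite distance (default 0.5).
#' @param max_mappings Guard on the inner-sphere enumeration.
#' @return A `patch_distance_result`.
#' @export
patch_distance <- function(a, b, phi1 = 0.2, phi2 = 0.2, phi3 = 5,
                           seed_rmsd_max = 2, match_cutoff = 3,
                           min_match_frac = 0.5, max_mappings = 1e5) {
  if (patch_order_key(b) < patch_order_key(a)) {
    res <- patch_distance(b, a, phi1, phi2, phi3, seed_rmsd_max,
                          match_cutoff, min_match_frac, max_mappings)
    if (!is.null(res$mapping)) res$mapping <- res$mapping[, c(2, 1), drop = FALSE]
    if (!is.null(res$transform)) res$transform <- invert_transform(res$transform)
    return(res)
  }
  if (!patch_compatible(a, b, phi1, phi2, phi3))
    return(distance_result(Inf))
  xa <- patch_coords(a); xb <- patch_coords(b)
  ta <- a$types; tb <- b$types
  ia <- a$inner; ib <- b$inner
  maps <- proper_mappings(ta[ia], tb[ib], max_mappings)
  n_min <- min(nrow(xa), nrow(xb))
  need <- max(3L, ceiling(min_match_frac * n_min))
  best <- Inf; best_map <- NULL; best_tf <- NULL; seeds <- 0L
  for (mp in maps) {
    if (nrow(mp) < 3L) next          # too few pairs to define a rigid seed
    fit <- kabsch_superpose(xa[ia[mp[, 1]], , drop = FALSE],
                            xb[ib[mp[, 2]], , drop = FALSE])
    if (fit$rmsd >= seed_rmsd_max) next
    seeds <- seeds + 1L
    xb_tr <- apply_transform(xb, fit)
    full <- greedy_match(xa, ta, xb_tr, tb, match_cutoff)
    if (nrow(full) < need) next
    refit <- kabsch_superpose(xa[full[, 1], , drop = FALSE],
                              xb[full[, 2], , drop = FALSE])
    if (refit$rmsd < best) {
      best <- refit$rmsd
      best_map <- full
      best_tf <- refit[c("rotation", "translation")]
    }
  }
  if (!is.finite(best)) return(distance_result(Inf, seed_count = seeds))
  distance_result(best, best_map, best_tf, seed_count = seeds)
}

#' All-vs-all patch distance matrix
#'
#' Computes the heuristic patch distance for every unordered pair once; the
#' matrix is symmetric with a zero diagonal and `Inf` marking incompatible
#' (or unseedable) pairs.
#'
#' @param patches List of `surface_patch` objects (>= 2).
#' @param ... Passed to [patch_distance()].
#' @return Numeric matrix with patch ids as dimnames.
#' @export
pairwise_patch_distances <- function(patches, ...) {
  n <- length(patches)
  stopifnot(n >= 2)
  ids <- vapply(patches, function(p) p$id, character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- patch_distance(patches[[i]], patches[[j]], ...)$value
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}
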