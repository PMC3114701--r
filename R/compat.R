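# Scoring structures against a patch library: per-patch distance to the
# closest library element (DCLE), cluster-preference vectors and their
# Delta statistic, rank-sum tests, and native-vs-decoy model ranking.

#' Assign a patch to its closest library element
#'
#' Computes the heuristic patch distance to every centroid and returns the
#' argmin cluster with the DCLE (distance to the closest library element).
#' Ties go to the lowest cluster index; a patch incompatible with (or
#' unseedable against) every centroid gets cluster `NA` and infinite DCLE.
#'
#' @param patch A `surface_patch`.
#' @param library A `patch_library`.
#' @param ... Distance parameters passed to [patch_distance()].
#' @return List with `cluster` (integer or `NA`) and `dcle` (Angstrom or
#'   `Inf`).
#' @export
assign_patch <- function(patch, library, ...) {
  stopifnot(inherits(library, "patch_library"))
  d <- vapply(library$centroids,
              function(ct) patch_distance(patch, ct, ...)$value,
              numeric(1))
  if (all(!is.finite(d)))
    return(list(cluster = NA_integer_, dcle = Inf))
  list(cluster = which.min(d), dcle = min(d))
}

#' Profile a structure against a patch library
#'
#' Runs the full per-structure pipeline -- SASA, surface-atom selection,
#' patch extraction, per-patch library assignment -- and summarises the
#' result as a compatibility profile: the per-patch DCLE values and cluster
#' assignments, the cluster-preference vector F(Q) (fraction of assigned
#' patches closest to each centroid), the mean finite DCLE and the fraction
#' of patches with infinite DCLE.
#'
#' @param structure A `structure_model`.
#' @param library A `patch_library`.
#' @param thresholds A `surface_thresholds` table (the one the library was
#'   trained with).
#' @param radius Patch radius in Angstrom.
#' @param probe_radius,n_sphere_points SASA parameters, see
#'   [compute_sasa()].
#' @param ... Distance parameters passed to [patch_distance()].
#' @return A `compat_profile`: list with `source_id`, `patches` (data frame
#'   of id, cluster, dcle), `preference`, `mean_finite_dcle`,
#'   `frac_infinite` and `n_patches`.
#' @export
profile_structure <- function(structure, library, thresholds, radius = 7,
                              probe_radius = 1.4, n_sphere_points = 960,
                              ...) {
  sasa <- compute_sasa(structure, probe_radius, n_sphere_points)
  surf <- select_surface_atoms(structure, sasa, thresholds)
  patches <- extract_patches(structure, surf, radius = radius)
  k <- library$k
  src <- attr(structure, "identifier")
  if (length(patches) == 0L) {
    return(structure(
      list(source_id = src,
           patches = data.frame(id = character(0), cluster = integer(0),
                                dcle = numeric(0)),
           preference = rep(0, k),
           mean_finite_dcle = NA_real_,
           frac_infinite = NA_real_,
           n_patches = 0L,
           empty = TRUE),
      class = "compat_profile"))
  }
  asg <- lapply(patches, assign_patch, library = library, ...)
  cl <- vapply(asg, function(x) x$cluster, integer(1))
  dcle <- vapply(asg, function(x) x$dcle, numeric(1))
  assigned <- !is.na(cl)
  pref <- tabulate(cl[assigned], nbins = k)
  pref <- if (any(assigned)) pref / sum(assigned) else rep(0, k)
  structure(
    list(source_id = src,
         patches = data.frame(
           id = vapply(patches, function(p) p$id, character(1)),
           cluster = cl, dcle = dcle),
         preference = pref,
         mean_finite_dcle = if (any(is.finite(dcle)))
           mean(dcle[is.finite(dcle)]) else NA_real_,
         frac_infinite = mean(!is.finite(dcle)),
         n_patches = length(patches),
         empty = FALSE),
    class = "compat_profile")
}

#' @export
print.compat_profile <- function(x, ...) {
  cat("compat_profile '", x$source_id, "': ", x$n_patches, " patches, ",
      "mean finite DCLE = ", format(round(x$mean_finite_dcle, 3)),
      " A, infinite fraction = ", format(round(x$frac_infinite, 3)),
      "\n", sep = "")
  invisible(x)
}

#' Cluster-preference difference (Delta statistic)
#'
#' Element-wise absolute difference between two cluster-preference vectors,
#' `Delta_i = |f(Q0, C_i) - f(Q, C_i)|`.  Comparing a preference vector with
#' itself gives an all-zero Delta; the sum of Delta over clusters is bounded
#' by 2 (twice the total-variation distance).
#'
#' @param f0,fq Preference vectors of equal length (e.g. training set vs a
#'   query set).
#' @return Numeric vector of per-cluster Delta values.
#' @export
delta_preferences <- function(f0, fq) {
  if (length(f0) != length(fq))
    stop("preference vectors have different lengths (", length(f0), " vs ",
         length(fq), ")", call. = FALSE)
  abs(f0 - fq)
}

#' Wilcoxon rank-sum test tolerating infinite values
#'
#' Two-sided rank-sum test with normal approximation, tie correction and
#' continuity correction.  Infinite values are allowed: they rank above all
#' finite values (mutually tied), which is implemented by a rank-preserving
#' replacement before delegating to [stats::wilcox.test()].
#'
#' @param x,y Numeric samples (each >= 2 values); `Inf` allowed.
#' @return List with `statistic` (W, the Mann-Whitney count for `x`) and
#'   `p.value`.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  all_v <- c(x, y)
  finite <- all_v[is.finite(all_v)]
  repl <- if (length(finite) > 0) max(finite) + 1 else 1
  x2 <- ifelse(is.finite(x), x, repl)
  y2 <- ifelse(is.finite(y), y, repl)
  if (length(unique(c(x2, y2))) == 1L) {
    # identical constants: no evidence against the null
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  wt <- stats::wilcox.test(x2, y2, exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Score and rank candidate models of one target
#'
#' Profiles each model against the library and ranks them by a lexicographic
#' structure-level score: first the fraction of patches with infinite DCLE,
#' then the mean finite DCLE -- lower is better on both.  Ties keep input
#' order; a model with no patches ranks last and is flagged.
#'
#' @param models List of `structure_model` objects (>= 2), e.g. a native
#'   structure plus predicted decoys.
#' @param library A `patch_library`.
#' @param thresholds A `surface_thresholds` table.
#' @param ... Passed to [profile_structure()].
#' @return A `model_ranking` data frame with columns `model`,
#'   `frac_infinite`, `mean_dcle`, `n_patches`, `rank`, ordered best first.
#' @export
rank_models <- function(models, library, thresholds, ...) {
  stopifnot(length(models) >= 2)
  profiles <- lapply(models, profile_structure,
                     library = library, thresholds = thresholds, ...)
  frac_inf <- vapply(profiles, function(p)
    if (p$n_patches == 0L) Inf else p$frac_infinite, numeric(1))
  mean_d <- vapply(profiles, function(p)
    if (p$n_patches == 0L || is.na(p$mean_finite_dcle)) Inf
    else p$mean_finite_dcle, numeric(1))
  ord <- order(frac_inf, mean_d, seq_along(models))
  res <- data.frame(
    model = vapply(profiles, function(p) p$source_id, character(1)),
    frac_infinite = frac_inf,
    mean_dcle = mean_d,
    n_patches = vapply(profiles, function(p) p$n_patches, integer(1)),
    stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  res$rank <- seq_along(models)
  rownames(res) <- NULL
  attr(res, "profiles") <- profiles[ord]
  class(res) <- c("model_ranking", "data.frame")
  res
}
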