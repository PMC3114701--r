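# Seeded benchmark experiments: the random-ranking null and the synthetic
# native-vs-decoy discrimination study.  These are the package's own
# desk-scale replications of the checks a patch library is meant to pass;
# the methods vignette discusses what they do and do not show.

#' Native-first rate under uniformly random rankings
#'
#' Simulates rankings of `n_models` candidate models per target with the
#' native placed uniformly at random, and returns the percentage of trials
#' in which the native ranks first.  The expectation is 100/n_models
#' (16.67% for the native-plus-five-decoys setting).
#'
#' @param n_trials Number of simulated targets.
#' @param n_models Models per target (native included).
#' @param rng_seed Integer seed.
#' @return Percentage (0-100) of trials with the native ranked first.
#' @export
random_ranking_null <- function(n_trials = 2e7, n_models = 6, rng_seed = 1L) {
  stopifnot(n_trials >= 1, n_models >= 2)
  with_rng_seed(rng_seed, {
    hits <- 0
    remaining <- n_trials
    chunk <- 5e6
    while (remaining > 0) {
      m <- min(chunk, remaining)
      hits <- hits + sum(sample.int(n_models, m, replace = TRUE) == 1L)
      remaining <- remaining - m
    }
    100 * hits / n_trials
  })
}

#' Synthetic native-vs-decoy discrimination experiment
#'
#' The full desk-scale study: build a patch library from a seeded ensemble
#' of native-like structures ([make_native_ensemble()]), then over
#' `n_trials` trials rank a fresh native structure against `n_decoys`
#' decoys obtained by sigma = 2 A Gaussian perturbation, pooling native and
#' decoy DCLE values for a rank-sum test.  A separate sweep profiles
#' natives perturbed at each noise level in `sigmas` to trace how the DCLE
#' distribution degrades with model error.
#'
#' Mean finite DCLE values are reported on the extended real line: a pool
#' with no finite DCLE at all has mean `Inf` (every patch is incompatible
#' with the library).
#'
#' @param rng_seed Integer seed driving the ensemble, the library build and
#'   every trial.
#' @param n_trials Ranking trials.
#' @param n_decoys Decoys per trial.
#' @param decoy_sigma Decoy perturbation (Angstrom).
#' @param sigmas Noise levels of the DCLE sweep.
#' @param n_sigma_trials Natives profiled per noise level.
#' @param k Library size for the desk-scale corpus.
#' @param native_length Chain length of the query natives.
#' @return List with `native_first_pct`, `native_ranks`, `wilcoxon`
#'   (rank-sum test of native vs decoy DCLE pools), `sigma_summary` (data
#'   frame: sigma, mean_finite_dcle, frac_infinite, n_patches),
#'   `library_stats`, and the `library` itself.
#' @export
decoy_discrimination_experiment <- function(rng_seed = 1L, n_trials = 50,
                                            n_decoys = 5, decoy_sigma = 2,
                                            sigmas = c(0, 0.5, 1, 2),
                                            n_sigma_trials = 10, k = 25,
                                            native_length = 20) {
  ens <- make_native_ensemble(rng_seed = rng_seed)
  n_fam <- length(ens$motifs)
  config <- default_config()
  config$k <- k
  config$rng_seed <- rng_seed
  built <- build_library(ens$structures, config)
  lib <- built$library
  thr <- built$thresholds

  native_ranks <- integer(n_trials)
  native_pool <- numeric(0)
  decoy_pool <- numeric(0)
  for (tr in seq_len(n_trials)) {
    fam <- ((tr - 1L) %% n_fam) + 1L
    native <- ensemble_native(ens, fam, native_length,
                              identifier = paste0("native-", tr))
    decoys <- lapply(seq_len(n_decoys), function(j)
      perturb_structure(native, decoy_sigma,
                        rng_seed = rng_seed + 997L * tr + j))
    rk <- rank_models(c(list(native), decoys), lib, thr)
    native_ranks[tr] <- rk$rank[rk$model == paste0("native-", tr)]
    profs <- attr(rk, "profiles")
    for (p in profs) {
      if (p$source_id == paste0("native-", tr))
        native_pool <- c(native_pool, p$patches$dcle)
      else decoy_pool <- c(decoy_pool, p$patches$dcle)
    }
  }

  sigma_summary <- do.call(rbind, lapply(sigmas, function(sg) {
    vals <- numeric(0)
    for (tr in seq_len(n_sigma_trials)) {
      fam <- ((tr - 1L) %% n_fam) + 1L
      native <- ensemble_native(ens, fam, native_length)
      st <- perturb_structure(native, sg,
                              rng_seed = rng_seed + 7717L * tr +
                                round(1000 * sg))
      prof <- profile_structure(st, lib, thr)
      vals <- c(vals, prof$patches$dcle)
    }
    data.frame(sigma = sg,
               mean_finite_dcle = if (any(is.finite(vals)))
                 mean(vals[is.finite(vals)]) else Inf,
               frac_infinite = mean(!is.finite(vals)),
               n_patches = length(vals))
  }))

  list(native_first_pct = 100 * mean(native_ranks == 1L),
       native_ranks = native_ranks,
       wilcoxon = rank_sum_test(native_pool, decoy_pool),
       native_pool = native_pool,
       decoy_pool = decoy_pool,
       sigma_summary = sigma_summary,
       library_stats = list(n_patches = length(built$patches),
                            n_removed = length(built$weeded$removed),
                            k = lib$k),
       library = lib,
       thresholds = thr)
}
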