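# Surface atom selection by per-type SASA percentile thresholds, and
# extraction of surface patches around exposed beta-carbon pivots.

#' Fit per-atom-type surface-area thresholds
#'
#' For every atom type observed in the corpus (a type is a residue:atom pair,
#' see [atom_types()]), the threshold `access_surf_t` is a high percentile
#' (default the 99th) of the pooled SASA distribution of that type.  An atom
#' is later called a surface atom when its SASA is at least `alpha` times its
#' type's threshold.
#'
#' @param corpus A list whose elements are lists with components `structure`
#'   (a `structure_model`) and `sasa` (the matching [compute_sasa()] vector).
#' @param percentile Percentile of the per-type SASA distribution (0-100).
#' @param alpha Scale factor in (0, 1] applied to the threshold at selection
#'   time; stored with the table.
#' @return A `surface_thresholds` object: a named numeric vector of
#'   thresholds (Angstrom^2) with attributes `alpha`, `percentile` and
#'   `corpus_size`.
#' @export
fit_thresholds <- function(corpus, percentile = 99, alpha = 0.9) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  stopifnot(percentile > 0, percentile <= 100, alpha > 0, alpha <= 1)
  types <- unlist(lapply(corpus, function(el) atom_types(el$structure)))
  sasa <- unlist(lapply(corpus, function(el) {
    stopifnot(length(el$sasa) == nrow(el$structure))
    el$sasa
  }))
  # type 7 quantile: sorted-values linear interpolation
  thr <- tapply(sasa, types, stats::quantile,
                probs = percentile / 100, type = 7, names = FALSE)
  thr <- stats::setNames(as.numeric(thr), names(thr))
  structure(thr,
            alpha = alpha,
            percentile = percentile,
            corpus_size = length(corpus),
            class = "surface_thresholds")
}

#' @export
print.surface_thresholds <- function(x, ...) {
  cat("surface_thresholds:", length(x), "atom types, alpha =",
      attr(x, "alpha"), ", percentile =", attr(x, "percentile"),
      ", corpus of", attr(x, "corpus_size"), "structures\n")
  invisible(x)
}

#' Select solvent-exposed (surface) atoms
#'
#' Atom `i` of type `t` is a surface atom iff `sasa[i] >= alpha *
#' access_surf_t` (inclusive boundary).  Atoms whose type was never seen when
#' fitting the threshold table are never selected and trigger a warning.
#'
#' @param structure A `structure_model`.
#' @param sasa SASA vector aligned with `structure`.
#' @param thresholds A `surface_thresholds` table from [fit_thresholds()].
#' @return Integer vector of surface atom indices (in structure order).
#' @export
select_surface_atoms <- function(structure, sasa, thresholds) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(thresholds, "surface_thresholds"))
  if (length(sasa) != nrow(structure))
    stop("sasa vector not aligned with structure", call. = FALSE)
  types <- atom_types(structure)
  thr <- unname(unclass(thresholds)[types])
  unseen <- is.na(thr)
  if (any(unseen))
    warning(sum(unseen), " atoms of ", length(unique(types[unseen])),
            " types absent from the threshold table; never surface",
            call. = FALSE)
  alpha <- attr(thresholds, "alpha")
  which(!unseen & sasa >= alpha * thr)
}

#' Radius of gyration of a set of atoms
#'
#' Unweighted: the root-mean-square distance of the atoms from their
#' geometric centroid.
#'
#' @param atoms A data frame with `x`, `y`, `z` columns, or a numeric matrix
#'   with 3 columns.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(atoms) {
  xyz <- if (is.matrix(atoms)) atoms else as.matrix(atoms[, c("x", "y", "z")])
  stopifnot(nrow(xyz) >= 1)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Construct a surface patch from an atom table
#'
#' Builds a `surface_patch` from a table of (surface) atoms: annotates atom
#' types, tallies the chemical composition, computes the radius of gyration
#' and the pivot-centred inner sphere.  [extract_patches()] is the usual way
#' to obtain patches from a structure; this constructor is exposed for
#' synthetic patches.
#'
#' @param atoms Data frame of atom records (columns as in a
#'   `structure_model`).
#' @param pivot_index Row index of the pivot atom within `atoms`.
#' @param radius Patch radius in Angstrom.
#' @param source_id Identifier of the originating structure.
#' @param id Patch identifier; derived from source and pivot when `NULL`.
#' @return A `surface_patch` object.
#' @export
make_patch <- function(atoms, pivot_index = 1L, radius = 7,
                       source_id = "synthetic", id = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1,
            pivot_index >= 1, pivot_index <= nrow(atoms))
  rownames(atoms) <- NULL
  types <- atom_types(atoms)
  pv <- atoms[pivot_index, ]
  if (is.null(id))
    id <- paste0(source_id, "/", pv$chain, pv$resno, pv$insert, ":", pv$atom)
  p <- structure(
    list(id = id,
         source_id = source_id,
         pivot_index = as.integer(pivot_index),
         atoms = atoms,
         types = types,
         radius = radius,
         composition = table(types),
         rg = radius_of_gyration(atoms),
         inner = integer(0),
         inner_radius = NA_real_,
         small = FALSE),
    class = "surface_patch")
  compute_inner_sphere(p)
}

#' @export
print.surface_patch <- function(x, ...) {
  cat("surface_patch '", x$id, "': ", nrow(x$atoms), " atoms (",
      length(x$inner), " inner, r_in = ", format(x$inner_radius),
      "), rg = ", format(round(x$rg, 2)), " A",
      if (x$small) ", small" else "", "\n", sep = "")
  invisible(x)
}

patch_coords <- function(patch) as.matrix(patch$atoms[, c("x", "y", "z")])

#' Compute the inner sphere of a patch
#'
#' The inner sphere is a pivot-centred subsphere used to seed the distance
#' heuristic.  Its radius is found by a descending scan from the patch radius
#' in 0.25 Angstrom steps: the largest scanned radius holding at most 9 patch
#' atoms is taken, which prefers the largest atom count not exceeding 9.  If
#' no radius yields at least 4 atoms the whole patch is its own inner sphere
#' and the patch is flagged `small`.
#'
#' @param patch A `surface_patch`.
#' @return The patch with `inner` (atom indices), `inner_radius` and `small`
#'   filled in.
#' @export
compute_inner_sphere <- function(patch) {
  stopifnot(inherits(patch, "surface_patch"))
  xyz <- patch_coords(patch)
  pv <- xyz[patch$pivot_index, ]
  d <- sqrt(rowSums(sweep(xyz, 2, pv)^2))
  n <- nrow(xyz)
  if (n <= 9L) {
    patch$inner <- seq_len(n)
    patch$inner_radius <- patch$radius
    patch$small <- n < 4L
    return(patch)
  }
  radii <- seq(patch$radius, 0.25, by = -0.25)
  counts <- vapply(radii, function(r) sum(d <= r), integer(1))
  ok <- which(counts <= 9L)
  if (length(ok) == 0L || counts[ok[1]] < 4L) {
    # pathological shell: fall back to the 9 atoms nearest the pivot
    patch$inner <- order(d)[seq_len(min(9L, n))]
    patch$inner_radius <- max(d[patch$inner])
    patch$small <- length(patch$inner) < 4L
    return(patch)
  }
  r_in <- radii[ok[1]]
  patch$inner <- which(d <= r_in)
  patch$inner_radius <- r_in
  patch$small <- FALSE
  patch
}

#' Extract surface patches around exposed beta-carbons
#'
#' A patch is the set of surface atoms within `radius` of a pivot -- a
#' solvent-exposed beta-carbon (atom name `"CB"`) -- plus the pivot itself.
#' Every exposed CB yields one patch; patches typically overlap.  Glycine has
#' no CB and contributes no pivots (its surface atoms still appear inside
#' other residues' patches).
#'
#' @param structure A `structure_model`.
#' @param surface Integer indices of surface atoms from
#'   [select_surface_atoms()].
#' @param radius Patch radius in Angstrom (inclusive boundary).
#' @return A list of `surface_patch` objects (possibly empty).
#' @export
extract_patches <- function(structure, surface, radius = 7) {
  stopifnot(inherits(structure, "structure_model"),
            all(surface >= 1), all(surface <= nrow(structure)))
  surface <- sort(unique(as.integer(surface)))
  surf_atoms <- structure[surface, , drop = FALSE]
  xyz <- as.matrix(surf_atoms[, c("x", "y", "z")])
  pivots <- which(surf_atoms$atom == "CB")
  src <- attr(structure, "identifier")
  lapply(pivots, function(pi) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[pi, ])^2))
    member <- which(d <= radius)
    make_patch(surf_atoms[member, , drop = FALSE],
               pivot_index = match(pi, member),
               radius = radius, source_id = src)
  })
}
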