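# Seeded synthetic structures, patches and planted-cluster datasets.
#
# The generator produces mini-protein-like structures: ideal backbone
# geometry (helical, extended, or coil CA traces with 3.8 A CA-CA spacing),
# C-beta atoms placed away from the local chain direction, and short
# side-chain stubs per residue type.  These are not physically realistic
# proteins -- they exist so that every pipeline stage (SASA, surface
# selection, patch extraction, distances, clustering, scoring) can be
# exercised deterministically without external data.

# side-chain stub atoms beyond CB, per residue type
SIDECHAIN_STUBS <- list(
  ALA = character(0), SER = "OG", CYS = "SG",
  VAL = c("CG1", "CG2"), THR = c("OG1", "CG2"),
  LEU = c("CG", "CD1"), ILE = c("CG1", "CD1"),
  ASP = c("CG", "OD1"), ASN = c("CG", "OD1"),
  GLU = c("CG", "CD"), GLN = c("CG", "CD"),
  LYS = c("CG", "CD"), ARG = c("CG", "CD"),
  MET = c("CG", "SD"), PHE = c("CG", "CD1"),
  TYR = c("CG", "CD1"), TRP = c("CG", "CD1"),
  HIS = c("CG", "ND1"), PRO = c("CG", "CD")
)

DEFAULT_PALETTE <- c("ALA", "SER", "VAL", "LEU", "ASP", "LYS", "PHE", "THR")

element_of <- function(atom_name) substr(gsub("[0-9]", "", atom_name), 1, 1)

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(1, 0, 0) else v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Random rigid transform
#'
#' A uniformly random proper rotation (QR of a Gaussian matrix, sign-fixed)
#' plus a random translation, for rigid-invariance experiments.
#'
#' @param rng_seed Integer seed.
#' @param translation_scale Standard deviation of the translation (Angstrom).
#' @return List with `rotation` (3x3) and `translation` (length 3).
#' @export
random_rigid_transform <- function(rng_seed = 1L, translation_scale = 10) {
  with_rng_seed(rng_seed, {
    m <- matrix(stats::rnorm(9), 3, 3)
    qr_d <- qr(m)
    q <- qr.Q(qr_d)
    q <- q %*% diag(sign(diag(qr.R(qr_d))))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    list(rotation = q,
         translation = stats::rnorm(3, sd = translation_scale))
  })
}

#' Apply a rigid transform to a structure or patch
#'
#' @param x A `structure_model` or `surface_patch`.
#' @param transform List with `rotation` and `translation`, e.g. from
#'   [random_rigid_transform()].
#' @return Object of the same class with transformed coordinates (patch
#'   invariants recomputed).
#' @export
transform_coords <- function(x, transform) {
  if (inherits(x, "surface_patch")) {
    at <- x$atoms
    xyz <- apply_transform(as.matrix(at[, c("x", "y", "z")]), transform)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    return(make_patch(at, pivot_index = x$pivot_index, radius = x$radius,
                      source_id = x$source_id, id = x$id))
  }
  stopifnot(inherits(x, "structure_model"))
  xyz <- apply_transform(as.matrix(x[, c("x", "y", "z")]), transform)
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}

ca_trace <- function(n, geometry) {
  if (geometry == "helix") {
    i <- seq_len(n) - 1
    theta <- i * 100 * pi / 180
    list(ca = cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i),
         out = cbind(cos(theta), sin(theta), 0))
  } else if (geometry == "sheet") {
    i <- seq_len(n) - 1
    list(ca = cbind(3.3 * i, 0.95 * (-1)^i, 0),
         out = cbind(0, 0, (-1)^i))
  } else { # coil: seeded self-avoiding-ish random walk
    ca <- matrix(0, n, 3)
    dir <- unit(stats::rnorm(3))
    for (i in seq(2, n)) {
      for (try in seq_len(60)) {
        nd <- unit(dir + 0.7 * stats::rnorm(3))
        cand <- ca[i - 1, ] + 3.8 * nd
        if (i <= 3) break
        d <- sqrt(rowSums(sweep(ca[seq_len(i - 2), , drop = FALSE], 2,
                                cand)^2))
        if (all(d > 3.5)) break
      }
      ca[i, ] <- cand
      dir <- nd
    }
    out <- t(vapply(seq_len(n), function(i) {
      tangent <- if (i == 1) ca[2, ] - ca[1, ]
      else if (i == n) ca[n, ] - ca[n - 1, ]
      else ca[i + 1, ] - ca[i - 1, ]
      unit(cross3(unit(tangent), unit(stats::rnorm(3))))
    }, numeric(3)))
    list(ca = ca, out = out)
  }
}

#' Generate a synthetic mini-protein structure
#'
#' Builds a deterministic mini-protein: CA trace with ideal 3.8 A spacing in
#' the requested geometry, backbone N/C/O atoms, CB atoms pointing away from
#' the local chain direction, and 0-2 side-chain stub atoms per residue
#' type.  Glycine gets no CB.  Coordinates are rounded to 3 decimals (PDB
#' precision) so structures round-trip exactly through [write_pdb()] /
#' [read_pdb()].
#'
#' @param n_residues Number of residues (>= 3).
#' @param geometry One of `"helix"`, `"sheet"`, `"coil"`.
#' @param rng_seed Integer seed (residue sampling, coil walk, noise).
#' @param noise_sigma Isotropic Gaussian coordinate noise in Angstrom.
#' @param palette Residue names to sample from.
#' @param sequence Optional fixed residue sequence (character vector of
#'   length `n_residues`); overrides palette sampling, so different seeds
#'   give noise realisations of the same "protein".
#' @param identifier Structure identifier.
#' @return A `structure_model`.
#' @export
make_structure <- function(n_residues = 12, geometry = c("helix", "sheet", "coil"),
                           rng_seed = 1L, noise_sigma = 0,
                           palette = DEFAULT_PALETTE,
                           sequence = NULL,
                           identifier = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 3, noise_sigma >= 0,
            all(palette %in% STANDARD_RESIDUES))
  if (!is.null(sequence))
    stopifnot(length(sequence) == n_residues,
              all(sequence %in% STANDARD_RESIDUES))
  if (is.null(identifier))
    identifier <- paste0("syn-", geometry, "-", n_residues, "-s", rng_seed)
  with_rng_seed(rng_seed, {
    resnames <- if (is.null(sequence)) sample(palette, n_residues,
                                              replace = TRUE) else sequence
    tr <- ca_trace(n_residues, geometry)
    ca <- tr$ca; out <- tr$out
    rows <- vector("list", n_residues)
    for (i in seq_len(n_residues)) {
      prev <- if (i == 1) ca[i, ] - (ca[i + 1, ] - ca[i, ]) else ca[i - 1, ]
      nxt <- if (i == n_residues) ca[i, ] + (ca[i, ] - ca[i - 1, ]) else ca[i + 1, ]
      u_prev <- unit(prev - ca[i, ])
      u_next <- unit(nxt - ca[i, ])
      o_i <- out[i, ]
      names_i <- c("N", "CA", "C", "O")
      pos <- rbind(
        ca[i, ] + 1.46 * unit(u_prev + 0.30 * o_i),
        ca[i, ],
        ca[i, ] + 1.52 * unit(u_next - 0.20 * o_i),
        ca[i, ] + 1.52 * unit(u_next - 0.20 * o_i) +
          1.23 * unit(cross3(u_next, o_i) + 0.30 * o_i)
      )
      if (resnames[i] != "GLY") {
        b <- -(u_prev + u_next)
        cb_dir <- if (sqrt(sum(b^2)) > 1e-3) unit(unit(b) + 0.5 * o_i) else o_i
        cb <- ca[i, ] + 1.53 * cb_dir
        names_i <- c(names_i, "CB")
        pos <- rbind(pos, cb)
        stubs <- SIDECHAIN_STUBS[[resnames[i]]]
        if (length(stubs) > 0) {
          perp <- unit(cross3(cb_dir, u_next))
          for (s in seq_along(stubs)) {
            sign_s <- if (s == 1) 1 else -1
            pos <- rbind(pos, cb + 1.52 * unit(cb_dir + sign_s * 0.6 * perp))
            names_i <- c(names_i, stubs[s])
          }
        }
      }
      rows[[i]] <- data.frame(
        chain = "A", resno = i, insert = "", resname = resnames[i],
        atom = names_i, element = element_of(names_i),
        x = pos[, 1], y = pos[, 2], z = pos[, 3], occupancy = 1,
        stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    if (noise_sigma > 0) {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), sd = noise_sigma)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), sd = noise_sigma)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), sd = noise_sigma)
    }
    atoms$x <- round(atoms$x, 3)
    atoms$y <- round(atoms$y, 3)
    atoms$z <- round(atoms$z, 3)
    new_structure_model(atoms, identifier)
  })
}

#' Perturb a structure with isotropic Gaussian noise
#'
#' Adds a seeded Gaussian displacement to every atom; a crude stand-in for
#' the coordinate error of predicted decoy models.
#'
#' @param structure A `structure_model`.
#' @param sigma Per-coordinate standard deviation in Angstrom (>= 0).
#' @param rng_seed Integer seed.
#' @param identifier Identifier of the perturbed copy.
#' @return A `structure_model`.
#' @export
perturb_structure <- function(structure, sigma, rng_seed = 1L,
                              identifier = NULL) {
  stopifnot(inherits(structure, "structure_model"), sigma >= 0)
  if (is.null(identifier))
    identifier <- paste0(attr(structure, "identifier"),
                         "-p", sigma, "-s", rng_seed)
  if (sigma == 0) {
    attr(structure, "identifier") <- identifier
    return(structure)
  }
  with_rng_seed(rng_seed, {
    n <- nrow(structure)
    structure$x <- round(structure$x + stats::rnorm(n, sd = sigma), 3)
    structure$y <- round(structure$y + stats::rnorm(n, sd = sigma), 3)
    structure$z <- round(structure$z + stats::rnorm(n, sd = sigma), 3)
    attr(structure, "identifier") <- identifier
    structure
  })
}

#' Generate an ensemble of native-like synthetic structures
#'
#' Emulates a training corpus of solved structures as a set of structure
#' "families": each family is a periodic two-residue sequence motif on an
#' idealised backbone, and its members are chain-length variants of that
#' motif.  Because the local environment of a mid-chain pivot repeats both
#' along a chain and across members (translational periodicity, as on real
#' beta-sheet surfaces), patch chemical compositions and geometries recur
#' throughout the ensemble -- the property of real corpora that makes
#' surface patches clusterable under the strict compatibility pre-filter.
#'
#' @param n_families Number of distinct sequence motifs.
#' @param lengths Chain lengths of the members of each family.
#' @param geometry Backbone geometry (see [make_structure()]).
#' @param rng_seed Integer seed (motif sampling).
#' @param palette Residues to draw the family motifs from.
#' @return List with `structures` (length `n_families * length(lengths)`),
#'   `motifs` (per-family residue pairs) and `family` (family index per
#'   structure).
#' @export
make_native_ensemble <- function(n_families = 4,
                                 lengths = c(10, 12, 14, 16, 18),
                                 geometry = "sheet", rng_seed = 1L,
                                 palette = DEFAULT_PALETTE) {
  stopifnot(n_families >= 1, all(lengths >= 3))
  stopifnot(2 * n_families <= length(palette))
  motifs <- with_rng_seed(rng_seed, {
    # disjoint residue pairs, one per family: residues are not shared
    # between families, so each atom type's exposure statistics come from
    # one family's recurring environment only
    shuffled <- sample(palette)
    lapply(seq_len(n_families), function(f) shuffled[c(2 * f - 1, 2 * f)])
  })
  structures <- list(); family <- integer(0)
  for (f in seq_len(n_families)) {
    for (l in lengths) {
      sq <- rep(motifs[[f]], length.out = l)
      structures <- c(structures, list(make_structure(
        l, geometry, rng_seed = rng_seed,
        sequence = sq,
        identifier = paste0("native-f", f, "-n", l))))
      family <- c(family, f)
    }
  }
  list(structures = structures, motifs = motifs, family = family)
}

#' Synthetic native structure of an ensemble family
#'
#' A fresh member of one of the ensemble's families at a chain length not
#' necessarily present in the training corpus; its mid-chain patches match
#' the family's recurring patches while its termini do not.
#'
#' @param ensemble Result of [make_native_ensemble()].
#' @param family Family index.
#' @param n_residues Chain length.
#' @param geometry Backbone geometry (must match the ensemble's).
#' @param identifier Structure identifier.
#' @return A `structure_model`.
#' @export
ensemble_native <- function(ensemble, family = 1L, n_residues = 20,
                            geometry = "sheet", identifier = NULL) {
  sq <- rep(ensemble$motifs[[family]], length.out = n_residues)
  if (is.null(identifier))
    identifier <- paste0("native-f", family, "-n", n_residues, "-query")
  make_structure(n_residues, geometry, rng_seed = 1L, sequence = sq,
                 identifier = identifier)
}

# Distinct atom types used for synthetic template patches; distinct types
# keep the proper-mapping enumeration unique and cheap.
PLANTED_TYPES <- c("SER:OG", "VAL:CG1", "LEU:CD1", "ASP:OD1",
                   "LYS:CD", "PHE:CG", "THR:OG1", "ASN:OD1")

patch_atoms_from_types <- function(types, xyz) {
  parts <- strsplit(types, ":", fixed = TRUE)
  data.frame(
    chain = "A", resno = seq_along(types), insert = "",
    resname = vapply(parts, `[`, character(1), 1),
    atom = vapply(parts, `[`, character(1), 2),
    element = element_of(vapply(parts, `[`, character(1), 2)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    stringsAsFactors = FALSE)
}

# Random patch geometry: pivot at origin, remaining atoms at 2.5-6 A from
# the pivot with >= 1.8 A between atoms (rejection sampling).
random_patch_geometry <- function(n_atoms) {
  xyz <- matrix(0, n_atoms, 3)
  for (i in seq(2, n_atoms)) {
    repeat {
      v <- unit(stats::rnorm(3)) * stats::runif(1, 2.5, 6)
      d <- sqrt(rowSums(sweep(xyz[seq_len(i - 1), , drop = FALSE], 2, v)^2))
      if (all(d > 1.8)) break
    }
    xyz[i, ] <- v
  }
  xyz
}

#' Generate a random synthetic surface patch
#'
#' A pivot CB at the origin plus `n_atoms - 1` typed atoms at realistic
#' spacing (2.5-6 A from the pivot, >= 1.8 A apart).
#'
#' @param n_atoms Total atom count (2-9).
#' @param rng_seed Integer seed.
#' @param pivot_type Type of the pivot atom.
#' @param max_type_mult Maximum multiplicity of any non-pivot type.
#' @return A `surface_patch`.
#' @export
make_random_patch <- function(n_atoms = 7, rng_seed = 1L,
                              pivot_type = "ALA:CB", max_type_mult = 2) {
  stopifnot(n_atoms >= 2, n_atoms <= 9)
  with_rng_seed(rng_seed, {
    pool <- rep(PLANTED_TYPES, max_type_mult)
    types <- c(pivot_type, sample(pool, n_atoms - 1))
    xyz <- random_patch_geometry(n_atoms)
    make_patch(patch_atoms_from_types(types, xyz), pivot_index = 1L,
               source_id = paste0("rand-s", rng_seed))
  })
}

#' Generate a compatible patch pair (template and noisy rigid copy)
#'
#' The second patch is a rigid-transformed copy of the first with its
#' non-pivot atoms listed in a random order and optional Gaussian coordinate
#' noise -- compatible by construction, with a known small distance.
#'
#' @param n_atoms Atom count (<= 9 so the exact oracle applies).
#' @param noise_sigma Per-coordinate Gaussian noise on the copy (Angstrom).
#' @param rng_seed Integer seed.
#' @return List with patches `a` and `b`.
#' @export
make_patch_pair <- function(n_atoms = 7, noise_sigma = 0.2, rng_seed = 1L) {
  a <- make_random_patch(n_atoms, rng_seed = rng_seed)
  with_rng_seed(rng_seed + 1000003L, {
    at <- a$atoms
    perm <- c(1L, 1L + sample(nrow(at) - 1L))
    at <- at[perm, , drop = FALSE]
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sigma),
                          ncol = 3)
    tf <- list(rotation = random_rigid_transform(rng_seed + 7L)$rotation,
               translation = stats::rnorm(3, sd = 8))
    xyz <- apply_transform(xyz, tf)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    b <- make_patch(at, pivot_index = 1L,
                    source_id = paste0(a$source_id, "-copy"))
    list(a = a, b = b)
  })
}

#' Generate planted patch clusters with known labels
#'
#' Builds `k_groups` template patches sharing one chemical composition
#' (distinct atom types, so every pair is compatible and the proper mapping
#' is unique) but with distinct geometries, then emits `per_group` noisy
#' copies of each.  A construction check guarantees that the smallest
#' inter-group exact distance exceeds 3x the largest intra-group distance;
#' failing that, generation retries with a derived seed (bounded, then
#' errors).
#'
#' @param k_groups Number of planted groups (>= 2).
#' @param per_group Copies per group.
#' @param intra_noise Per-coordinate noise within a group (Angstrom).
#' @param rng_seed Integer seed.
#' @param n_atoms Atoms per patch (<= 8 so the exact oracle applies).
#' @param max_tries Construction-check retries.
#' @return List with `patches` (length `k_groups * per_group`) and `labels`
#'   (integer group ids).
#' @export
make_planted_patches <- function(k_groups = 3, per_group = 20,
                                 intra_noise = 0.3, rng_seed = 1L,
                                 n_atoms = 7, max_tries = 20) {
  stopifnot(k_groups >= 2, n_atoms >= 5, n_atoms <= 8)
  types <- c("ALA:CB", PLANTED_TYPES[seq_len(n_atoms - 1)])
  for (try_i in seq_len(max_tries)) {
    seed_i <- rng_seed + 7919L * (try_i - 1L)
    res <- with_rng_seed(seed_i, {
      templates <- lapply(seq_len(k_groups), function(g) {
        xyz <- random_patch_geometry(n_atoms)
        make_patch(patch_atoms_from_types(types, xyz), pivot_index = 1L,
                   source_id = paste0("group", g))
      })
      patches <- list(); labels <- integer(0)
      max_intra <- 0
      for (g in seq_len(k_groups)) {
        txyz <- patch_coords(templates[[g]])
        for (r in seq_len(per_group)) {
          xyz <- txyz
          if (intra_noise > 0)
            xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = intra_noise),
                                ncol = 3)
          p <- make_patch(patch_atoms_from_types(types, xyz),
                          pivot_index = 1L,
                          source_id = paste0("group", g, "-", r))
          d <- exact_patch_distance(p, templates[[g]])$value
          max_intra <- max(max_intra, d)
          patches <- c(patches, list(p))
          labels <- c(labels, g)
        }
      }
      min_inter <- Inf
      for (g in seq_len(k_groups - 1)) {
        for (h in seq(g + 1, k_groups)) {
          d <- exact_patch_distance(templates[[g]], templates[[h]])$value
          min_inter <- min(min_inter, d)
        }
      }
      ok <- is.finite(min_inter) && min_inter > 3 * max_intra
      list(ok = ok,
           patches = patches, labels = labels,
           templates = templates,
           min_inter = min_inter, max_intra = max_intra)
    })
    if (res$ok) return(res)
  }
  stop("could not construct planted clusters with the required separation",
       call. = FALSE)
}
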