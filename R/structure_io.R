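# Reading protein structures into a typed atom model and annotating them
# with solvent-accessible surface area (SASA).

#' Standard amino-acid residue names
#'
#' Three-letter codes of the 20 standard amino acids.  Only atoms of these
#' residues are kept by [read_pdb()].
#' @export
STANDARD_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Build a structure model from an atom table
#'
#' Validates an atom table and attaches the `structure_model` class and the
#' identifier.  Required columns: `chain`, `resno`, `insert`, `resname`,
#' `atom`, `element`, `x`, `y`, `z`, `occupancy`.  [read_pdb()] and
#' [make_structure()] are the usual constructors; this one serves direct
#' construction from data.
#'
#' @param atoms Data frame of atom records.
#' @param identifier Structure identifier string.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, identifier = "structure") {
  new_structure_model(atoms, identifier)
}

new_structure_model <- function(atoms, identifier) {
  required <- c("chain", "resno", "insert", "resname", "atom", "element",
                "x", "y", "z", "occupancy")
  stopifnot(is.data.frame(atoms), all(required %in% names(atoms)))
  if (nrow(atoms) == 0L)
    stop("structure '", identifier, "' contains no standard amino-acid atoms",
         call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates in '", identifier, "'", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) records after altloc resolution in '",
         identifier, "'", call. = FALSE)
  rownames(atoms) <- NULL
  structure(atoms,
            identifier = identifier,
            class = c("structure_model", "data.frame"))
}

#' Read a protein structure from a PDB file
#'
#' Reads the first model of a PDB file and returns the heavy atoms of the 20
#' standard amino acids as a `structure_model` (a data frame of atom records
#' with an `identifier` attribute).  Hydrogens, waters, and HETATM records
#' are discarded; alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by file order).
#'
#' @param path Path to a PDB file.
#' @param identifier Structure identifier; defaults to the file name without
#'   extension.
#' @return A `structure_model` data frame with columns `chain`, `resno`,
#'   `insert`, `resname`, `atom`, `element`, `x`, `y`, `z`, `occupancy`.
#' @export
read_pdb <- function(path, identifier = NULL) {
  if (!file.exists(path))
    stop("cannot read PDB file: ", path, call. = FALSE)
  if (is.null(identifier))
    identifier <- sub("\\.[^.]*$", "", basename(path))
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% STANDARD_RESIDUES, , drop = FALSE]
  if (nrow(at) > 0L) {
    elem <- at$elesy
    missing_elem <- is.na(elem) | elem == ""
    elem[missing_elem] <- substr(gsub("[0-9]", "", at$elety[missing_elem]), 1, 1)
    at$elesy <- toupper(elem)
    at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  }
  if (nrow(at) == 0L)
    stop("no standard amino-acid ATOM records in ", path, call. = FALSE)

  # altloc resolution: keep highest occupancy per (chain, resno, insert, atom);
  # ties go to the record that appears first in the file.
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety)
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(rownames(at), rownames(pdb$atom))), , drop = FALSE]

  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom = at$elety,
    element = at$elesy,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  new_structure_model(atoms, identifier)
}

#' Write a structure model to a PDB file
#'
#' @param structure A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "structure_model"))
  xyz <- as.vector(t(as.matrix(structure[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = rep("ATOM", nrow(structure)),
    resno = structure$resno,
    resid = structure$resname,
    insert = structure$insert,
    chain = structure$chain,
    elety = structure$atom,
    o = structure$occupancy,
    b = rep(0, nrow(structure)),
    elesy = structure$element
  )
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model '", attr(x, "identifier"), "': ",
      nrow(x), " atoms, ",
      length(unique(paste(x$chain, x$resno, x$insert))), " residues\n",
      sep = "")
  invisible(x)
}

#' Atom type labels
#'
#' The chemical type of an atom is the pair (residue name, atom name), e.g.
#' `"ALA:CB"`; an alanine C-beta and a serine C-beta are different types.
#'
#' @param structure A `structure_model` or any data frame with `resname` and
#'   `atom` columns.
#' @return Character vector of type labels, one per atom.
#' @export
atom_types <- function(structure) {
  paste(structure$resname, structure$atom, sep = ":")
}

# Van der Waals radii (Angstrom), Chothia-style: carbonyl carbon is smaller
# than aliphatic/aromatic carbon.
vdw_radius <- function(atom_name, element) {
  r <- rep(1.80, length(element))
  r[element == "C"] <- 1.87
  r[element == "C" & atom_name == "C"] <- 1.76
  r[element == "N"] <- 1.65
  r[element == "O"] <- 1.40
  r[element == "S"] <- 1.85
  r
}

# Deterministic, nearly uniform unit sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area
#'
#' Computes SASA for every atom by the Shrake-Rupley sphere-sampling
#' algorithm: each atom's van der Waals sphere is inflated by the probe
#' radius and sampled with a deterministic point lattice; points not buried
#' inside any neighbouring inflated sphere count as accessible.
#'
#' @param structure A `structure_model`.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points Number of quadrature points per atom (>= 100).
#' @return Numeric vector of SASA values (Angstrom^2), aligned with the
#'   structure's atoms.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960) {
  stopifnot(inherits(structure, "structure_model"),
            probe_radius > 0, n_sphere_points >= 100)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  n <- nrow(xyz)
  radii <- vdw_radius(structure$atom, structure$element) + probe_radius
  pts <- sphere_points(n_sphere_points)

  d2 <- as.matrix(stats::dist(xyz))^2
  diag(d2) <- Inf
  if (any(d2 < 1e-12))
    stop("degenerate geometry: two atoms share identical coordinates",
         call. = FALSE)

  sasa <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose inflated sphere can reach atom i's sampling sphere
    reach <- (radii[i] + radii)^2
    nb <- which(d2[i, ] < reach)
    p <- pts * radii[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    accessible <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(accessible)) break
      dx <- p[accessible, 1] - xyz[j, 1]
      dy <- p[accessible, 2] - xyz[j, 2]
      dz <- p[accessible, 3] - xyz[j, 3]
      accessible[accessible] <- (dx * dx + dy * dy + dz * dz) >= radii[j]^2
    }
    sasa[i] <- mean(accessible) * 4 * pi * radii[i]^2
  }
  sasa
}
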