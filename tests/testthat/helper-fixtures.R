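# Shared test fixtures, built in code.

# minimal structure_model from typed coordinates
tiny_structure <- function(xyz, resname = "ALA", atom = "CB",
                           identifier = "tiny") {
  n <- nrow(xyz)
  structure_model(data.frame(
    chain = "A", resno = seq_len(n), insert = "",
    resname = rep_len(resname, n), atom = rep_len(atom, n),
    element = substr(gsub("[0-9]", "", rep_len(atom, n)), 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    stringsAsFactors = FALSE), identifier)
}

# patch built directly from types and coordinates (pivot = first row)
typed_patch <- function(types, xyz, source_id = "test") {
  parts <- strsplit(types, ":", fixed = TRUE)
  atoms <- data.frame(
    chain = "A", resno = seq_along(types), insert = "",
    resname = vapply(parts, `[`, character(1), 1),
    atom = vapply(parts, `[`, character(1), 2),
    element = substr(gsub("[0-9]", "", vapply(parts, `[`, character(1), 2)),
                     1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    stringsAsFactors = FALSE)
  make_patch(atoms, pivot_index = 1L, source_id = source_id)
}

# a PDB ATOM record in fixed-column format
pdb_atom_line <- function(serial, name, resname, resno, x, y, z,
                          altloc = " ", occ = 1, element = NULL,
                          record = "ATOM") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, altloc, resname, "A", resno, x, y, z,
          occ, 0, element)
}

# fraction of infinite values, NA-free
frac_inf <- function(x) mean(!is.finite(x))

# adjusted Rand index (independent of the clustering implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
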