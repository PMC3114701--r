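# Plain-text, versioned serialization: threshold tables, patch files,
# distance matrices, and library bundles.

FORMAT_VERSION <- "patchlib-v1"

#' Write / read a surface-threshold table
#'
#' Two-column tab-separated table (atom type, threshold in Angstrom^2) with
#' header comments recording alpha, the percentile and the corpus size.
#'
#' @param thresholds A `surface_thresholds` object.
#' @param path File path.
#' @return `path` invisibly; `read_thresholds()` returns the table.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "surface_thresholds"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ", FORMAT_VERSION, " thresholds"),
    sprintf("# alpha=%.6g percentile=%.6g corpus_size=%d",
            attr(thresholds, "alpha"), attr(thresholds, "percentile"),
            attr(thresholds, "corpus_size")),
    "type\tthreshold",
    sprintf("%s\t%.6f", names(thresholds), as.numeric(thresholds))
  ), con)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  header <- meta[grepl("alpha=", meta)][1]
  get_num <- function(key) {
    as.numeric(sub(paste0(".*", key, "=([0-9.eE+-]+).*"), "\\1", header))
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]  # column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  thr <- as.numeric(vapply(parts, `[`, character(1), 2))
  names(thr) <- vapply(parts, `[`, character(1), 1)
  structure(thr,
            alpha = get_num("alpha"),
            percentile = get_num("percentile"),
            corpus_size = as.integer(get_num("corpus_size")),
            class = "surface_thresholds")
}

#' Write / read surface patches as line-oriented text
#'
#' Each patch is one block: a `>patch` header carrying id, source, pivot
#' index, radius, inner radius and the small-patch flag, followed by one
#' tab-separated atom line per atom (chain, resno, insert, resname, atom,
#' element, x, y, z, inner-sphere membership).
#'
#' @param patches List of `surface_patch` objects.
#' @param path File path.
#' @return `path` invisibly; `read_patches()` returns the patch list.
#' @export
write_patches <- function(patches, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", FORMAT_VERSION, " patches n=", length(patches)),
             con)
  for (p in patches) {
    writeLines(sprintf(
      ">patch\t%s\tsource=%s\tpivot=%d\tradius=%.4g\tinner_radius=%.4g\tsmall=%d",
      p$id, p$source_id, p$pivot_index, p$radius, p$inner_radius,
      as.integer(p$small)), con)
    inner <- seq_len(nrow(p$atoms)) %in% p$inner
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%.6f\t%.6f\t%.6f\t%d",
                       p$atoms$chain, p$atoms$resno,
                       ifelse(p$atoms$insert == "", ".", p$atoms$insert),
                       p$atoms$resname, p$atoms$atom, p$atoms$element,
                       p$atoms$x, p$atoms$y, p$atoms$z,
                       as.integer(inner)), con)
  }
  invisible(path)
}

#' @rdname write_patches
#' @export
read_patches <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  heads <- which(startsWith(lines, ">patch"))
  ends <- c(heads[-1] - 1L, length(lines))
  lapply(seq_along(heads), function(i) {
    h <- strsplit(lines[heads[i]], "\t", fixed = TRUE)[[1]]
    field <- function(key) {
      v <- h[startsWith(h, paste0(key, "="))]
      sub(paste0(key, "="), "", v, fixed = TRUE)
    }
    body <- lines[seq(heads[i] + 1L, ends[i])]
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    atoms <- data.frame(
      chain = parts[, 1], resno = as.integer(parts[, 2]),
      insert = ifelse(parts[, 3] == ".", "", parts[, 3]),
      resname = parts[, 4], atom = parts[, 5], element = parts[, 6],
      x = as.numeric(parts[, 7]), y = as.numeric(parts[, 8]),
      z = as.numeric(parts[, 9]), occupancy = 1,
      stringsAsFactors = FALSE)
    make_patch(atoms, pivot_index = as.integer(field("pivot")),
               radius = as.numeric(field("radius")),
               source_id = field("source"), id = h[2])
  })
}

#' Write / read an all-vs-all distance matrix
#'
#' Square tab-separated numeric table with `inf` marking infinite distances;
#' the first column holds patch identifiers in row order.
#'
#' @param dmatrix Matrix from [pairwise_patch_distances()].
#' @param path File path.
#' @return `path` invisibly; `read_distance_matrix()` returns the matrix.
#' @export
write_distance_matrix <- function(dmatrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", FORMAT_VERSION, " distance-matrix n=",
                    nrow(dmatrix)), con)
  ids <- rownames(dmatrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dmatrix)))
  writeLines(paste(c("id", ids), collapse = "\t"), con)
  for (i in seq_len(nrow(dmatrix))) {
    vals <- ifelse(is.finite(dmatrix[i, ]), sprintf("%.6f", dmatrix[i, ]),
                   "inf")
    writeLines(paste(c(ids[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    v <- p[-1]
    out <- suppressWarnings(as.numeric(v))
    out[v == "inf"] <- Inf
    out
  }, numeric(length(header))))
  dimnames(m) <- list(vapply(parts, `[`, character(1), 1), header)
  m
}

#' Write / read a patch-library bundle
#'
#' A library is serialized as a directory: `manifest.json` (format version,
#' k, seed, iteration count, cluster sizes, training fractions, parameter
#' snapshot), `centroids.txt` (the centroid patches, see [write_patches()]),
#' and optionally `thresholds.tsv` (the surface-threshold table the library
#' was trained with).
#'
#' @param library A `patch_library`.
#' @param dir Bundle directory (created if missing).
#' @param thresholds Optional `surface_thresholds` to embed.
#' @param config Optional named parameter list echoed into the manifest.
#' @return `dir` invisibly; `read_library()` returns a list with `library`
#'   and `thresholds` (`NULL` if absent).
#' @export
write_library <- function(library, dir, thresholds = NULL, config = NULL) {
  stopifnot(inherits(library, "patch_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = FORMAT_VERSION,
    k = library$k,
    rng_seed = library$rng_seed,
    iterations = library$iterations,
    cluster_sizes = library$cluster_sizes,
    training_fractions = library$training_fractions,
    assignments = library$assignments,
    medoid_idx = library$medoid_idx,
    params = library$params,
    config = config
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_patches(library$centroids, file.path(dir, "centroids.txt"))
  if (!is.null(thresholds))
    write_thresholds(thresholds, file.path(dir, "thresholds.tsv"))
  invisible(dir)
}

#' @rdname write_library
#' @export
read_library <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  centroids <- read_patches(file.path(dir, "centroids.txt"))
  lib <- structure(
    list(centroids = centroids,
         medoid_idx = manifest$medoid_idx,
         assignments = manifest$assignments,
         cluster_sizes = manifest$cluster_sizes,
         training_fractions = manifest$training_fractions,
         k = as.integer(manifest$k),
         rng_seed = manifest$rng_seed,
         iterations = manifest$iterations,
         params = manifest$params),
    class = "patch_library")
  thr_path <- file.path(dir, "thresholds.tsv")
  thresholds <- if (file.exists(thr_path)) read_thresholds(thr_path) else NULL
  list(library = lib, thresholds = thresholds,
       config = manifest$config)
}
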