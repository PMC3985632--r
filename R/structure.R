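#' 3D chromosome structure
#'
#' A `c3d_structure` is an ordered set of 3D bin-midpoint coordinates, one per
#' modeled bin, in model units (nominally calibrated to micrometers through
#' the FISH-derived distance thresholds). Point order follows bin genomic
#' order: the chromosome is a continuous piece-wise linear curve through the
#' points.
#'
#' @param points n x 3 numeric matrix (or a tibble with columns `x`, `y`, `z`)
#'   of bin midpoint coordinates.
#' @param chrom chromosome name.
#' @param resolution bin size in base pairs.
#' @return A `c3d_structure`.
#' @export
c3d_structure <- function(points, chrom = "chrU", resolution = NA_real_) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- as.matrix(points)
  if (ncol(points) != 3) abort("structure points must have 3 columns (x, y, z)")
  if (nrow(points) < 1) abort("structure needs at least one point")
  if (!all(is.finite(points))) abort("structure coordinates must be finite")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, chrom = chrom, resolution = resolution),
            class = "c3d_structure")
}

#' @export
print.c3d_structure <- function(x, ...) {
  cat(sprintf("<c3d_structure> %s: %d bins, resolution %s bp\n",
              x$chrom, nrow(x$points), format(x$resolution)))
  invisible(x)
}

#' @export
length.c3d_structure <- function(x) nrow(x$points)

#' @export
as_tibble.c3d_structure <- function(x, ...) {
  pts <- x$points
  tibble(index = seq_len(nrow(pts)) - 1L,
         x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' Squared pairwise distances of a structure
#'
#' @param S a `c3d_structure`.
#' @return n x n matrix of squared Euclidean distances between bin midpoints.
#' @export
squared_distances <- function(S) {
  as.matrix(stats::dist(S$points))^2
}

#' Write a structure to disk
#'
#' TSV output is `index x y z` (0-based index, full precision) and
#' round-trips exactly. PDB output writes one CA pseudo-atom per bin with
#' consecutive residue numbers; coordinates are divided by a linear scale
#' factor chosen so they fit the fixed-width PDB coordinate fields, recorded
#' in a `REMARK 250 SCALE` line and undone by [read_structure()].
#'
#' @param S a `c3d_structure`.
#' @param path output file path.
#' @param format `"tsv"` or `"pdb"`.
#' @param bfactor optional per-bin values for the PDB B-factor column (e.g.
#'   compartment labels).
#' @return `path`, invisibly.
#' @export
write_structure <- function(S, path, format = c("tsv", "pdb"), bfactor = NULL) {
  stopifnot(inherits(S, "c3d_structure"))
  format <- match.arg(format)
  X <- S$points
  if (!all(is.finite(X))) abort("structure coordinates must be finite")
  if (format == "tsv") {
    lines <- sprintf("%d\t%s\t%s\t%s", seq_len(nrow(X)) - 1L,
                     format(X[, 1], digits = 17, trim = TRUE),
                     format(X[, 2], digits = 17, trim = TRUE),
                     format(X[, 3], digits = 17, trim = TRUE))
    writeLines(lines, path)
    return(invisible(path))
  }
  if (is.null(bfactor)) bfactor <- rep(0, nrow(X))
  if (length(bfactor) != nrow(X)) abort("bfactor length must match point count")
  # PDB %8.3f fields hold |x| < 1000; scale by a power of 10 when needed
  scale <- 10^max(0, ceiling(log10(max(abs(X), 1e-12) / 999)))
  lines <- c(
    sprintf("REMARK 250 SCALE %g", scale),
    sprintf("REMARK 250 CHROMOSOME %s RESOLUTION %s", S$chrom,
            format(S$resolution)),
    vapply(seq_len(nrow(X)), function(i) {
      sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
              i, i, X[i, 1] / scale, X[i, 2] / scale, X[i, 3] / scale,
              bfactor[i])
    }, character(1)),
    c(sprintf("CONECT%5d%5d", seq_len(nrow(X) - 1), seq_len(nrow(X) - 1) + 1),
      "END")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a structure from disk
#'
#' Inverse of [write_structure()]: exact for TSV, within the 3-decimal PDB
#' field precision (times the recorded scale factor) for PDB.
#'
#' @param path file path.
#' @param format `"tsv"` or `"pdb"`.
#' @param chrom,resolution metadata for the returned structure (PDB input
#'   recovers them from the REMARK line when present).
#' @return A `c3d_structure`; PDB input additionally carries the B-factor
#'   column as attribute `"bfactor"`.
#' @export
read_structure <- function(path, format = c("tsv", "pdb"),
                           chrom = "chrU", resolution = NA_real_) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (length(lines) == 0) abort("empty structure file")
  if (format == "tsv") {
    dat <- read.table(text = lines, header = FALSE,
                      col.names = c("index", "x", "y", "z"))
    dat <- dat[order(dat$index), ]
    return(c3d_structure(as.matrix(dat[, c("x", "y", "z")]),
                         chrom = chrom, resolution = resolution))
  }
  scale <- 1
  sc <- grep("^REMARK 250 SCALE ", lines, value = TRUE)
  if (length(sc) > 0) scale <- as.numeric(sub("^REMARK 250 SCALE ", "", sc[1]))
  meta <- grep("^REMARK 250 CHROMOSOME ", lines, value = TRUE)
  if (length(meta) > 0) {
    parts <- strsplit(sub("^REMARK 250 ", "", meta[1]), " +")[[1]]
    chrom <- parts[2]
    resolution <- suppressWarnings(as.numeric(parts[4]))
  }
  at <- grep("^ATOM ", lines, value = TRUE)
  if (length(at) == 0) abort("no ATOM records in PDB file")
  X <- cbind(
    as.numeric(substr(at, 31, 38)),
    as.numeric(substr(at, 39, 46)),
    as.numeric(substr(at, 47, 54))
  ) * scale
  S <- c3d_structure(X, chrom = chrom, resolution = resolution)
  attr(S, "bfactor") <- as.numeric(substr(at, 61, 66))
  S
}

#' Write an ensemble to JSON
#'
#' Stores structures, per-member seeds, final objective values and the
#' provenance (parameters + cutoff) in one JSON document.
#'
#' @param E a `c3d_ensemble` from [build_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(E, path) {
  stopifnot(inherits(E, "c3d_ensemble"))
  obj <- list(
    chrom = E$structures[[1]]$chrom,
    resolution = E$structures[[1]]$resolution,
    seeds = E$seeds,
    final_scores = E$final_scores,
    provenance = E$provenance,
    structures = lapply(E$structures, function(s) {
      list(x = s$points[, 1], y = s$points[, 2], z = s$points[, 3])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ensemble from JSON
#'
#' @param path file written by [write_ensemble()].
#' @return A `c3d_ensemble`.
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  structs <- lapply(obj$structures, function(s) {
    c3d_structure(cbind(unlist(s$x), unlist(s$y), unlist(s$z)),
                  chrom = obj$chrom,
                  resolution = if (is.null(obj$resolution)) NA_real_ else obj$resolution)
  })
  new_ensemble(structs, seeds = unlist(obj$seeds),
               final_scores = unlist(obj$final_scores),
               provenance = obj$provenance)
}
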