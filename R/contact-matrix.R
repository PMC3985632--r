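#' Hi-C contact matrix
#'
#' A `c3d_matrix` bundles a square, symmetric, nonnegative matrix of (raw or
#' normalized) interaction frequencies (IFs) with per-bin region metadata and
#' the bin resolution. Bins flagged `modeled = FALSE` (centromere or
#' zero-coverage bins) are carried in the region table but ignored by all
#' modeling operations. The matrix diagonal is ignored downstream.
#'
#' @param values square numeric matrix of interaction frequencies.
#' @param regions optional tibble with columns `chrom`, `start`, `end`,
#'   `index` (0-based bin index) and `modeled`; one row per matrix row. When
#'   `NULL` a default table of consecutive modeled bins is synthesized.
#' @param resolution bin size in base pairs (`NA` when unknown).
#' @param normalized logical; `TRUE` once [normalize_matrix()] has been applied.
#'
#' @return A `c3d_matrix` object.
#' @export
contact_matrix <- function(values, regions = NULL, resolution = NA_real_,
                           normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    abort(sprintf("contact matrix must be square (got %d x %d): non-square input",
                  nrow(values), ncol(values)))
  }
  if (!is.numeric(values) || anyNA(values)) {
    abort("contact matrix must be numeric with no missing values")
  }
  if (any(values < 0)) abort("contact matrix has negative values")
  dimnames(values) <- NULL
  asym <- max(abs(values - t(values)))
  if (asym > 1e-9) {
    abort(sprintf("contact matrix not symmetric (max |C - t(C)| = %g)", asym))
  }
  values <- (values + t(values)) / 2
  n <- nrow(values)
  if (is.null(regions)) {
    res <- if (is.na(resolution)) 1 else resolution
    regions <- tibble(
      chrom = "chrU",
      start = (seq_len(n) - 1) * res,
      end = seq_len(n) * res,
      index = seq_len(n) - 1L,
      modeled = TRUE
    )
  } else {
    regions <- as_tibble(regions)
    check_regions(regions, n)
  }
  structure(
    list(values = values, regions = regions,
         resolution = resolution, normalized = isTRUE(normalized)),
    class = "c3d_matrix"
  )
}

check_regions <- function(regions, n) {
  need <- c("chrom", "start", "end", "index", "modeled")
  missing_cols <- setdiff(need, names(regions))
  if (length(missing_cols) > 0) {
    abort(paste0("region table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(regions) != n) {
    abort(sprintf("region count (%d) does not match matrix dimension (%d)",
                  nrow(regions), n))
  }
  if (any(regions$end <= regions$start)) abort("regions must satisfy end > start")
  if (is.unsorted(regions$start, strictly = TRUE)) {
    abort("regions must be sorted by start and non-overlapping")
  }
  invisible(regions)
}

#' @export
print.c3d_matrix <- function(x, ...) {
  cat(sprintf("<c3d_matrix> %d x %d bins (%d modeled), %s\n",
              nrow(x$values), ncol(x$values), sum(x$regions$modeled),
              if (x$normalized) "normalized" else "raw"))
  cat(sprintf("  resolution: %s bp; total IF: %g; max IF: %g\n",
              format(x$resolution), total_if(x), max_if(x)))
  invisible(x)
}

#' @export
dim.c3d_matrix <- function(x) dim(x$values)

#' Summed upper-triangle interaction frequency
#'
#' @param x a `c3d_matrix`.
#' @return Sum of the strict upper triangle of the IF matrix.
#' @export
total_if <- function(x) {
  stopifnot(inherits(x, "c3d_matrix"))
  sum(x$values[upper.tri(x$values)])
}

#' Maximum off-diagonal interaction frequency
#'
#' @param x a `c3d_matrix`.
#' @return Largest off-diagonal IF value (0 for a 1x1 matrix).
#' @export
max_if <- function(x) {
  stopifnot(inherits(x, "c3d_matrix"))
  ut <- x$values[upper.tri(x$values)]
  if (length(ut) == 0) 0 else max(ut)
}

#' Read a contact matrix from text
#'
#' Supports a dense whitespace/tab-delimited square matrix and a sparse COO
#' triplet format with lines `i j value` (0-based bin indices). COO input is
#' symmetrized on load: when both `(i, j)` and `(j, i)` are present their mean
#' is used.
#'
#' @param path file path.
#' @param format `"dense"` or `"coo"`.
#' @param regions optional path to a BED-like region table (see
#'   [read_regions()]); its row count fixes the matrix dimension for COO input.
#' @param n for COO input without a region table, the number of bins (defaults
#'   to the largest index seen plus one).
#' @param resolution bin size in base pairs.
#' @return A raw [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("dense", "coo"),
                                regions = NULL, n = NULL,
                                resolution = NA_real_) {
  format <- match.arg(format)
  reg <- if (!is.null(regions)) read_regions(regions) else NULL
  if (format == "dense") {
    vals <- as.matrix(read.table(path, header = FALSE))
    dimnames(vals) <- NULL
    if (nrow(vals) != ncol(vals)) {
      abort(sprintf("non-square dense matrix: %d rows x %d columns",
                    nrow(vals), ncol(vals)))
    }
  } else {
    coo <- read.table(path, header = FALSE,
                      col.names = c("i", "j", "value"))
    if (nrow(coo) == 0) abort("empty COO file")
    if (any(coo$i < 0 | coo$j < 0)) abort("negative bin index in COO input")
    nn <- if (!is.null(reg)) nrow(reg) else if (!is.null(n)) n else max(coo$i, coo$j) + 1
    if (any(coo$i >= nn | coo$j >= nn)) {
      abort(sprintf("COO index out of range for %d bins", nn))
    }
    vals <- matrix(0, nn, nn)
    cnt <- matrix(0L, nn, nn)
    for (k in seq_len(nrow(coo))) {
      ii <- coo$i[k] + 1L; jj <- coo$j[k] + 1L
      vals[ii, jj] <- vals[ii, jj] + coo$value[k]
      cnt[ii, jj] <- cnt[ii, jj] + 1L
    }
    both <- cnt > 0 & t(cnt) > 0 & upper.tri(cnt)
    sym <- vals + t(vals)
    sym[both | t(both)] <- sym[both | t(both)] / 2
    diag(sym) <- diag(vals)
    vals <- sym
  }
  if (any(vals < 0)) abort("contact matrix has negative values")
  contact_matrix(vals, regions = reg, resolution = resolution,
                 normalized = FALSE)
}

#' Write a contact matrix to text
#'
#' @param x a `c3d_matrix`.
#' @param path output file path.
#' @param format `"dense"` (full matrix, tab-delimited) or `"coo"` (upper
#'   triangle plus diagonal, 0-based `i j value` lines, zeros omitted).
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(x, path, format = c("dense", "coo")) {
  stopifnot(inherits(x, "c3d_matrix"))
  format <- match.arg(format)
  if (format == "dense") {
    write.table(format(x$values, digits = 17, scientific = FALSE, trim = TRUE),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(x$values, diag = TRUE) & x$values != 0,
                 arr.ind = TRUE)
    lines <- sprintf("%d\t%d\t%s", idx[, 1] - 1L, idx[, 2] - 1L,
                     format(x$values[idx], digits = 17, scientific = FALSE,
                            trim = TRUE))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a BED-like region table
#'
#' Expected columns (tab-separated, no header): `chrom start end index modeled`
#' with 0-based half-open genomic intervals, a 0-based bin index and a 0/1
#' modeled flag (centromere and unmappable bins carry 0).
#'
#' @param path file path.
#' @return Tibble with columns `chrom`, `start`, `end`, `index`, `modeled`.
#' @export
read_regions <- function(path) {
  reg <- read.table(path, header = FALSE,
                    col.names = c("chrom", "start", "end", "index", "modeled"),
                    colClasses = c("character", "numeric", "numeric",
                                   "integer", "integer"))
  reg$modeled <- reg$modeled != 0
  as_tibble(reg)
}

#' Write a BED-like region table
#'
#' @param regions tibble as returned by [read_regions()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  out <- regions
  out$modeled <- as.integer(out$modeled)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
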