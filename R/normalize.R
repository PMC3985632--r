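#' Observed/expected normalization of a Hi-C matrix
#'
#' Divides each observed interaction frequency by its expected value under a
#' marginal-product null: `N_ij = C_ij / (m_i * m_j / T)` where `m_i` is the
#' total interaction count of bin i (row sum) and `T` the grand total. The
#' normalized IF is the likelihood ratio (odds) of observing the contact
#' relative to expectation: values above 1 indicate enrichment. Bins with zero
#' marginal carry no information and are masked: their entries are set to 0
#' and the bin is flagged `modeled = FALSE`; the remaining entries are
#' normalized over the reduced marginals.
#'
#' Normalization is scale-invariant (`normalize(k * C) == normalize(C)`) and
#' the expected matrix preserves the marginals (`sum_j E_ij == m_i`).
#'
#' @param C a raw [contact_matrix()] with at least one positive entry.
#' @return A normalized `c3d_matrix`.
#' @export
normalize_matrix <- function(C) {
  stopifnot(inherits(C, "c3d_matrix"))
  if (C$normalized) abort("matrix is already normalized")
  V <- C$values
  if (any(V < 0)) abort("contact matrix has negative values")
  if (all(V == 0)) abort("all-zero matrix cannot be normalized")
  regions <- C$regions
  keep <- regions$modeled
  # zero-marginal bins among the modeled set are masked before computing
  # expected counts, so dead bins do not deflate the marginals of live ones
  repeat {
    sub <- V[keep, keep, drop = FALSE]
    alive <- rowSums(sub) > 0
    if (all(alive)) break
    keep[keep] <- alive
  }
  if (sum(keep) < 2) abort("fewer than 2 informative bins after masking")
  m <- rowSums(sub)
  total <- sum(m)
  expected <- outer(m, m) / total
  norm_sub <- sub / expected
  out <- matrix(0, nrow(V), ncol(V))
  out[keep, keep] <- norm_sub
  regions$modeled <- keep
  contact_matrix(out, regions = regions, resolution = C$resolution,
                 normalized = TRUE)
}

#' Constraint set: contacts, non-contacts and adjacent pairs
#'
#' Partition of the upper-triangle bin pairs of the modeled bins into
#' contacts (normalized IF above the cutoff, carrying their IF as weight),
#' non-contacts, and adjacent pairs `(i, i+1)`. Built by [apply_cutoff()].
#'
#' @name c3d_constraints
NULL

new_constraints <- function(contacts, noncontacts, adjacent, n, cutoff,
                            max_if, total_if, chrom = "chrU",
                            resolution = NA_real_) {
  structure(
    list(contacts = contacts, noncontacts = noncontacts, adjacent = adjacent,
         n = n, cutoff = cutoff, max_if = max_if, total_if = total_if,
         chrom = chrom, resolution = resolution),
    class = "c3d_constraints"
  )
}

#' @export
print.c3d_constraints <- function(x, ...) {
  cat(sprintf(
    "<c3d_constraints> %d bins: %d contacts, %d non-contacts, %d adjacent (cutoff %g)\n",
    x$n, nrow(x$contacts), nrow(x$noncontacts), nrow(x$adjacent), x$cutoff))
  invisible(x)
}

#' Classify bin pairs by an IF cutoff
#'
#' Over the modeled bins (re-indexed 0..n-1 in genomic order), a pair
#' `(i, j)` with `i + 1 < j` becomes a contact iff its normalized IF strictly
#' exceeds `cutoff`, otherwise a non-contact. Consecutive pairs `(i, i+1)` are
#' governed by the adjacency term of the objective and bypass the cutoff —
#' except consecutive modeled bins flanking an unmodeled (centromere) gap,
#' which are not physically linked in the model and are classified by the
#' cutoff like any other pair.
#'
#' @param N a normalized `c3d_matrix`.
#' @param cutoff nonnegative IF threshold. The calibrated defaults are 0.66
#'   (1 MB, normal B-cell), 2.0 (200 KB) and 0.5 (leukemia B-cell); see
#'   [default_cutoff()].
#' @return A `c3d_constraints` object; `contacts` is a tibble `i, j, weight`
#'   (0-based modeled-bin indices, weight = normalized IF), `noncontacts` and
#'   `adjacent` are tibbles `i, j`.
#' @export
apply_cutoff <- function(N, cutoff) {
  stopifnot(inherits(N, "c3d_matrix"))
  if (!N$normalized) abort("apply_cutoff expects a normalized matrix")
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0) {
    abort("cutoff must be a single nonnegative number")
  }
  keep <- N$regions$modeled
  V <- N$values[keep, keep, drop = FALSE]
  reg <- N$regions[keep, , drop = FALSE]
  n <- nrow(V)
  if (n < 2) abort("need at least 2 modeled bins")
  ut <- which(upper.tri(V), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  # adjacency requires genomic contiguity: original bin indices consecutive
  adj <- (j == i + 1) & (reg$index[j] == reg$index[i] + 1L)
  vals <- V[ut]
  is_contact <- !adj & vals > cutoff
  is_noncontact <- !adj & !is_contact
  new_constraints(
    contacts = tibble(i = i[is_contact] - 1L, j = j[is_contact] - 1L,
                      weight = vals[is_contact]),
    noncontacts = tibble(i = i[is_noncontact] - 1L, j = j[is_noncontact] - 1L),
    adjacent = tibble(i = i[adj] - 1L, j = j[adj] - 1L),
    n = n, cutoff = cutoff,
    max_if = max_if(N), total_if = total_if(N),
    chrom = reg$chrom[1], resolution = N$resolution
  )
}

#' Percentage of bin pairs in contact
#'
#' Reporting aid for cutoff selection: the fraction (as a percentage) of
#' upper-triangle bin pairs whose normalized IF exceeds the cutoff, per
#' matrix. On real data the equivalent inter-chromosomal table guides the
#' choice of cutoff via the chromosome-territory feature.
#'
#' @param mats a normalized `c3d_matrix` or a (possibly named) list of them.
#' @param cutoff nonnegative IF threshold.
#' @return Tibble with columns `name`, `n_bins`, `n_pairs`, `pct_in_contact`.
#' @export
contact_percentages <- function(mats, cutoff) {
  if (inherits(mats, "c3d_matrix")) mats <- list(mats)
  if (length(mats) == 0) abort("no matrices supplied")
  nm <- names(mats)
  if (is.null(nm)) nm <- paste0("matrix", seq_along(mats))
  purrr::map2(mats, nm, function(m, name) {
    stopifnot(inherits(m, "c3d_matrix"))
    keep <- m$regions$modeled
    V <- m$values[keep, keep, drop = FALSE]
    if (nrow(V) < 2) abort("empty matrix: need at least 2 modeled bins")
    ut <- V[upper.tri(V)]
    tibble(name = name, n_bins = nrow(V), n_pairs = length(ut),
           pct_in_contact = 100 * mean(ut > cutoff))
  }) |> bind_rows()
}

#' Calibrated IF cutoff defaults
#'
#' @param resolution `"1MB"` or `"200KB"`.
#' @param cell `"normal"` (GM06990-like B-cell) or `"leukemia"`.
#' @return The IF cutoff: 0.66 at 1 MB for the normal cell, 2.0 at 200 KB,
#'   0.5 for the leukemia cell.
#' @export
default_cutoff <- function(resolution = c("1MB", "200KB"),
                           cell = c("normal", "leukemia")) {
  resolution <- match.arg(resolution)
  cell <- match.arg(cell)
  if (cell == "leukemia") return(0.5)
  if (resolution == "200KB") 2.0 else 0.66
}
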