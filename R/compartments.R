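#' A/B compartment assignment by PCA of the contact map
#'
#' Human chromatin partitions into two large-scale compartments with
#' enriched intra-compartment contacts. The assignment follows the standard
#' contact-map signature: the first principal component of the
#' (optionally Pearson-correlation-transformed) column-centered normalized
#' map splits the bins by the sign of its loading. Labels are neutral
#' \{1, 2\} — mapping them to euchromatin/heterochromatin needs external
#' information (e.g. gene density) and is out of scope.
#'
#' The sign of a principal component is arbitrary; for determinism the
#' loading of the bin with the largest absolute loading is made positive.
#' A near-degenerate spectrum (PC1 close to PC2, or no variance) is flagged.
#'
#' @param N a normalized `c3d_matrix` with at least 4 modeled bins.
#' @param use_correlation transform the map to its Pearson correlation
#'   matrix before PCA (default `TRUE`; this also makes the assignment
#'   invariant to symmetric row/column scaling).
#' @return A `c3d_compartments` tibble with one row per modeled bin
#'   (`index`, `pc1`, `label`) and attributes `variance_explained` and
#'   `degenerate`.
#' @export
assign_compartments <- function(N, use_correlation = TRUE) {
  stopifnot(inherits(N, "c3d_matrix"))
  keep <- N$regions$modeled
  V <- N$values[keep, keep, drop = FALSE]
  if (nrow(V) < 4) abort("need at least 4 modeled bins")
  if (max(V) == min(V)) abort("degenerate spectrum: all-constant contact map")
  M <- if (use_correlation) {
    cc <- suppressWarnings(cor(V))
    if (anyNA(cc)) abort("degenerate spectrum: zero-variance bins in correlation transform")
    cc
  } else V
  Mc <- sweep(M, 2, colMeans(M))  # column-center
  pc <- prcomp(Mc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  variance_explained <- ev[1] / sum(ev)
  degenerate <- length(ev) > 1 && (ev[1] - ev[2]) < 1e-9 * max(ev[1], 1e-300)
  loading <- pc$x[, 1]  # per-bin score along PC1
  if (loading[which.max(abs(loading))] < 0) loading <- -loading
  out <- tibble(index = N$regions$index[keep],
                pc1 = as.numeric(loading),
                label = ifelse(loading >= 0, 1L, 2L))
  attr(out, "variance_explained") <- variance_explained
  attr(out, "degenerate") <- degenerate
  class(out) <- c("c3d_compartments", class(out))
  out
}

#' Are two compartment assignments equivalent?
#'
#' Compartment labels are defined only up to the 1<->2 swap; this helper
#' compares two assignments modulo that relabeling.
#'
#' @param a,b label vectors (or `c3d_compartments` tibbles).
#' @return `TRUE` when the partitions agree exactly.
#' @export
same_partition <- function(a, b) {
  la <- if (is.data.frame(a)) a$label else a
  lb <- if (is.data.frame(b)) b$label else b
  if (length(la) != length(lb)) return(FALSE)
  all(la == lb) || all(la == (3L - lb))
}

#' Distance and IF profiles within and between compartments
#'
#' For each genomic separation `s` (in bins, from 2 up to
#' `max_separation`), the mean spatial distance in the model and the mean
#' normalized IF are computed for pairs within compartment 1, within
#' compartment 2, and between compartments. Separation 1 (adjacent bins) is
#' excluded since adjacency is constrained, not data-driven.
#'
#' @param S a `c3d_structure` over the modeled bins.
#' @param N the normalized `c3d_matrix`.
#' @param A a `c3d_compartments` assignment for the same bins.
#' @param max_separation largest genomic separation (bins) to profile.
#' @return Tibble `separation, group, n_pairs, mean_distance, mean_if` with
#'   `group` in `within_1`, `within_2`, `between`; strata with no pairs are
#'   absent.
#' @export
compartment_profiles <- function(S, N, A, max_separation = 20) {
  stopifnot(inherits(S, "c3d_structure"), inherits(N, "c3d_matrix"))
  keep <- N$regions$modeled
  V <- N$values[keep, keep, drop = FALSE]
  n <- nrow(V)
  if (length(S) != n || nrow(A) != n) {
    abort("structure, matrix and assignment dimensions disagree")
  }
  D <- sqrt(squared_distances(S))
  lab <- A$label
  purrr::map(2:min(max_separation, n - 1), function(s) {
    i <- seq_len(n - s)
    j <- i + s
    grp <- dplyr::case_when(lab[i] == 1L & lab[j] == 1L ~ "within_1",
                            lab[i] == 2L & lab[j] == 2L ~ "within_2",
                            TRUE ~ "between")
    tibble(separation = s, group = grp,
           distance = D[cbind(i, j)], if_value = V[cbind(i, j)])
  }) |>
    bind_rows() |>
    group_by(.data$separation, .data$group) |>
    summarise(n_pairs = dplyr::n(),
              mean_distance = mean(.data$distance),
              mean_if = mean(.data$if_value), .groups = "drop")
}

#' Write a compartment-colored structure
#'
#' Writes the structure as a PDB pseudo-atom trace with the compartment
#' label (1.0 / 2.0) in the B-factor column, for coloring in molecular
#' viewers.
#'
#' @param S a `c3d_structure`.
#' @param A a `c3d_compartments` assignment with one row per point.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
color_structure <- function(S, A, path) {
  stopifnot(inherits(S, "c3d_structure"))
  if (nrow(A) != length(S)) {
    abort("assignment must have one label per structure point")
  }
  write_structure(S, path, format = "pdb", bfactor = as.numeric(A$label))
}
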