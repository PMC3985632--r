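#' Score a structure against its constraint set
#'
#' A contact is satisfied when its squared midpoint distance is strictly
#' below the squared contact threshold; a non-contact is satisfied when its
#' squared distance is at least the threshold. The report mirrors the
#' standard per-chromosome evaluation columns: contact and non-contact
#' satisfaction fractions, the percentage of total IF carried by satisfied
#' contacts, and violation statistics (average squared distance and average
#' IF of unsatisfied contacts, average squared distance of unsatisfied
#' non-contacts, average IF over all contacts). Averages over empty sets are
#' reported as `NA`.
#'
#' @param S a `c3d_structure`.
#' @param cs a `c3d_constraints`.
#' @param params a `c3d_params` (supplies the contact threshold).
#' @return One-row tibble with columns `contact_score`, `noncontact_score`,
#'   `satisfied_if_pct`, `avg_sq_dist_unsat_contacts`,
#'   `avg_if_unsat_contacts`, `avg_sq_dist_unsat_noncontacts`, `avg_if_all`.
#' @export
score_structure <- function(S, cs, params) {
  X <- check_dims(S, cs)
  th <- effective_thresholds(params)
  d2c <- pair_d2(X, cs$contacts$i + 1L, cs$contacts$j + 1L)
  d2n <- pair_d2(X, cs$noncontacts$i + 1L, cs$noncontacts$j + 1L)
  sat_c <- d2c < th$dc2
  sat_n <- d2n >= th$dc2
  w <- cs$contacts$weight
  mean_or_na <- function(v) if (length(v) == 0) NA_real_ else mean(v)
  tibble(
    contact_score = mean_or_na(sat_c),
    noncontact_score = mean_or_na(sat_n),
    satisfied_if_pct = if (length(w) == 0) NA_real_ else 100 * sum(w[sat_c]) / sum(w),
    avg_sq_dist_unsat_contacts = mean_or_na(d2c[!sat_c]),
    avg_if_unsat_contacts = mean_or_na(w[!sat_c]),
    avg_sq_dist_unsat_noncontacts = mean_or_na(d2n[!sat_n]),
    avg_if_all = mean_or_na(w)
  )
}

#' Optimal rigid superposition of two structures
#'
#' Least-squares (Kabsch) superposition of `B` onto `A`: proper rotation
#' (determinant +1) plus translation, so chirality is preserved and a
#' mirrored structure keeps a positive RMSD.
#'
#' @param A,B `c3d_structure`s with the same number of points (>= 3).
#' @return List with `rotation` (3 x 3), `translation` (length 3, applied
#'   after rotation of centered `B`), `rmsd`, `transformed` (a
#'   `c3d_structure`: `B` superposed onto `A`), and `degenerate` (`TRUE` when
#'   the point set is collinear or coincident, where the rotation is not
#'   unique).
#' @export
superimpose <- function(A, B) {
  stopifnot(inherits(A, "c3d_structure"), inherits(B, "c3d_structure"))
  XA <- A$points; XB <- B$points
  if (nrow(XA) != nrow(XB)) abort("structures must have equal point counts")
  if (nrow(XA) < 3) abort("superposition needs at least 3 points")
  ca <- colMeans(XA); cb <- colMeans(XB)
  Ac <- sweep(XA, 2, ca); Bc <- sweep(XB, 2, cb)
  H <- crossprod(Bc, Ac)  # 3x3 covariance
  sv <- svd(H)
  d <- if (det(sv$v %*% t(sv$u)) < 0) -1 else 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)
  Bt <- sweep(Bc %*% t(R), 2, ca, "+")
  rmsd <- sqrt(mean(rowSums((Bt - XA)^2)))
  list(rotation = R, translation = ca - as.numeric(R %*% cb), rmsd = rmsd,
       transformed = c3d_structure(Bt, chrom = B$chrom,
                                   resolution = B$resolution),
       degenerate = degenerate)
}

#' GDT-HA structural similarity
#'
#' Global distance test (high accuracy) adapted to chromosome models: after
#' one global least-squares superposition, the fraction of index-matched
#' point pairs within each of four distance thresholds (2.0, 1.5, 1.0 and
#' 0.5 model units — lowered from the protein-scale 4/2/1/0.5) is averaged.
#' Because contact data cannot distinguish a structure from its mirror
#' image, `mirror_aware = TRUE` (default) also scores the reflected partner
#' and returns the better value, with attribute `"mirror_used"`.
#'
#' @param A,B `c3d_structure`s with equal point counts (>= 3).
#' @param thresholds distance thresholds (model units).
#' @param mirror_aware also try the reflection of `B`.
#' @return Similarity in \[0, 1\]; attributes `"mirror_used"` (logical).
#' @export
gdt_ha <- function(A, B, thresholds = c(2.0, 1.5, 1.0, 0.5),
                   mirror_aware = TRUE) {
  score_once <- function(B) {
    sup <- superimpose(A, B)
    dist <- sqrt(rowSums((sup$transformed$points - A$points)^2))
    mean(vapply(thresholds, function(t) mean(dist < t), numeric(1)))
  }
  s <- score_once(B)
  mirror_used <- FALSE
  if (mirror_aware) {
    Bm <- B
    Bm$points[, 1] <- -Bm$points[, 1]
    sm <- score_once(Bm)
    if (sm > s) { s <- sm; mirror_used <- TRUE }
  }
  attr(s, "mirror_used") <- mirror_used
  s
}

#' Pairwise similarity of an ensemble
#'
#' GDT-HA between every pair of ensemble members, and the mean over
#' off-diagonal pairs — the within-ensemble consistency score.
#'
#' @param E a `c3d_ensemble` with at least 2 members.
#' @param mirror_aware passed to [gdt_ha()].
#' @return List: `similarity` (m x m symmetric matrix, unit diagonal),
#'   `mirror_used` (m x m logical), `mean` (off-diagonal mean).
#' @export
pairwise_similarity <- function(E, mirror_aware = TRUE) {
  stopifnot(inherits(E, "c3d_ensemble"))
  m <- length(E$structures)
  if (m < 2) abort("pairwise similarity needs at least 2 structures")
  sim <- diag(1, m)
  mir <- matrix(FALSE, m, m)
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      s <- gdt_ha(E$structures[[a]], E$structures[[b]],
                  mirror_aware = mirror_aware)
      sim[a, b] <- sim[b, a] <- as.numeric(s)
      mir[a, b] <- mir[b, a] <- attr(s, "mirror_used")
    }
  }
  list(similarity = sim, mirror_used = mir,
       mean = mean(sim[upper.tri(sim)]))
}

#' Select the representative (medoid) model of an ensemble
#'
#' With a single cluster, K-medoids reduces to the exact medoid: the member
#' minimizing the summed distance to all others, where the distance between
#' two models is the inverse of their GDT-HA score (floored at 1e-6), or
#' optionally `1 - GDT-HA`. Ties break to the lowest index.
#'
#' @param E a `c3d_ensemble`.
#' @param distance `"inverse"` (1/GDT-HA, default) or `"one_minus"`.
#' @param similarity optional precomputed similarity matrix (from
#'   [pairwise_similarity()]), to avoid recomputation.
#' @return 1-based index of the medoid member.
#' @export
select_representative <- function(E, distance = c("inverse", "one_minus"),
                                  similarity = NULL) {
  stopifnot(inherits(E, "c3d_ensemble"))
  distance <- match.arg(distance)
  m <- length(E$structures)
  if (m == 0) abort("empty ensemble")
  if (m == 1) return(1L)
  sim <- if (is.null(similarity)) pairwise_similarity(E)$similarity else similarity
  d <- switch(distance,
              inverse = 1 / pmax(sim, 1e-6),
              one_minus = 1 - sim)
  diag(d) <- 0
  which.min(rowSums(d))  # which.min takes the lowest index on ties
}

#' Mean cross-ensemble similarity
#'
#' Mean GDT-HA over all cross pairs between two ensembles (e.g. models of
#' the same chromosome in two cell types or at two resolutions), or between
#' their representative models only.
#'
#' @param E1,E2 `c3d_ensemble`s with equal point counts.
#' @param mode `"cross"` (all pairs, default) or `"representative"`.
#' @param mirror_aware passed to [gdt_ha()].
#' @return Mean GDT-HA (scalar).
#' @export
compare_ensembles <- function(E1, E2, mode = c("cross", "representative"),
                              mirror_aware = TRUE) {
  stopifnot(inherits(E1, "c3d_ensemble"), inherits(E2, "c3d_ensemble"))
  mode <- match.arg(mode)
  if (length(E1$structures[[1]]) != length(E2$structures[[1]])) {
    abort("ensembles have different point counts")
  }
  if (mode == "representative") {
    r1 <- select_representative(E1)
    r2 <- select_representative(E2)
    return(as.numeric(gdt_ha(E1$structures[[r1]], E2$structures[[r2]],
                             mirror_aware = mirror_aware)))
  }
  vals <- purrr::map(E1$structures, function(a) {
    purrr::map_dbl(E2$structures, function(b) {
      as.numeric(gdt_ha(a, b, mirror_aware = mirror_aware))
    })
  })
  mean(unlist(vals))
}

#' Contact-withholding robustness test
#'
#' Randomly keeps `keep_fraction` of the contacts for training and withholds
#' the rest, reclassifying them as non-contacts; reconstructs a model from
#' the reduced set; and reports the percentage of withheld contacts that the
#' model nevertheless satisfies (squared distance below the contact
#' threshold). The per-contact table carries each withheld pair's IF and
#' recovery flag, supporting the IF-ordered comparison in which recovered
#' contacts are the higher-IF ones.
#'
#' @param cs a `c3d_constraints`.
#' @param keep_fraction fraction of contacts kept for training (0 < f < 1;
#'   published protocol uses 0.7).
#' @param params a `c3d_params`.
#' @param opts an [optimizer_options()]; `opts$seed` also seeds the split.
#' @return List: `recovery_pct`, `withheld` (tibble `i, j, weight,
#'   recovered`), `fit` (the training reconstruction), `kept_contacts`,
#'   `withheld_contacts`.
#' @export
robustness_test <- function(cs, keep_fraction = 0.7, params,
                            opts = optimizer_options()) {
  stopifnot(inherits(cs, "c3d_constraints"))
  if (!(keep_fraction > 0 && keep_fraction < 1)) {
    abort("keep_fraction must be in (0, 1)")
  }
  nc <- nrow(cs$contacts)
  n_keep <- round(keep_fraction * nc)
  if (n_keep < 1 || n_keep >= nc) {
    abort(sprintf(
      "degenerate split: keeping %d of %d contacts leaves an empty side",
      n_keep, nc))
  }
  keep_idx <- with_seed(opts$seed, sample.int(nc, n_keep))
  kept <- cs$contacts[sort(keep_idx), , drop = FALSE]
  withheld <- cs$contacts[-sort(keep_idx), , drop = FALSE]
  train <- new_constraints(
    contacts = kept,
    noncontacts = bind_rows(cs$noncontacts,
                            withheld[, c("i", "j"), drop = FALSE]) |>
      arrange(.data$i, .data$j),
    adjacent = cs$adjacent,
    n = cs$n, cutoff = cs$cutoff, max_if = cs$max_if, total_if = cs$total_if,
    chrom = cs$chrom, resolution = cs$resolution
  )
  fit <- reconstruct(train, params, opts)
  th <- effective_thresholds(params)
  d2 <- pair_d2(fit$structure$points, withheld$i + 1L, withheld$j + 1L)
  recovered <- d2 < th$dc2
  list(
    recovery_pct = 100 * mean(recovered),
    withheld = mutate(withheld, recovered = recovered),
    fit = fit,
    kept_contacts = nrow(kept),
    withheld_contacts = nrow(withheld)
  )
}
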