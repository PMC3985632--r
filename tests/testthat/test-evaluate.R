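make_cs <- function(contacts, noncontacts, adjacent, n, max_if = NULL) {
  if (is.null(max_if)) {
    max_if <- if (nrow(contacts) > 0) max(contacts$weight) else 1
  }
  chromo3d:::new_constraints(contacts = contacts, noncontacts = noncontacts,
                             adjacent = adjacent, n = n, cutoff = 0,
                             max_if = max_if,
                             total_if = sum(contacts$weight))
}

test_that("structure scoring matches direct formula evaluation", {
  p <- model_parameters()  # dc2 = 7
  cs <- make_cs(
    contacts = tibble::tibble(i = c(0L, 0L), j = c(2L, 3L), weight = c(9, 1)),
    noncontacts = tibble::tibble(i = 1L, j = 3L),
    adjacent = tibble::tibble(i = 0:2, j = 1:3),
    n = 4L)
  # contact (0,2) satisfied (d^2 = 5), contact (0,3) violated (d^2 = 81),
  # non-contact (1,3) satisfied (d^2 = 50)
  S <- c3d_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1, 0), c(9, 0, 0)))
  rep <- score_structure(S, cs, p)
  expect_equal(rep$contact_score, 0.5)
  expect_equal(rep$noncontact_score, 1.0)
  expect_equal(rep$satisfied_if_pct, 90)
  expect_equal(rep$avg_sq_dist_unsat_contacts, 81)
  expect_equal(rep$avg_if_unsat_contacts, 1)
  expect_true(is.na(rep$avg_sq_dist_unsat_noncontacts))
  expect_equal(rep$avg_if_all, 5)
})

test_that("scoring handles the perfect and degenerate extremes", {
  p <- model_parameters()
  cs <- make_cs(
    contacts = tibble::tibble(i = 0L, j = 2L, weight = 2),
    noncontacts = tibble::tibble(i = 1L, j = 3L),
    adjacent = tibble::tibble(i = 0:2, j = 1:3),
    n = 4L)
  good <- c3d_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(8, 0, 0)))
  rep <- score_structure(good, cs, p)
  expect_equal(rep$contact_score, 1)
  expect_equal(rep$noncontact_score, 1)
  expect_equal(rep$satisfied_if_pct, 100)
  # all points coincident: contacts trivially satisfied, non-contacts all violated
  degen <- c3d_structure(matrix(0, 4, 3))
  rep2 <- score_structure(degen, cs, p)
  expect_equal(rep2$contact_score, 1)
  expect_equal(rep2$noncontact_score, 0)
})

test_that("Kabsch superposition recovers rigid transforms and preserves chirality", {
  set.seed(21)
  A <- c3d_structure(matrix(rnorm(24), 8, 3))
  # 90 degree rotation about z plus translation
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  B <- A
  B$points <- sweep(A$points %*% t(Rz), 2, c(3, -2, 7), "+")
  sup <- superimpose(A, B)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_equal(sup$transformed$points, A$points, tolerance = 1e-9)
  # identity
  expect_equal(superimpose(A, A)$rmsd, 0, tolerance = 1e-12)
  # mirrored chiral set cannot be superposed by a proper rotation
  C <- chiral_structure()
  Cm <- C
  Cm$points[, 1] <- -Cm$points[, 1]
  expect_gt(superimpose(C, Cm)$rmsd, 0.1)
  expect_error(superimpose(A, c3d_structure(matrix(rnorm(9), 3, 3))),
               "equal point counts")
})

test_that("superposition agrees with an independent fitting routine", {
  set.seed(33)
  A <- c3d_structure(matrix(rnorm(30), 10, 3))
  B <- c3d_structure(A$points + 0.3 * matrix(rnorm(30), 10, 3))
  ours <- superimpose(A, B)$rmsd
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(A$points)),
                                         mobile = as.vector(t(B$points))))
  ref_rmsd <- sqrt(mean(colSums(matrix((ref - as.vector(t(A$points)))^2,
                                       nrow = 3))))
  expect_equal(ours, ref_rmsd, tolerance = 1e-6)
})

test_that("GDT-HA contracts: identity, rigid copies and mirrors", {
  set.seed(12)
  A <- c3d_structure(matrix(rnorm(45, sd = 2), 15, 3))
  expect_equal(as.numeric(gdt_ha(A, A)), 1)
  expect_equal(as.numeric(gdt_ha(A, rigid_copy(A, seed = 4))), 1)
  Am <- A
  Am$points[, 3] <- -Am$points[, 3]
  with_mirror <- gdt_ha(A, Am, mirror_aware = TRUE)
  expect_equal(as.numeric(with_mirror), 1)
  expect_true(attr(with_mirror, "mirror_used"))
  without <- gdt_ha(A, Am, mirror_aware = FALSE)
  expect_lt(as.numeric(without), 1)
  # symmetry
  B <- c3d_structure(A$points + matrix(rnorm(45, sd = 0.7), 15, 3))
  expect_equal(as.numeric(gdt_ha(A, B)), as.numeric(gdt_ha(B, A)),
               tolerance = 1e-9)
})

test_that("GDT-HA equals the threshold-count definition on a hand case", {
  # B = A with per-point displacements of known size along x
  A <- c3d_structure(cbind(seq(0, 45, by = 5), 0, 0))
  disp <- c(0.2, 0.2, 0.7, 0.7, 1.2, 1.2, 1.8, 1.8, 5, 5)
  B <- A
  B$points[, 2] <- B$points[, 2] + disp
  # no superposition can improve on identity here (displacements are small
  # and symmetric); verify against directly computed threshold fractions
  sup <- superimpose(A, B)
  d <- sqrt(rowSums((sup$transformed$points - A$points)^2))
  expected <- mean(vapply(c(2, 1.5, 1, 0.5), function(t) mean(d < t),
                          numeric(1)))
  expect_equal(as.numeric(gdt_ha(A, B, mirror_aware = FALSE)), expected)
})

test_that("ensemble similarity averages off-diagonal GDT-HA", {
  set.seed(5)
  X <- matrix(rnorm(30, sd = 2), 10, 3)
  structs <- list(c3d_structure(X),
                  c3d_structure(X + 0.5 * matrix(rnorm(30), 10, 3)),
                  c3d_structure(X + 1.5 * matrix(rnorm(30), 10, 3)))
  E <- chromo3d:::new_ensemble(structs, seeds = 1:3, final_scores = 1:3)
  ps <- pairwise_similarity(E)
  expect_equal(ps$similarity, t(ps$similarity))
  expect_equal(diag(ps$similarity), rep(1, 3))
  manual <- mean(c(ps$similarity[1, 2], ps$similarity[1, 3],
                   ps$similarity[2, 3]))
  expect_equal(ps$mean, manual)
  # identical members give similarity exactly 1
  E2 <- chromo3d:::new_ensemble(list(structs[[1]], structs[[1]]),
                                seeds = 1:2, final_scores = 1:2)
  expect_equal(pairwise_similarity(E2)$mean, 1)
})

test_that("representative selection agrees with exhaustive medoid search", {
  # {X, X, Y}: an X copy (lowest index) must win
  set.seed(8)
  X <- matrix(rnorm(30, sd = 2), 10, 3)
  Y <- X + matrix(rnorm(30), 10, 3)
  E <- chromo3d:::new_ensemble(
    list(c3d_structure(X), c3d_structure(X), c3d_structure(Y)),
    seeds = 1:3, final_scores = 1:3)
  expect_equal(select_representative(E), 1L)

  # randomized ensembles vs brute force, both distance variants
  for (trial in 1:25) {
    set.seed(trial)
    m <- sample(2:8, 1)
    base <- matrix(rnorm(24, sd = 2), 8, 3)
    structs <- lapply(seq_len(m), function(k) {
      c3d_structure(base + rexp(1) * matrix(rnorm(24), 8, 3))
    })
    E <- chromo3d:::new_ensemble(structs, seeds = seq_len(m),
                                 final_scores = seq_len(m))
    sim <- pairwise_similarity(E)$similarity
    expect_equal(select_representative(E, similarity = sim),
                 brute_medoid(sim))
    expect_equal(select_representative(E, distance = "one_minus",
                                       similarity = sim),
                 brute_medoid(sim, "one_minus"))
  }
  # singleton
  E1 <- chromo3d:::new_ensemble(list(c3d_structure(base)), seeds = 1,
                                final_scores = 1)
  expect_equal(select_representative(E1), 1L)
})

test_that("cross-ensemble comparison respects rigid invariance and singletons", {
  set.seed(14)
  X <- matrix(rnorm(36, sd = 2), 12, 3)
  A <- c3d_structure(X)
  B <- c3d_structure(X + 0.8 * matrix(rnorm(36), 12, 3))
  E1 <- chromo3d:::new_ensemble(list(A), seeds = 1, final_scores = 1)
  E2 <- chromo3d:::new_ensemble(list(B), seeds = 1, final_scores = 1)
  expect_equal(compare_ensembles(E1, E2), as.numeric(gdt_ha(A, B)))
  # rigid transform of all of E2 leaves the cross mean unchanged
  E2r <- chromo3d:::new_ensemble(list(rigid_copy(B, seed = 6)), seeds = 1,
                                 final_scores = 1)
  expect_equal(compare_ensembles(E1, E2r), compare_ensembles(E1, E2),
               tolerance = 1e-9)
  # mismatched point counts rejected
  E3 <- chromo3d:::new_ensemble(list(c3d_structure(X[1:10, ])), seeds = 1,
                                final_scores = 1)
  expect_error(compare_ensembles(E1, E3), "point counts")
})

test_that("robustness split is seeded, reproducible and guards degenerate cases", {
  res <- standard_instance(15, seed = 13)
  p <- model_parameters()
  opts <- optimizer_options(seed = 9, max_iterations = 400)
  r1 <- robustness_test(res$cs, keep_fraction = 0.7, params = p, opts = opts)
  r2 <- robustness_test(res$cs, keep_fraction = 0.7, params = p, opts = opts)
  expect_identical(r1$recovery_pct, r2$recovery_pct)
  expect_identical(r1$withheld$recovered, r2$withheld$recovered)
  expect_equal(r1$kept_contacts + r1$withheld_contacts, nrow(res$cs$contacts))
  # kept + withheld partition the original contact set
  key <- function(d) paste(d$i, d$j)
  expect_length(intersect(key(r1$withheld), key(res$cs$contacts)),
                nrow(r1$withheld))
  small <- res$cs
  small$contacts <- small$contacts[1:10, ]
  expect_error(robustness_test(small, keep_fraction = 0.999, params = p,
                               opts = opts), "degenerate split")
})
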