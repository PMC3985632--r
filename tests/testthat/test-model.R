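test_that("calibrated parameter defaults satisfy the threshold invariants", {
  p1 <- default_parameters("1MB")
  expect_equal(p1$dc2, 7.0)
  expect_equal(p1$dmax2, 20.0)
  p2 <- default_parameters("200KB")
  expect_equal(p2$dc2, 4.5)
  expect_equal(p2$dmin2, 0.02)
  expect_equal(p2$dmaxadj2, 1.0)
  expect_equal(p2$dmax2, 20.0)
  for (p in list(p1, p2)) {
    expect_true(p$dmin2 < p$dc2 && p$dc2 < p$dmax2)
    expect_true(p$dmin2 < p$dmaxadj2)
  }
  expect_error(default_parameters("5KB"), "unknown resolution")
  expect_error(model_parameters(dc2 = 30), "dmin2 < dc2 < dmax2")
})

test_that("per-chromosome overrides replace the tuned weights", {
  tab <- data.frame(chrom = c("chr1", "chr2"), W1 = c(2, 3), W3 = c(0.5, NA))
  p <- default_parameters("1MB", chrom = "chr1", overrides = tab)
  expect_equal(p$W1, 2)
  expect_equal(p$W3, 0.5)
  p2 <- default_parameters("1MB", chrom = "chr2", overrides = tab)
  expect_equal(p2$W1, 3)
  expect_equal(p2$W3, 1)  # NA -> keep default
  p3 <- default_parameters("1MB", overrides = list(W4 = 0))
  expect_equal(p3$W4, 0)
})

test_that("objective evaluates single-pair cases at their tanh landmarks", {
  p <- model_parameters(W2 = 0)
  th <- p$dc2
  cs <- chromo3d:::new_constraints(
    contacts = tibble::tibble(i = 0L, j = 2L, weight = 1),
    noncontacts = tibble::tibble(i = integer(), j = integer()),
    adjacent = tibble::tibble(i = c(0L, 1L), j = c(1L, 2L)),
    n = 3L, cutoff = 0, max_if = 1, total_if = 1)
  at_d <- function(d) {
    S <- c3d_structure(rbind(c(0, 0, 0), c(d / 2, 1, 0), c(d, 0, 0)))
    attr(objective(S, cs, p), "breakdown")[["contact_term"]]
  }
  # contact exactly at the threshold: tanh(0) = 0
  expect_equal(at_d(sqrt(th)), 0, tolerance = 1e-12)
  # deep inside the threshold with W1=W2=1, w=1: both tanh terms saturate to 2
  p2 <- model_parameters()
  cs2 <- cs
  S <- c3d_structure(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)))
  # d^2(0,2) = 4: dc2 - 4 = 3 and 4 - dmin2 ~ 3.96, both tanh near 1
  bd <- attr(objective(S, cs2, p2), "breakdown")
  expect_gt(bd[["contact_term"]], 2 * tanh(3) - 1e-6)
  expect_lt(bd[["contact_term"]], 2)
  # breakdown sums to the total
  expect_equal(sum(bd), as.numeric(objective(S, cs2, p2)))
})

test_that("objective is invariant under rigid motion and reflection", {
  res <- standard_instance(12, seed = 5)
  p <- model_parameters()
  S <- initialize_structure(12, seed = 8)
  S$points <- S$points * 3
  f0 <- as.numeric(objective(S, res$cs, p))
  Sr <- rigid_copy(S, seed = 2)
  expect_equal(as.numeric(objective(Sr, res$cs, p)), f0, tolerance = 1e-9)
  Sm <- S
  Sm$points[, 2] <- -Sm$points[, 2]
  expect_equal(as.numeric(objective(Sm, res$cs, p)), f0, tolerance = 1e-9)
})

test_that("objective respects its tanh-saturation upper bound", {
  res <- standard_instance(12, seed = 6)
  p <- model_parameters()
  cs <- res$cs
  wmax <- max(cs$contacts$weight) / cs$max_if
  bound <- (p$W1 * wmax + p$W2) * nrow(cs$contacts) +
    2 * p$W3 * nrow(cs$noncontacts) + 2 * p$W4 * nrow(cs$adjacent)
  for (seed in 1:5) {
    S <- initialize_structure(12, seed = seed)
    S$points <- S$points * seed
    expect_lt(abs(as.numeric(objective(S, cs, p))), bound)
  }
})

test_that("analytic gradient matches finite differences on random instances", {
  p <- model_parameters()
  for (seed in 1:5) {
    res <- standard_instance(10, seed = seed)
    S <- initialize_structure(10, seed = seed + 50)
    S$points <- S$points * 4  # spread so all pair classes are active
    G <- objective_gradient(S, res$cs, p)
    FD <- fd_gradient(S, res$cs, p)
    expect_lt(max(abs(G - FD)) / max(abs(FD)), 1e-5)
  }
})

test_that("gradient vectors sum to zero (translation invariance)", {
  res <- standard_instance(10, seed = 9)
  S <- initialize_structure(10, seed = 1)
  G <- objective_gradient(S, res$cs, model_parameters())
  expect_equal(colSums(G), rep(0, 3), tolerance = 1e-12)
})

test_that("an unsatisfied contact pulls its points together", {
  p <- model_parameters(W2 = 0, W4 = 0)
  cs <- chromo3d:::new_constraints(
    contacts = tibble::tibble(i = 0L, j = 2L, weight = 1),
    noncontacts = tibble::tibble(i = integer(), j = integer()),
    adjacent = tibble::tibble(i = c(0L, 1L), j = c(1L, 2L)),
    n = 3L, cutoff = 0, max_if = 1, total_if = 1)
  S <- c3d_structure(rbind(c(0, 0, 0), c(2, 1, 0), c(4, 0, 0)))  # d^2 = 16 > dc2
  G <- objective_gradient(S, cs, p)
  sep <- S$points[1, ] - S$points[3, ]
  # gradient at point 0 points toward point 2 (ascent closes the gap)
  expect_lt(sum(G[1, ] * sep), 0)
  expect_gt(sum(G[3, ] * sep), 0)
})

test_that("linear threshold convention squares the stored values", {
  cs <- chromo3d:::new_constraints(
    contacts = tibble::tibble(i = 0L, j = 2L, weight = 1),
    noncontacts = tibble::tibble(i = integer(), j = integer()),
    adjacent = tibble::tibble(i = c(0L, 1L), j = c(1L, 2L)),
    n = 3L, cutoff = 0, max_if = 1, total_if = 1)
  S <- c3d_structure(rbind(c(0, 0, 0), c(2, 2, 0), c(4, 0, 0)))
  p_sq <- model_parameters(dc2 = 16, W2 = 0)
  p_lin <- model_parameters(dc2 = 4, dmin2 = 0.2, dmax2 = 4.5,
                            dmaxadj2 = 1.3, W2 = 0,
                            threshold_convention = "linear")
  # d^2(0,2) = 16 sits exactly at both thresholds: contact term 0
  expect_equal(attr(objective(S, cs, p_sq), "breakdown")[["contact_term"]],
               attr(objective(S, cs, p_lin), "breakdown")[["contact_term"]],
               tolerance = 1e-12)
})
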