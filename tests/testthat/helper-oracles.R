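# Shared fixtures and independent oracles used across the suite.

# Central finite-difference gradient of the objective (oracle for the
# analytic gradient).
fd_gradient <- function(S, cs, params, h = 1e-6) {
  X <- S$points
  G <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) {
    for (k in 1:3) {
      Sp <- S; Sp$points[i, k] <- X[i, k] + h
      Sm <- S; Sm$points[i, k] <- X[i, k] - h
      G[i, k] <- (as.numeric(objective(Sp, cs, params)) -
                    as.numeric(objective(Sm, cs, params))) / (2 * h)
    }
  }
  G
}

# Exhaustive medoid: minimize the summed pair distance by direct enumeration.
brute_medoid <- function(sim, distance = c("inverse", "one_minus")) {
  distance <- match.arg(distance)
  m <- nrow(sim)
  sums <- vapply(seq_len(m), function(a) {
    others <- setdiff(seq_len(m), a)
    sum(vapply(others, function(b) {
      switch(distance,
             inverse = 1 / max(sim[a, b], 1e-6),
             one_minus = 1 - sim[a, b])
    }, numeric(1)))
  }, numeric(1))
  which(sums == min(sums))[1]
}

# Symmetric two-block matrix with constant intra-/inter-block IF, the
# canonical compartment fixture.
two_block_matrix <- function(n1, n2, intra = 5, inter = 1) {
  n <- n1 + n2
  lab <- c(rep(1L, n1), rep(2L, n2))
  V <- outer(lab, lab, function(a, b) ifelse(a == b, intra, inter))
  diag(V) <- 0
  list(matrix = contact_matrix(V, normalized = FALSE), labels = lab)
}

# A chiral 4-point structure (no proper rotation maps it onto its mirror).
chiral_structure <- function(scale = 1) {
  c3d_structure(scale * rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0),
                              c(0.2, 0.4, 1.7)))
}

# Random rigid motion (proper rotation + translation) applied to a structure.
rigid_copy <- function(S, seed = 1) {
  Q <- with(list(), {
    set.seed(seed)
    qr.Q(qr(matrix(rnorm(9), 3, 3)))
  })
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  set.seed(seed + 1)
  shift <- rnorm(3, sd = 5)
  S2 <- S
  S2$points <- sweep(S$points %*% Q, 2, shift, "+")
  S2
}

# Standard noiseless binary instance + constraint set under the 1 MB
# defaults; the tiny cutoff recovers the true contact set exactly.
standard_instance <- function(n, seed, cutoff = 1e-6) {
  inst <- make_instance(n, "random_walk", dc2 = 7, if_model = "binary",
                        noise = 0, seed = seed)
  norm <- normalize_matrix(inst$matrix)
  list(inst = inst, norm = norm, cs = apply_cutoff(norm, cutoff))
}
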