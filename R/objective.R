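# Precompute the flat pair table the objective and gradient iterate over.
# Contact weights w_ij are the normalized IF divided by the configured
# denominator (max IF by default, bounding w in (0, 1]).
pair_table <- function(cs, params) {
  denom <- switch(params$weight_denominator,
                  max = cs$max_if,
                  total = cs$total_if)
  if (!is.finite(denom) || denom <= 0) denom <- 1
  list(
    ci = cs$contacts$i + 1L, cj = cs$contacts$j + 1L,
    cw = cs$contacts$weight / denom,
    ni = cs$noncontacts$i + 1L, nj = cs$noncontacts$j + 1L,
    ai = cs$adjacent$i + 1L, aj = cs$adjacent$j + 1L
  )
}

pair_d2 <- function(X, i, j) {
  if (length(i) == 0) return(numeric(0))
  dx <- X[i, 1] - X[j, 1]
  dy <- X[i, 2] - X[j, 2]
  dz <- X[i, 3] - X[j, 3]
  dx * dx + dy * dy + dz * dz
}

#' Reconstruction objective
#'
#' The score of a structure against a constraint set is a sum of smooth tanh
#' terms over the three pair classes:
#' \deqn{F = \sum_{contacts} [w_{ij} W_1 \tanh(d_c^2 - d_{ij}^2) +
#'         W_2 \tanh(d_{ij}^2 - d_{min}^2)] +
#'       \sum_{non\mbox{-}contacts} [W_3 \tanh(d_{ij}^2 - d_c^2) +
#'         W_3 \tanh(d_{max}^2 - d_{ij}^2)] +
#'       \sum_{adjacent} [W_4 \tanh(d_{maxadj}^2 - d_{ij}^2) +
#'         W_4 \tanh(d_{ij}^2 - d_{min}^2)]}
#' Higher is better: the first term rewards pulling contacting bins inside
#' the contact threshold while keeping them apart by the minimum distance,
#' the second pushes non-contacts outside the threshold but within the
#' chromosome territory, and the third keeps adjacent bins within bond range.
#' The tanh smoothing keeps every term bounded in (-1, 1) and analytically
#' differentiable. Contact terms are weighted by `w_ij`, the normalized IF
#' over the configured denominator, so high-likelihood contacts dominate.
#' The objective depends on coordinates only through pairwise distances and
#' is therefore invariant under rigid motion and reflection.
#'
#' @param S a `c3d_structure` with one point per constraint-set bin.
#' @param cs a `c3d_constraints`.
#' @param params a `c3d_params`.
#' @return The scalar objective, with attribute `"breakdown"` (named vector
#'   of the contact, non-contact and adjacency terms, summing to the total).
#' @export
objective <- function(S, cs, params) {
  X <- check_dims(S, cs)
  th <- effective_thresholds(params)
  pt <- pair_table(cs, params)
  d2c <- pair_d2(X, pt$ci, pt$cj)
  d2n <- pair_d2(X, pt$ni, pt$nj)
  d2a <- pair_d2(X, pt$ai, pt$aj)
  contact <- sum(pt$cw * params$W1 * tanh(th$dc2 - d2c) +
                   params$W2 * tanh(d2c - th$dmin2))
  noncontact <- sum(params$W3 * tanh(d2n - th$dc2) +
                      params$W3 * tanh(th$dmax2 - d2n))
  adjacency <- sum(params$W4 * tanh(th$dmaxadj2 - d2a) +
                     params$W4 * tanh(d2a - th$dmin2))
  total <- contact + noncontact + adjacency
  attr(total, "breakdown") <- c(contact_term = contact,
                                noncontact_term = noncontact,
                                adjacency_term = adjacency)
  total
}

check_dims <- function(S, cs) {
  stopifnot(inherits(S, "c3d_structure"), inherits(cs, "c3d_constraints"))
  X <- S$points
  if (nrow(X) != cs$n) {
    abort(sprintf("structure has %d points but constraint set has %d bins",
                  nrow(X), cs$n))
  }
  if (!all(is.finite(X))) abort("structure coordinates must be finite")
  X
}

# sech^2(u) = 1 - tanh(u)^2, the derivative of tanh
sech2 <- function(u) {
  t <- tanh(u)
  1 - t * t
}

#' Analytic gradient of the reconstruction objective
#'
#' Exact partial derivatives of [objective()] with respect to every
#' coordinate. For a pair term `g(d2)`, the contribution to point i is
#' `g'(d2) * 2 * (x_i - x_j)` (and its negation to point j). Because the
#' objective depends only on pairwise distances, the gradient vectors sum to
#' zero over all points.
#'
#' @inheritParams objective
#' @return n x 3 matrix of partial derivatives.
#' @export
objective_gradient <- function(S, cs, params) {
  X <- check_dims(S, cs)
  th <- effective_thresholds(params)
  pt <- pair_table(cs, params)
  G <- matrix(0, nrow(X), 3)
  accumulate <- function(G, i, j, gprime) {
    if (length(i) == 0) return(G)
    D <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    contrib <- 2 * gprime * D
    G[, 1] <- G[, 1] + rowsum_into(contrib[, 1], i, nrow(G)) -
      rowsum_into(contrib[, 1], j, nrow(G))
    G[, 2] <- G[, 2] + rowsum_into(contrib[, 2], i, nrow(G)) -
      rowsum_into(contrib[, 2], j, nrow(G))
    G[, 3] <- G[, 3] + rowsum_into(contrib[, 3], i, nrow(G)) -
      rowsum_into(contrib[, 3], j, nrow(G))
    G
  }
  d2c <- pair_d2(X, pt$ci, pt$cj)
  gp_c <- -pt$cw * params$W1 * sech2(th$dc2 - d2c) +
    params$W2 * sech2(d2c - th$dmin2)
  G <- accumulate(G, pt$ci, pt$cj, gp_c)
  d2n <- pair_d2(X, pt$ni, pt$nj)
  gp_n <- params$W3 * sech2(d2n - th$dc2) -
    params$W3 * sech2(th$dmax2 - d2n)
  G <- accumulate(G, pt$ni, pt$nj, gp_n)
  d2a <- pair_d2(X, pt$ai, pt$aj)
  gp_a <- -params$W4 * sech2(th$dmaxadj2 - d2a) +
    params$W4 * sech2(d2a - th$dmin2)
  G <- accumulate(G, pt$ai, pt$aj, gp_a)
  G
}

rowsum_into <- function(v, idx, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
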