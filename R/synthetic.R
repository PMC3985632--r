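#' Simulate a ground-truth chromosome structure
#'
#' Three generators cover the features the pipeline must handle:
#' `random_walk` is a fixed-step random walk reflected inside a confinement
#' sphere (a crude chromosome territory), `helix` is a deterministic helix
#' with equal consecutive-point distances, and `two_blob` places two dense
#' clusters joined by a linker (a two-compartment caricature for
#' compartment-detection tests).
#'
#' The default confinement radius is `sqrt(20)/2`, so the territory diameter
#' of the simulated chromosome respects the model's default maximum
#' intra-chromosomal squared distance (`dmax2 = 20`); with the default
#' contact threshold this regime also reproduces the high intra-chromosomal
#' contact fractions seen in 1 MB Hi-C maps.
#'
#' @param n number of bins (>= 4).
#' @param generator `"random_walk"`, `"helix"` or `"two_blob"`.
#' @param seed RNG seed (ignored by the deterministic helix).
#' @param confinement_radius sphere radius for `random_walk` (model units).
#' @param step_length per-bin step of the walk.
#' @param blob_sd,blob_separation spread of and distance between the two
#'   clusters for `two_blob`.
#' @return A `c3d_structure`.
#' @export
simulate_structure <- function(n, generator = c("random_walk", "helix",
                                                "two_blob"),
                               seed = 1L, confinement_radius = sqrt(20) / 2,
                               step_length = 1, blob_sd = 0.8,
                               blob_separation = 6) {
  if (n < 4) abort("need at least 4 bins")
  if (length(generator) == 1 &&
      !generator %in% c("random_walk", "helix", "two_blob")) {
    abort(sprintf("invalid generator name '%s'", generator))
  }
  generator <- match.arg(generator)
  X <- switch(
    generator,
    helix = {
      t <- seq_len(n)
      # radius and pitch chosen so consecutive points are ~1 unit apart
      cbind(1.5 * cos(t * 0.6), 1.5 * sin(t * 0.6), t * 0.45)
    },
    random_walk = with_seed(seed, {
      X <- matrix(0, n, 3)
      for (k in 2:n) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        p <- X[k - 1, ] + step_length * dir
        r <- sqrt(sum(p^2))
        if (r > confinement_radius) {
          # reflect the radial overshoot back inside the sphere
          p <- p * (2 * confinement_radius - r) / r
        }
        X[k, ] <- p
      }
      X
    }),
    two_blob = with_seed(seed, {
      n1 <- floor(n / 2)
      c1 <- c(-blob_separation / 2, 0, 0)
      c2 <- c(blob_separation / 2, 0, 0)
      X <- rbind(
        sweep(matrix(stats::rnorm(3 * n1, sd = blob_sd), n1, 3), 2, c1, "+"),
        sweep(matrix(stats::rnorm(3 * (n - n1), sd = blob_sd), n - n1, 3), 2,
              c2, "+")
      )
      X
    })
  )
  c3d_structure(X, chrom = paste0("sim_", generator))
}

#' Generate a Hi-C-like contact matrix from a structure
#'
#' Inverts the contact definition: with `if_model = "binary"` a pair gets
#' count 1 exactly when its squared distance is below `dc2` (so downstream
#' cutoff filtering can recover the true contact set exactly); with
#' `if_model = "inverse_distance"` the expected count is proportional to
#' `1 / d^2` (capped at close range), giving graded IFs. `noise` scales
#' Poisson sampling dispersion: counts are drawn as
#' `noise * rpois(mean / noise)`, so the expected matrix is unchanged while
#' the relative noise grows with `noise`; `noise = 0` returns the expected
#' counts deterministically.
#'
#' @param S a `c3d_structure` (the ground truth).
#' @param dc2 squared contact-distance threshold (> 0).
#' @param if_model `"binary"` or `"inverse_distance"`.
#' @param noise Poisson mean-scaling factor (>= 0).
#' @param seed RNG seed for the Poisson draws.
#' @param intensity expected count of an inverse-distance pair at unit
#'   squared distance.
#' @return A raw `c3d_matrix`.
#' @export
contacts_from_structure <- function(S, dc2,
                                    if_model = c("binary", "inverse_distance"),
                                    noise = 0, seed = 1L, intensity = 10) {
  stopifnot(inherits(S, "c3d_structure"))
  if (!(dc2 > 0)) abort("dc2 must be positive")
  if (noise < 0) abort("noise must be nonnegative")
  if_model <- match.arg(if_model)
  D2 <- squared_distances(S)
  n <- nrow(D2)
  mean_mat <- if (if_model == "binary") {
    (D2 < dc2) * 1
  } else {
    intensity / pmax(D2, 0.25)  # cap: coincident pairs get a finite mean
  }
  diag(mean_mat) <- 0
  vals <- mean_mat
  if (noise > 0) {
    ut <- which(upper.tri(vals), arr.ind = TRUE)
    draws <- with_seed(seed,
                       noise * rpois(nrow(ut), mean_mat[ut] / noise))
    vals[ut] <- draws
    vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  }
  contact_matrix(vals, resolution = S$resolution, normalized = FALSE)
}

#' Bundle a synthetic ground-truth instance
#'
#' The standard fixture for optimizer, evaluation and robustness tests: a
#' simulated structure plus the contact matrix it generates.
#'
#' @inheritParams simulate_structure
#' @inheritParams contacts_from_structure
#' @param ... further arguments to [simulate_structure()].
#' @return A `c3d_instance` list: `truth`, `matrix`, `generator`, `if_model`,
#'   `noise`, `dc2`, `seed`.
#' @export
make_instance <- function(n, generator = "random_walk", dc2 = 7.0,
                          if_model = "binary", noise = 0, seed = 1L, ...) {
  truth <- simulate_structure(n, generator, seed = seed, ...)
  mat <- contacts_from_structure(truth, dc2 = dc2, if_model = if_model,
                                 noise = noise, seed = seed + 1000L)
  structure(list(truth = truth, matrix = mat, generator = generator,
                 if_model = if_model, noise = noise, dc2 = dc2, seed = seed),
            class = "c3d_instance")
}

#' @export
print.c3d_instance <- function(x, ...) {
  cat(sprintf("<c3d_instance> %s: %d bins, %s IFs, noise %g, seed %d\n",
              x$generator, length(x$truth), x$if_model, x$noise, x$seed))
  invisible(x)
}

#' Constraint set with ground-truth labels from a synthetic instance
#'
#' Builds the constraint set whose contact/non-contact partition is the
#' *geometric truth* of the instance (a pair is a contact iff its true
#' squared distance is below the instance's `dc2`) while contact weights are
#' the normalized IFs of the simulated matrix. With graded IF models,
#' thresholding the normalized matrix cannot reproduce the true partition
#' exactly (marginal normalization distorts the IF-distance relation), so
#' label noise would confound tests of the optimizer and of the
#' contact-withholding protocol; this constructor removes that confound.
#'
#' @param inst a `c3d_instance` (all matrix entries must be informative, i.e.
#'   no masked bins — true for noiseless instances).
#' @return A `c3d_constraints` with `cutoff = NA`.
#' @export
true_constraints <- function(inst) {
  stopifnot(inherits(inst, "c3d_instance"))
  norm <- normalize_matrix(inst$matrix)
  if (!all(norm$regions$modeled)) {
    abort("instance has uninformative bins; true_constraints needs a full matrix")
  }
  V <- norm$values
  D2 <- squared_distances(inst$truth)
  n <- nrow(V)
  ut <- which(upper.tri(V), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  adj <- j == i + 1
  ctc <- !adj & D2[ut] < inst$dc2
  ncc <- !adj & !ctc
  new_constraints(
    contacts = tibble(i = i[ctc] - 1L, j = j[ctc] - 1L, weight = V[ut][ctc]),
    noncontacts = tibble(i = i[ncc] - 1L, j = j[ncc] - 1L),
    adjacent = tibble(i = i[adj] - 1L, j = j[adj] - 1L),
    n = n, cutoff = NA_real_, max_if = max_if(norm), total_if = total_if(norm),
    chrom = inst$truth$chrom, resolution = inst$truth$resolution
  )
}

#' Calibrate the contact weight against heavy-tailed IFs
#'
#' Contact terms are weighted by `w_ij = N_ij / max_if`, so on maps with
#' heavy-tailed interaction frequencies most contacts carry a tiny weight
#' and the contact term is dominated by the unit-weight non-contact and
#' adjacency terms. The published protocol compensates by tuning the term
#' weights per chromosome around the average IF until contact and
#' non-contact scores balance; this helper applies the same idea in one
#' step: it rescales `W1` so the *mean* effective contact weight
#' (`mean(w_ij) * W1`) equals `target`.
#'
#' @param cs a `c3d_constraints` with at least one contact.
#' @param params a `c3d_params` to update.
#' @param target desired mean effective contact weight (1 balances the
#'   contact term against the unit-weight terms).
#' @return `params` with `W1` replaced.
#' @export
calibrate_weights <- function(cs, params = model_parameters(), target = 1) {
  stopifnot(inherits(cs, "c3d_constraints"))
  if (nrow(cs$contacts) == 0) abort("constraint set has no contacts")
  denom <- switch(params$weight_denominator, max = cs$max_if,
                  total = cs$total_if)
  mean_w <- mean(cs$contacts$weight) / denom
  params$W1 <- target / mean_w
  params
}

#' Serialize a synthetic instance to text files
#'
#' Writes `<prefix>_truth.tsv` (structure), `<prefix>_matrix.tsv` (dense
#' matrix) and `<prefix>_regions.tsv` (region table), all round-trippable
#' through the package readers.
#'
#' @param inst a `c3d_instance`.
#' @param prefix output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_instance <- function(inst, prefix) {
  stopifnot(inherits(inst, "c3d_instance"))
  paths <- c(truth = paste0(prefix, "_truth.tsv"),
             matrix = paste0(prefix, "_matrix.tsv"),
             regions = paste0(prefix, "_regions.tsv"))
  write_structure(inst$truth, paths["truth"], format = "tsv")
  write_contact_matrix(inst$matrix, paths["matrix"], format = "dense")
  write_regions(inst$matrix$regions, paths["regions"])
  invisible(paths)
}
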