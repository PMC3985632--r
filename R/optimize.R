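#' Optimizer options
#'
#' Constants for steepest gradient ascent with backtracking (Armijo) line
#' search. The ascent direction is the *normalized* gradient, so the step is
#' a displacement in model units; this keeps early iterations from
#' overshooting into the flat saturated region of the tanh terms, where the
#' gradient vanishes and contacts can no longer be pulled back. Each line
#' search starts at twice the previously accepted step (capped at
#' `initial_step`) and shrinks by `shrink` until the Armijo
#' sufficient-increase condition holds. Defaults: initial step 0.2 model
#' units, shrink 0.5, sufficient-increase constant 1e-4, at most 50
#' backtracks per iteration; stop when the relative objective improvement
#' stays below `tol = 1e-8` for `patience = 40` consecutive iterations, or
#' after `max_iterations = 10000`.
#'
#' @param max_iterations iteration cap (>= 1).
#' @param tol relative-improvement stopping threshold.
#' @param patience consecutive low-improvement iterations before stopping.
#' @param armijo_c sufficient-increase constant in (0, 1).
#' @param shrink step shrink factor in (0, 1).
#' @param initial_step first (and maximum) trial displacement of each line
#'   search, in model units.
#' @param max_backtracks line-search trials per iteration.
#' @param seed base RNG seed for random initialization.
#' @return An `c3d_opts` list.
#' @export
optimizer_options <- function(max_iterations = 10000, tol = 1e-8,
                              patience = 40, armijo_c = 1e-4, shrink = 0.5,
                              initial_step = 0.2, max_backtracks = 50,
                              seed = 1L) {
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  if (!(shrink > 0 && shrink < 1)) abort("shrink must be in (0, 1)")
  if (!(armijo_c > 0 && armijo_c < 1)) abort("armijo_c must be in (0, 1)")
  structure(list(max_iterations = max_iterations, tol = tol,
                 patience = patience, armijo_c = armijo_c, shrink = shrink,
                 initial_step = initial_step, max_backtracks = max_backtracks,
                 seed = as.integer(seed)),
            class = "c3d_opts")
}

#' Random initial structure
#'
#' All coordinates are drawn i.i.d. uniform on (-0.5, 0.5); the optimizer
#' unfolds the model from this small random cloud.
#'
#' @param n number of bins (>= 2).
#' @param seed RNG seed (reproducible; does not disturb the caller's RNG).
#' @param chrom,resolution metadata for the structure.
#' @return A `c3d_structure`.
#' @export
initialize_structure <- function(n, seed, chrom = "chrU",
                                 resolution = NA_real_) {
  if (n < 2) abort("need at least 2 points")
  X <- with_seed(seed, matrix(runif(3 * n, -0.5, 0.5), n, 3))
  c3d_structure(X, chrom = chrom, resolution = resolution)
}

#' Reconstruct a structure by gradient ascent
#'
#' Maximizes [objective()] by steepest gradient ascent with backtracking line
#' search from a random initialization. Each accepted step satisfies the
#' Armijo sufficient-increase condition, so the objective trace is
#' non-decreasing by construction. If the line search cannot find an uphill
#' step (step underflow at a near-stationary point), optimization stops and
#' reports the reason rather than failing.
#'
#' @param cs a `c3d_constraints` with at least one contact.
#' @param params a `c3d_params`.
#' @param opts an [optimizer_options()].
#' @param init optional starting `c3d_structure`; by default a random
#'   initialization seeded with `opts$seed`.
#' @return A `c3d_fit` list: `structure` (final model, centered at the
#'   origin), `trace` (tibble `iteration, objective, step`), `final_objective`,
#'   `converged`, `stop_reason`, `seed`.
#' @export
reconstruct <- function(cs, params, opts = optimizer_options(), init = NULL) {
  stopifnot(inherits(cs, "c3d_constraints"))
  if (nrow(cs$contacts) == 0) abort("constraint set has no contacts")
  validate_params(params)
  S <- if (is.null(init)) {
    initialize_structure(cs$n, opts$seed, chrom = cs$chrom,
                         resolution = cs$resolution)
  } else init
  X <- S$points
  Swork <- S
  f <- as.numeric(objective(Swork, cs, params))
  trace_obj <- numeric(opts$max_iterations + 1)
  trace_step <- numeric(opts$max_iterations + 1)
  trace_obj[1] <- f
  trace_step[1] <- NA_real_
  iters <- 0L
  low_improve <- 0L
  step0 <- opts$initial_step
  stop_reason <- "max_iterations"
  for (it in seq_len(opts$max_iterations)) {
    G <- objective_gradient(Swork, cs, params)
    gnorm <- sqrt(sum(G * G))
    if (gnorm == 0) { stop_reason <- "zero_gradient"; break }
    U <- G / gnorm  # unit ascent direction; step is a displacement in model units
    step <- step0
    accepted <- FALSE
    for (bt in seq_len(opts$max_backtracks)) {
      Xnew <- X + step * U
      Swork$points <- Xnew
      fnew <- as.numeric(objective(Swork, cs, params))
      # Armijo: directional derivative along U is gnorm
      if (fnew >= f + opts$armijo_c * step * gnorm) { accepted <- TRUE; break }
      step <- step * opts$shrink
    }
    if (!accepted) { Swork$points <- X; stop_reason <- "line_search_underflow"; break }
    step0 <- min(2 * step, opts$initial_step)
    improve <- (fnew - f) / max(1, abs(f))
    X <- Xnew
    f <- fnew
    iters <- it
    trace_obj[it + 1] <- f
    trace_step[it + 1] <- step
    low_improve <- if (improve < opts$tol) low_improve + 1L else 0L
    if (low_improve >= opts$patience) { stop_reason <- "converged"; break }
  }
  X <- sweep(X, 2, colMeans(X))  # center on output; objective is unaffected
  final <- c3d_structure(X, chrom = cs$chrom, resolution = cs$resolution)
  structure(
    list(structure = final,
         trace = tibble(iteration = 0:iters,
                        objective = trace_obj[seq_len(iters + 1)],
                        step = trace_step[seq_len(iters + 1)]),
         final_objective = f,
         converged = stop_reason %in% c("converged", "zero_gradient"),
         stop_reason = stop_reason,
         seed = opts$seed),
    class = "c3d_fit"
  )
}

#' @export
print.c3d_fit <- function(x, ...) {
  cat(sprintf("<c3d_fit> %d bins, %d iterations, objective %.4f (%s)\n",
              length(x$structure), max(x$trace$iteration), x$final_objective,
              x$stop_reason))
  invisible(x)
}

new_ensemble <- function(structures, seeds, final_scores, provenance = list()) {
  stopifnot(length(structures) == length(seeds),
            length(structures) == length(final_scores))
  structure(list(structures = structures, seeds = seeds,
                 final_scores = final_scores, provenance = provenance),
            class = "c3d_ensemble")
}

#' Build an ensemble of reconstructed models
#'
#' Runs [reconstruct()] `m` times with seeds `opts$seed, opts$seed + 1, ...`
#' (independent random initializations, reproducible end-to-end). The
#' published protocol uses an ensemble of 300 models per chromosome.
#'
#' @inheritParams reconstruct
#' @param m ensemble size (default 300).
#' @param .progress print a line per member to stderr.
#' @return A `c3d_ensemble`: `structures`, `seeds`, `final_scores`, and
#'   `provenance` (parameters and cutoff used).
#' @export
build_ensemble <- function(cs, params, opts = optimizer_options(), m = 300,
                           .progress = FALSE) {
  if (m < 1) abort("ensemble size m must be >= 1")
  fits <- purrr::map(seq_len(m) - 1L, function(k) {
    o <- opts
    o$seed <- opts$seed + k
    fit <- reconstruct(cs, params, o)
    if (.progress) {
      message(sprintf("member %d/%d: objective %.4f after %d iterations",
                      k + 1, m, fit$final_objective, max(fit$trace$iteration)))
    }
    fit
  })
  new_ensemble(
    structures = purrr::map(fits, "structure"),
    seeds = purrr::map_int(fits, "seed"),
    final_scores = purrr::map_dbl(fits, "final_objective"),
    provenance = list(params = unclass(params), cutoff = cs$cutoff,
                      n = cs$n, base_seed = opts$seed)
  )
}

#' @export
print.c3d_ensemble <- function(x, ...) {
  cat(sprintf("<c3d_ensemble> %d models of %d bins; objective %.3f-%.3f\n",
              length(x$structures), length(x$structures[[1]]),
              min(x$final_scores), max(x$final_scores)))
  invisible(x)
}

#' @export
length.c3d_ensemble <- function(x) length(x$structures)

#' @export
tidy.c3d_ensemble <- function(x, ...) {
  tibble(member = seq_along(x$structures),
         seed = x$seeds,
         objective = x$final_scores)
}

#' @export
glance.c3d_ensemble <- function(x, ...) {
  tibble(n_models = length(x$structures),
         n_bins = length(x$structures[[1]]),
         min_objective = min(x$final_scores),
         median_objective = stats::median(x$final_scores),
         max_objective = max(x$final_scores))
}

#' @export
tidy.c3d_fit <- function(x, ...) x$trace

#' @export
glance.c3d_fit <- function(x, ...) {
  tibble(n_bins = length(x$structure),
         iterations = max(x$trace$iteration),
         final_objective = x$final_objective,
         converged = x$converged,
         stop_reason = x$stop_reason)
}
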