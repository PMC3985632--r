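#' Plot a contact map
#'
#' Heat map of the (raw or normalized) IF matrix on a log1p color scale.
#'
#' @param x a `c3d_matrix`.
#' @return A ggplot.
#' @export
plot_contact_map <- function(x) {
  stopifnot(inherits(x, "c3d_matrix"))
  n <- nrow(x$values)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$value <- as.vector(x$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = log1p(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "log1p(IF)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin",
                  title = if (x$normalized) "Normalized contact map" else "Raw contact map")
}

#' @rdname plot_contact_map
#' @param object,... autoplot interface.
#' @export
autoplot.c3d_matrix <- function(object, ...) plot_contact_map(object)

#' Plot the optimizer objective trace
#'
#' @param x a `c3d_fit` from [reconstruct()].
#' @return A ggplot of objective versus iteration.
#' @export
plot_objective_trace <- function(x) {
  stopifnot(inherits(x, "c3d_fit"))
  ggplot2::ggplot(x$trace, ggplot2::aes(x = .data$iteration,
                                        y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "objective",
                  title = "Gradient-ascent objective trace")
}

#' @rdname plot_objective_trace
#' @param object,... autoplot interface.
#' @export
autoplot.c3d_fit <- function(object, ...) plot_objective_trace(object)

#' Plot a structure curve
#'
#' 2D projection of the piece-wise linear chromosome curve, colored along
#' the genomic coordinate (optionally by compartment).
#'
#' @param x a `c3d_structure`.
#' @param assignment optional `c3d_compartments` tibble for coloring.
#' @return A ggplot (x/y projection).
#' @export
plot_structure <- function(x, assignment = NULL) {
  stopifnot(inherits(x, "c3d_structure"))
  df <- as_tibble(x)
  if (!is.null(assignment)) {
    df$compartment <- factor(assignment$label)
    aes <- ggplot2::aes(x = .data$x, y = .data$y, color = .data$compartment)
  } else {
    aes <- ggplot2::aes(x = .data$x, y = .data$y, color = .data$index)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (x/y projection)", x$chrom))
}

#' @rdname plot_structure
#' @param object,... autoplot interface.
#' @export
autoplot.c3d_structure <- function(object, ...) plot_structure(object, ...)

#' Plot compartment distance/IF profiles
#'
#' Mean spatial distance and mean IF against genomic separation, per
#' within/between-compartment stratum.
#'
#' @param profiles tibble from [compartment_profiles()].
#' @return A ggplot with distance and IF panels.
#' @export
plot_compartment_profiles <- function(profiles) {
  long <- tidyr::pivot_longer(profiles, c("mean_distance", "mean_if"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$separation, y = .data$value,
                                     color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "genomic separation (bins)", y = NULL,
                  title = "Compartment distance and IF profiles")
}

#' Plot withheld-contact recovery against IF rank
#'
#' Sorts the withheld contacts by decreasing IF and overlays the IFs of the
#' recovered subset, visualizing that recovered contacts concentrate at
#' high IF.
#'
#' @param robustness result of [robustness_test()].
#' @return A ggplot.
#' @export
plot_recovery_ifs <- function(robustness) {
  wh <- arrange(robustness$withheld, dplyr::desc(.data$weight))
  wh$rank <- seq_len(nrow(wh))
  rec <- filter(wh, .data$recovered)
  rec$rank <- seq_len(nrow(rec))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = wh,
                       ggplot2::aes(x = .data$rank, y = .data$weight,
                                    color = "withheld")) +
    ggplot2::geom_line(data = rec,
                       ggplot2::aes(x = .data$rank, y = .data$weight,
                                    color = "recovered")) +
    ggplot2::scale_color_manual(NULL, values = c(withheld = "darkgreen",
                                                 recovered = "red")) +
    ggplot2::labs(x = "contact rank (by IF, descending)", y = "normalized IF",
                  title = "Recovered vs withheld contact IFs")
}
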