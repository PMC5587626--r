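#' Plot the iteration trace of a registration analysis
#'
#' Per-dimension standard deviations across registration iterations; the
#' curves flattening out illustrates convergence.
#'
#' @param object A [register()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.registration <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$std,
                               colour = .data$dim_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "std of matched differences (ppm)",
                  colour = "dimension",
                  title = sprintf("Registration trace (%s mode)", object$mode)) +
    ggplot2::theme_minimal()
}

cluster_scatter <- function(pl, assignments, title) {
  cd <- comparable_dims(pl)
  if (length(cd) < 2) {
    stop("cluster plots need at least two comparable dimensions", call. = FALSE)
  }
  sm <- shift_matrix(pl)
  df <- tibble::tibble(x = sm[, cd[1]], y = sm[, cd[2]],
                       cluster = assignments$cluster)
  df$status <- ifelse(is.na(df$cluster), "unclustered", "clustered")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = df[df$status == "unclustered", ],
                        colour = "grey60", shape = 4, size = 2) +
    ggplot2::geom_point(data = df[df$status == "clustered", ],
                        ggplot2::aes(colour = factor(.data$cluster)),
                        size = 2, show.legend = FALSE) +
    ggplot2::scale_x_reverse() + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = paste0(dim_labels(pl)[cd[1]], " (ppm)"),
                  y = paste0(dim_labels(pl)[cd[2]], " (ppm)"),
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot spin-system clusters over the comparable dimensions
#'
#' Scatter of the first two comparable dimensions (axes reversed, spectrum
#' convention); clustered peaks are coloured by cluster, unclustered peaks
#' are grey crosses.
#'
#' @param object A [group_peaks()] or [run_pipeline()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grouping <- function(object, ...) {
  cluster_scatter(object$peaklist, object$assignments,
                  "Spin system grouping")
}

#' @rdname autoplot.grouping
#' @export
autoplot.spin_pipeline <- function(object, ...) {
  cluster_scatter(object$peaklist, object$assignments,
                  sprintf("Registration + grouping pipeline (%d tiers)",
                          object$n_tiers))
}

#' Plot grouping accuracy against noise level
#'
#' Reproduces the standard accuracy-vs-noise diagnostic: mean percentage of
#' grouped and overlapped peaks per noise level with SEM whiskers.
#'
#' @param curve An [aggregate_curve()] result.
#' @param by Name of the noise-level column used in `aggregate_curve()`.
#' @return A ggplot object.
#' @export
plot_noise_curve <- function(curve, by = "sigma_h") {
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data[[by]], y = .data$mean,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0) +
    ggplot2::labs(x = paste0(by, " (ppm)"), y = "% of peaks",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
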