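#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a registration analysis result
#'
#' @param x A [register()] result.
#' @param ... Unused.
#' @return One row per comparable dimension: `dim`, `dim_label`, `offset`
#'   (ppm), `std` (matched-difference scale, ppm), `sigma` (per-peak
#'   estimate, ppm).
#' @export
tidy.registration <- function(x, ...) {
  tibble::tibble(dim = seq_along(x$stds), dim_label = x$dim_labels,
                 offset = x$offsets, std = x$stds, sigma = x$sigma)
}

#' @rdname tidy.registration
#' @return `glance()`: a one-row summary.
#' @export
glance.registration <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_matched = x$n_matched,
                 iterations = x$iterations,
                 robustness = x$robustness_best,
                 converged = x$converged, failed = x$failed,
                 low_confidence = x$low_confidence)
}

#' Tidy a grouping result
#'
#' @param x A [group_peaks()] result.
#' @param ... Unused.
#' @return One row per peak: `peak_id`, `truth_group`, `cluster`, `tier`.
#' @export
tidy.grouping <- function(x, ...) x$assignments

#' @rdname tidy.grouping
#' @export
glance.grouping <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$clusters),
                 n_unclustered = length(x$unclustered),
                 n_peaks = nrow(x$assignments),
                 cutoff = x$cutoff,
                 p_value = x$config$p_value,
                 min_points = x$config$min_points)
}

#' Tidy a pipeline result
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return One row per peak: `peak_id`, `truth_group`, `cluster`, `tier`.
#' @export
tidy.spin_pipeline <- function(x, ...) x$assignments

#' @rdname tidy.spin_pipeline
#' @export
glance.spin_pipeline <- function(x, ...) {
  tibble::tibble(n_tiers = x$n_tiers,
                 n_clusters = length(x$clusters),
                 n_unclustered = length(x$final_unclustered),
                 n_peaks = nrow(x$assignments))
}

#' Tidy an evaluation report
#'
#' @param x A [score_grouping()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per true spin system (`truth_group`, `size`,
#'   `class`); `glance()`: the scalar metrics in one row.
#' @export
tidy.evaluation_report <- function(x, ...) x$per_group

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(observed_peaks = x$observed_peaks,
                 ungrouped_peaks = x$ungrouped_peaks,
                 true_spin_systems = x$true_spin_systems,
                 groupable_spin_systems = x$groupable_spin_systems,
                 identified = x$identified, overlapped = x$overlapped,
                 split = x$split, partial = x$partial, missing = x$missing,
                 pct_grouped = x$pct_grouped,
                 pct_overlapped = x$pct_overlapped,
                 pct_grouped_groupable = x$pct_grouped_groupable,
                 pct_overlapped_groupable = x$pct_overlapped_groupable)
}
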