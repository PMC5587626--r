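#' Expected peak and spin-system counts from a protein sequence
#'
#' For HN(CO)CACB-type peak lists the number of peaks and groupable spin
#' systems can be estimated from the sequence alone. Two methods are
#' offered:
#'
#' * `"estimate"` -- the conventional closed-form estimates
#'   `peaks = (L - nPro - nGly) * 2 + nGly - 1` and
#'   `spin_systems = L - 1 - nGly - nPro`, where `L` is the sequence length.
#'   These treat proline (no amide H) and glycine (no CB) as uniform
#'   corrections and can deviate by a small boundary term from the exact
#'   count (they can also go negative on degenerate sequences, in which case
#'   they are floored at 0 with a warning).
#' * `"exact"` -- direct enumeration of the generative rule: residue `i`
#'   (from 2 to L) yields peaks iff it is not proline; it yields 2 peaks when
#'   residue `i-1` has both CA and CB (non-glycine), otherwise 1.
#'   `spin_systems` counts the anchors with 2 peaks (the groupable systems);
#'   `spin_systems_all` additionally counts the 1-peak glycine-predecessor
#'   systems.
#'
#' @param sequence One-letter amino-acid sequence string.
#' @param spectrum_type Currently `"hncocacb"`.
#' @param method `"estimate"` or `"exact"`.
#' @return A one-row tibble with `peaks`, `spin_systems` (and, for
#'   `method = "exact"`, `spin_systems_all`).
#' @examples
#' expected_counts(strrep("A", 10))                  # no Pro/Gly
#' expected_counts("GAA", method = "exact")          # hand-checkable
#' @export
expected_counts <- function(sequence, spectrum_type = "hncocacb",
                            method = c("estimate", "exact")) {
  method <- match.arg(method)
  if (tolower(spectrum_type) != "hncocacb") {
    stop("expected_counts currently supports HN(CO)CACB only", call. = FALSE)
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  L <- length(aa)
  if (L < 2) stop("sequence must have at least 2 residues", call. = FALSE)
  n_pro <- sum(aa == "P")
  n_gly <- sum(aa == "G")
  if (method == "estimate") {
    peaks <- (L - n_pro - n_gly) * 2 + n_gly - 1
    systems <- L - 1 - n_gly - n_pro
    if (peaks < 0 || systems < 0) {
      warning("expected-count formula is negative for this sequence; flooring at 0")
      peaks <- max(0L, peaks)
      systems <- max(0L, systems)
    }
    tibble::tibble(peaks = as.integer(peaks),
                   spin_systems = as.integer(systems))
  } else {
    anchors <- which(seq_len(L) >= 2 & aa != "P")
    per_anchor <- ifelse(aa[anchors - 1] == "G", 1L, 2L)
    tibble::tibble(peaks = as.integer(sum(per_anchor)),
                   spin_systems = as.integer(sum(per_anchor == 2L)),
                   spin_systems_all = as.integer(length(anchors)))
  }
}

#' Score a grouping result against true spin systems
#'
#' Compares recovered clusters with the `truth_group` labels carried by
#' simulated (or assigned) peaks. Definitions:
#'
#' * **identified** spin system: some cluster contains exactly its peaks;
#' * **overlapped** spin system: one of its peaks sits in a cluster that
#'   mixes peaks of two or more true systems (every contributing system of
#'   such a cluster is counted as overlapped);
#' * **split** spin system: not identified or overlapped, but its peaks are
#'   distributed over two or more clusters;
#' * **partial**: some peaks clustered as a strict subset of the system (its
#'   cluster mixes with no other system) -- tallied separately;
#' * **missing**: none of its peaks were clustered.
#'
#' Percentages use two denominators: `pct_grouped` divides the number of
#' peaks in identified clusters by all truth-labeled peaks, while
#' `pct_grouped_groupable` divides by the peaks of systems with at least
#' `min_points` peaks (systems below that size -- e.g. the single CA peak
#' following a glycine in HN(CO)CACB -- cannot form a cluster and are
#' excluded). `pct_overlapped` variants are analogous.
#'
#' @param result A [group_peaks()] or [run_pipeline()] result, or a data
#'   frame with columns `truth_group` and `cluster` (one row per peak,
#'   `cluster` `NA` for unclustered peaks).
#' @param sequence Optional one-letter sequence used to attach the
#'   closed-form expected counts to the report.
#' @param min_points Minimum cluster size used for the "groupable"
#'   denominator; taken from the result when available.
#' @return An object of class `evaluation_report`.
#' @export
score_grouping <- function(result, sequence = NULL, min_points = NULL) {
  if (inherits(result, "grouping")) {
    assignments <- result$assignments
    if (is.null(min_points)) min_points <- result$config$min_points
  } else if (inherits(result, "spin_pipeline")) {
    assignments <- result$assignments
    if (is.null(min_points)) min_points <- result$min_points
  } else if (is.data.frame(result) &&
             all(c("truth_group", "cluster") %in% names(result))) {
    assignments <- result
    if (is.null(min_points)) min_points <- 2L
  } else {
    stop("`result` must be a grouping or spin_pipeline object, or a data ",
         "frame with truth_group and cluster columns", call. = FALSE)
  }
  truth <- assignments$truth_group
  if (all(is.na(truth))) {
    stop("peaks carry no truth_group labels; scoring requires simulated or ",
         "assigned data", call. = FALSE)
  }
  cluster <- assignments$cluster
  n_peaks_total <- nrow(assignments)
  labeled <- !is.na(truth)
  group_ids <- sort(unique(truth[labeled]))
  group_size <- table(factor(truth[labeled], levels = group_ids))
  groupable_groups <- group_ids[group_size >= min_points]
  n_groupable_peaks <- sum(truth %in% groupable_groups)

  cluster_ids <- sort(unique(cluster[!is.na(cluster)]))
  cluster_info <- purrr::map(cluster_ids, function(cid) {
    members <- which(!is.na(cluster) & cluster == cid)
    truths <- unique(truth[members][!is.na(truth[members])])
    type <- if (length(truths) >= 2) "overlapped"
    else if (length(truths) == 1 &&
             setequal(members, which(labeled & truth == truths))) "identified"
    else "partial"
    list(cluster = cid, members = members, truths = truths, type = type,
         n_members = length(members))
  })
  cluster_type <- vapply(cluster_info, `[[`, character(1), "type")

  classify_group <- function(g) {
    peaks_g <- which(labeled & truth == g)
    clusters_g <- unique(cluster[peaks_g][!is.na(cluster[peaks_g])])
    if (length(clusters_g) == 0) return("missing")
    types <- cluster_type[match(clusters_g, cluster_ids)]
    in_identified <- any(vapply(cluster_info[match(clusters_g, cluster_ids)],
                                function(ci) ci$type == "identified" &&
                                  identical(ci$truths, g), logical(1)))
    if (in_identified) return("identified")
    if (any(types == "overlapped")) return("overlapped")
    if (length(clusters_g) >= 2) return("split")
    "partial"
  }
  group_class <- vapply(group_ids, classify_group, character(1))

  peaks_identified <- sum(vapply(cluster_info, function(ci)
    if (ci$type == "identified") ci$n_members else 0L, numeric(1)))
  peaks_overlapped <- sum(vapply(cluster_info, function(ci)
    if (ci$type == "overlapped") sum(labeled[ci$members]) else 0L,
    numeric(1)))

  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  n_labeled <- sum(labeled)

  expected <- if (!is.null(sequence)) expected_counts(sequence) else NULL

  structure(list(
    observed_peaks = n_peaks_total,
    expected_peaks = if (!is.null(expected)) expected$peaks else NA_integer_,
    ungrouped_peaks = sum(is.na(cluster)),
    expected_spin_systems = if (!is.null(expected)) expected$spin_systems
                            else NA_integer_,
    true_spin_systems = length(group_ids),
    groupable_spin_systems = length(groupable_groups),
    identified = sum(group_class == "identified"),
    overlapped = sum(group_class == "overlapped"),
    split = sum(group_class == "split"),
    partial = sum(group_class == "partial"),
    missing = sum(group_class == "missing"),
    pct_grouped = pct(peaks_identified, n_labeled),
    pct_overlapped = pct(peaks_overlapped, n_labeled),
    pct_grouped_groupable = pct(peaks_identified, n_groupable_peaks),
    pct_overlapped_groupable = pct(peaks_overlapped, n_groupable_peaks),
    min_points = min_points,
    per_group = tibble::tibble(truth_group = group_ids, size =
                                 as.integer(group_size), class = group_class),
    per_cluster = tibble::tibble(
      cluster = cluster_ids,
      n_members = vapply(cluster_info, `[[`, integer(1) , "n_members"),
      type = cluster_type)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Spin system grouping evaluation\n")
  cat(sprintf("  peaks: %d observed, %d ungrouped\n", x$observed_peaks,
              x$ungrouped_peaks))
  cat(sprintf("  spin systems: %d true (%d groupable): %d identified, %d overlapped, %d split, %d partial, %d missing\n",
              x$true_spin_systems, x$groupable_spin_systems, x$identified,
              x$overlapped, x$split, x$partial, x$missing))
  cat(sprintf("  %% grouped: %.1f (all peaks) / %.1f (groupable peaks)\n",
              x$pct_grouped, x$pct_grouped_groupable))
  cat(sprintf("  %% overlapped: %.1f (all peaks) / %.1f (groupable peaks)\n",
              x$pct_overlapped, x$pct_overlapped_groupable))
  invisible(x)
}

#' Aggregate grouping accuracy over a noise grid
#'
#' Summarises per-peak-list evaluation results at each noise level: the mean
#' percentage of grouped and overlapped peaks and the standard error of the
#' mean (SEM = sd / sqrt(n) across peak lists). Levels represented by a
#' single list get SEM 0 and are flagged.
#'
#' @param reports A tibble with one row per evaluated peak list, containing
#'   the grouping metric columns and the noise-level column.
#' @param by Name of the noise-level column (e.g. `"sigma_h"`).
#' @param metrics Character vector of metric columns to aggregate.
#' @return A tibble with, per level and metric, `mean`, `sem`, `n` and
#'   `sem_defined`.
#' @export
aggregate_curve <- function(reports, by = "sigma_h",
                            metrics = c("pct_grouped", "pct_overlapped")) {
  stopifnot(by %in% names(reports), all(metrics %in% names(reports)))
  long <- tidyr::pivot_longer(reports[c(by, metrics)],
                              cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(by, "metric")))),
    mean = mean(.data$value),
    sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
    n = dplyr::n(),
    .groups = "drop")
  out$sem_defined <- out$n > 1
  out
}
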