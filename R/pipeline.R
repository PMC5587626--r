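#' Iterative registration + grouping pipeline
#'
#' Combines self-registration analysis and variance-informed grouping to peel
#' off successive variance populations within a single peak list. Each outer
#' iteration (tier) self-registers the current peak subset to estimate
#' per-dimension standard deviations, groups that subset with the resulting
#' chi-square tolerances, moves the clustered peaks into the results, and
#' repeats on the remaining unclustered peaks with enlarged starting
#' tolerances. Conceptually the peak list is treated as a linear mixture of
#' normal-like positional-variance populations: tighter tolerances first
#' recover the low-variance spin systems, later tiers capture the
#' larger-variance ones.
#'
#' The outer loop stops when (a) fewer than `2 * min_points` peaks remain,
#' (b) a tier forms no new clusters, (c) registration fails to find support,
#' or (d) `max_tiers` is reached.
#'
#' @param pl A [peak_list()].
#' @param reg_config A [registration_config()]. The pipeline default uses the
#'   robust `"mad"` scale estimator: the peak subsets seen by each tier are
#'   heavy-tailed mixtures of variance populations, and a robust scale keeps
#'   each tier's standard deviations anchored to the dominant population
#'   instead of drifting towards the pooled variance.
#' @param p_value,min_points Grouping parameters, see [grouping_config()].
#' @param grouping_scale Which registration scale feeds the grouping
#'   normalized distance: `"per_peak"` (default) uses the per-peak sigma
#'   estimates (matched-difference standard deviations divided by
#'   `sqrt(2)`), which keeps the cluster radius tight enough to separate
#'   neighbouring spin systems at realistic peak densities; `"difference"`
#'   uses the matched-difference standard deviations directly, making the
#'   normalized distance between two same-system peaks chi-square with `df`
#'   degrees of freedom (so `p_value` is the false-exclusion rate) at the
#'   price of a `sqrt(2)` larger radius.
#' @param max_tiers Maximum number of outer iterations (default 5).
#' @param warm_start_factor Multiplier applied to a tier's converged stds to
#'   seed the next tier's registration (default 3; the remaining population is
#'   expected to have larger variance).
#' @return An object of class `spin_pipeline`: list with `tiers` (per-tier
#'   list of `registration` and cluster index list), `assignments` (tibble
#'   with `peak_id`, `cluster`, `tier`), `clusters` (list of peak index
#'   vectors, global ids), `final_unclustered`, `n_tiers`.
#' @examples
#' pl <- simulate_peaklist(synth_assignments(40, seed = 1),
#'                         noise = noise_model(c(0.001, 0.01, 0.01)), seed = 2)
#' res <- run_pipeline(pl)
#' glance(res)
#' @export
run_pipeline <- function(pl,
                         reg_config = registration_config(estimator = "mad"),
                         p_value = 1e-4, min_points = 2L,
                         grouping_scale = c("per_peak", "difference"),
                         max_tiers = 5L, warm_start_factor = 3) {
  grouping_scale <- match.arg(grouping_scale)
  validate_peak_list(pl)
  if (n_peaks(pl) < 2L * min_points) {
    stop("pipeline needs at least 2 * min_points peaks", call. = FALSE)
  }
  remaining <- seq_len(n_peaks(pl))          # positions in the original list
  cluster_of <- rep(NA_integer_, n_peaks(pl))
  tier_of <- rep(NA_integer_, n_peaks(pl))
  tiers <- list()
  next_cluster <- 0L
  tier <- 0L
  init_stds <- reg_config$initial_stds

  while (tier < max_tiers && length(remaining) >= 2L * min_points) {
    tier <- tier + 1L
    sub <- subset_peaks(pl, remaining)
    cfg <- reg_config
    cfg$initial_stds <- init_stds
    reg <- register(sub, config = cfg, mode = "self")
    if (reg$failed) {
      tiers[[tier]] <- list(registration = reg, clusters = list(),
                            stopped = "registration failure")
      break
    }
    stds <- switch(grouping_scale,
                   difference = reg$stds,
                   per_peak = reg$sigma)
    stds <- pmax(stds, reg_config$std_floor)
    g <- group_peaks(sub, grouping_config(stds = stds, p_value = p_value,
                                          min_points = min_points),
                     tier = tier)
    if (length(g$clusters) == 0) {
      tiers[[tier]] <- list(registration = reg, clusters = list(),
                            stopped = "no new clusters")
      break
    }
    tier_clusters <- list()
    for (ci in seq_along(g$clusters)) {
      next_cluster <- next_cluster + 1L
      orig <- remaining[g$clusters[[ci]]]
      cluster_of[orig] <- next_cluster
      tier_of[orig] <- tier
      tier_clusters[[length(tier_clusters) + 1L]] <- orig
    }
    tiers[[tier]] <- list(registration = reg, clusters = tier_clusters,
                          stopped = NULL)
    remaining <- remaining[g$unclustered]
    init_stds <- reg$stds * warm_start_factor
  }

  assignments <- tibble::tibble(peak_id = pl$peak_id,
                                truth_group = pl$truth_group,
                                cluster = cluster_of,
                                tier = tier_of)
  clusters <- split(seq_len(n_peaks(pl)), cluster_of)
  clusters <- unname(clusters[order(as.integer(names(clusters)))])
  structure(list(tiers = tiers,
                 assignments = assignments,
                 clusters = clusters,
                 final_unclustered = which(is.na(cluster_of)),
                 n_tiers = length(tiers),
                 min_points = as.integer(min_points),
                 p_value = p_value,
                 grouping_scale = grouping_scale,
                 peaklist = pl),
            class = "spin_pipeline")
}

#' Single-pass registration + grouping
#'
#' Runs exactly one self-registration followed by one grouping pass -- the
#' uniform-tolerance baseline against which the iterative pipeline is
#' compared. Equivalent to [run_pipeline()] with `max_tiers = 1`.
#'
#' @inheritParams run_pipeline
#' @return A `spin_pipeline` object with at most one tier.
#' @export
single_iteration <- function(pl,
                             reg_config = registration_config(estimator = "mad"),
                             p_value = 1e-4, min_points = 2L,
                             grouping_scale = c("per_peak", "difference")) {
  run_pipeline(pl, reg_config = reg_config, p_value = p_value,
               min_points = min_points, grouping_scale = grouping_scale,
               max_tiers = 1L)
}

#' @export
print.spin_pipeline <- function(x, ...) {
  cat(sprintf("Registration + grouping pipeline: %d tier(s), %d cluster(s), %d unclustered of %d peaks\n",
              x$n_tiers, length(x$clusters), length(x$final_unclustered),
              nrow(x$assignments)))
  for (t in seq_along(x$tiers)) {
    reg <- x$tiers[[t]]$registration
    cat(sprintf("  tier %d: stds %s ppm, %d cluster(s)%s\n", t,
                paste(signif(reg$stds, 3), collapse = "/"),
                length(x$tiers[[t]]$clusters),
                if (!is.null(x$tiers[[t]]$stopped))
                  paste0(" [stopped: ", x$tiers[[t]]$stopped, "]") else ""))
  }
  invisible(x)
}
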