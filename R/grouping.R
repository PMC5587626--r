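#' Chi-square membership cutoff for spin-system grouping
#'
#' The grouping algorithm admits a peak into a spin-system cluster when its
#' variance-normalized distance to a cluster peak is at most
#' `sqrt(Qchisq_upper(p_value, df))`, the square root of the upper-tail
#' chi-square quantile at `p_value` with `df` degrees of freedom (the number
#' of comparable dimensions). Smaller `p_value` means a larger radius; as
#' `p_value` approaches 1 the cutoff shrinks to 0 and no peak joins any
#' non-identical cluster.
#'
#' @param p_value Probability in (0, 1); default 1e-4.
#' @param df Degrees of freedom (>= 1).
#' @return The cutoff in normalized distance units.
#' @examples
#' membership_cutoff(1e-4, 2)  # sqrt(18.4207) ~ 4.29
#' @export
membership_cutoff <- function(p_value, df) {
  if (!is.numeric(p_value) || p_value <= 0 || p_value >= 1) {
    stop("`p_value` must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(df >= 1)
  sqrt(stats::qchisq(p_value, df = df, lower.tail = FALSE))
}

#' Variance-normalized distance between two peaks
#'
#' Root of the sum of squared per-dimension differences between two peaks,
#' each scaled by that dimension's standard deviation, over the comparable
#' dimensions.
#'
#' @param a,b Numeric shift vectors (full dimensionality, ppm).
#' @param stds Positive standard deviations (ppm), one per comparable
#'   dimension.
#' @param comparable_dims Integer indices of the comparable dimensions.
#' @return A non-negative number.
#' @export
normalized_distance <- function(a, b, stds, comparable_dims) {
  if (any(stds <= 0)) stop("stds must be positive", call. = FALSE)
  d <- (a[comparable_dims] - b[comparable_dims]) / stds
  sqrt(sum(d^2))
}

#' Grouping configuration
#'
#' @param stds Positive standard deviations (ppm) per comparable dimension,
#'   normally supplied by self-registration analysis.
#' @param p_value Chi-square probability cutoff (default 1e-4); see
#'   [membership_cutoff()].
#' @param min_points Minimum number of peaks (including the query peak) that
#'   form a cluster (default 2, the number of peaks per spin system in
#'   HN(CO)CACB-type spectra; glycine singleton peaks then legitimately stay
#'   unclustered).
#' @return A list of class `grouping_config`.
#' @export
grouping_config <- function(stds, p_value = 1e-4, min_points = 2L) {
  stopifnot(all(stds > 0), min_points >= 1)
  if (p_value <= 0 || p_value >= 1) {
    stop("`p_value` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(stds = stds, p_value = p_value,
                 min_points = as.integer(min_points)),
            class = "grouping_config")
}

#' Group peaks of one peak list into spin-system clusters
#'
#' Variance-informed DBSCAN over a single peak list: the classic DBSCAN region
#' query (Euclidean epsilon-neighborhood) is replaced by the set of peaks
#' whose [normalized_distance()] is at most the chi-square
#' [membership_cutoff()]. A peak whose neighborhood (including itself) holds
#' at least `min_points` peaks is a core peak; clusters are grown from core
#' peaks by neighborhood expansion, and peaks unreachable from any core peak
#' are left unclustered. Peaks are visited in list order, so a border peak
#' reachable from two clusters joins the first-discovered one; output is
#' deterministic given the input order.
#'
#' @param pl A [peak_list()].
#' @param config A [grouping_config()] whose `stds` has one entry per
#'   comparable dimension of `pl`.
#' @param tier Integer tag recorded on the clusters (the pipeline iteration
#'   that produced them; default 1).
#' @return An object of class `grouping`: list with `clusters` (list of
#'   integer peak index vectors), `unclustered` (integer vector),
#'   `assignments` (tibble: `peak_id`, `cluster`, `tier`), `stds_used`,
#'   `cutoff`, `config`.
#' @examples
#' pl <- simulate_peaklist(synth_assignments(30, seed = 1))
#' g <- group_peaks(pl, grouping_config(stds = c(0.001, 0.01)))
#' glance(g)
#' @export
group_peaks <- function(pl, config, tier = 1L) {
  validate_peak_list(pl)
  stopifnot(inherits(config, "grouping_config"))
  cd <- comparable_dims(pl)
  if (length(config$stds) != length(cd)) {
    stop("`config$stds` must have one entry per comparable dimension",
         call. = FALSE)
  }
  n <- n_peaks(pl)
  if (n < config$min_points) {
    stop("peak list has fewer peaks than `min_points`", call. = FALSE)
  }
  cutoff <- membership_cutoff(config$p_value, df = length(cd))
  x <- shift_matrix(pl)[, cd, drop = FALSE]
  z <- sweep(x, 2, config$stds, "/")
  nd <- as.matrix(stats::dist(z))
  adj <- nd <= cutoff          # includes the diagonal (self)
  neighbor_count <- rowSums(adj)
  core <- neighbor_count >= config$min_points

  cluster_of <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  next_id <- 0L
  for (p in seq_len(n)) {
    if (visited[p] || !core[p]) next
    next_id <- next_id + 1L
    queue <- p
    visited[p] <- TRUE
    cluster_of[p] <- next_id
    while (length(queue) > 0) {
      q <- queue[1]
      queue <- queue[-1]
      if (!core[q]) next
      nb <- which(adj[q, ])
      for (r in nb) {
        if (is.na(cluster_of[r])) {
          cluster_of[r] <- next_id
          if (!visited[r]) {
            visited[r] <- TRUE
            queue <- c(queue, r)
          }
        }
      }
    }
  }

  clusters <- split(seq_len(n), cluster_of)
  clusters <- unname(clusters[order(as.integer(names(clusters)))])
  new_grouping(pl, clusters, which(is.na(cluster_of)), config, cutoff, tier)
}

new_grouping <- function(pl, clusters, unclustered, config, cutoff, tier) {
  n <- n_peaks(pl)
  cluster_of <- rep(NA_integer_, n)
  for (ci in seq_along(clusters)) cluster_of[clusters[[ci]]] <- ci
  assignments <- tibble::tibble(
    peak_id = pl$peak_id,
    truth_group = pl$truth_group,
    cluster = cluster_of,
    tier = ifelse(is.na(cluster_of), NA_integer_, as.integer(tier)))
  structure(list(clusters = clusters,
                 unclustered = unclustered,
                 assignments = assignments,
                 stds_used = config$stds,
                 cutoff = cutoff,
                 tier = as.integer(tier),
                 config = config,
                 peaklist = pl),
            class = "grouping")
}

#' @export
print.grouping <- function(x, ...) {
  cat(sprintf("Spin system grouping: %d cluster(s), %d unclustered peak(s) of %d\n",
              length(x$clusters), length(x$unclustered),
              nrow(x$assignments)))
  cat(sprintf("  cutoff %.4f normalized units (p = %g, df = %d), stds: %s ppm\n",
              x$cutoff, x$config$p_value, length(x$stds_used),
              paste(signif(x$stds_used, 4), collapse = ", ")))
  invisible(x)
}
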