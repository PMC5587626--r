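#' Registration analysis configuration
#'
#' Parameters of the peak list registration analysis. The algorithm keeps one
#' working standard deviation per comparable dimension -- the standard
#' deviation of the chemical-shift differences between mapped peak pairs --
#' and iterates until those values stop changing. Before any statistics exist,
#' the working values start from `initial_stds` (defaults: 0.02 ppm for
#' H-class dimensions, 0.2 ppm for N/C-class dimensions, typical starting
#' match tolerances in assignment practice).
#'
#' @param tolerance_units Match tolerance in standard-deviation units used to
#'   decide whether a peak-mapping pair supports another (default 4). The
#'   unit is the *per-peak* positional standard deviation (the
#'   matched-difference standard deviation divided by `sqrt(2)`): this
#'   reading keeps the first pipeline tier locked to the dominant
#'   low-variance population when several variance sources are mixed,
#'   whereas tolerances on the matched-difference scale drift towards the
#'   pooled variance.
#' @param std_factor Scaling of the matched-difference standard deviation in
#'   the chi-square statistic of the difference-of-differences (default 2;
#'   `sqrt(2)` is the value expected under independent error propagation and
#'   is selectable for comparison).
#' @param estimator Scale estimator for the per-dimension standard deviation
#'   of mapped-pair differences: `"sd"` (classical, default) or `"mad"`
#'   (median-absolute-deviation scaled to be consistent for Gaussian noise;
#'   robust to spurious pairs entering the mapping on sparse peak subsets).
#' @param initial_stds Optional numeric vector of starting standard deviations
#'   (ppm), one per comparable dimension.
#' @param convergence_tol Relative change in per-dimension standard deviations
#'   below which iteration stops (default 1e-3).
#' @param max_iterations Maximum number of registration iterations (default 20).
#' @param std_floor Lower floor (ppm) applied to working standard deviations so
#'   the chi-square statistic stays finite on duplicate-rich lists (default 1e-6).
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(tolerance_units = 4, std_factor = 2,
                                initial_stds = NULL, convergence_tol = 1e-3,
                                max_iterations = 20L, std_floor = 1e-6,
                                estimator = c("sd", "mad")) {
  stopifnot(tolerance_units > 0, std_factor > 0, convergence_tol > 0,
            max_iterations >= 1, std_floor > 0)
  if (!is.null(initial_stds)) stopifnot(all(initial_stds > 0))
  structure(list(tolerance_units = tolerance_units, std_factor = std_factor,
                 initial_stds = initial_stds,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 std_floor = std_floor,
                 estimator = match.arg(estimator)),
            class = "registration_config")
}

default_initial_stds <- function(pl) {
  cd <- comparable_dims(pl)
  labs <- toupper(dim_labels(pl)[cd])
  ifelse(grepl("^H", labs), 0.02, 0.2)
}

#' Euclidean distance matrix of a peak list
#'
#' Distance between every pair of peaks within one peak list, computed over
#' its comparable dimensions.
#'
#' @param pl A [peak_list()] with at least two peaks.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(pl) {
  validate_peak_list(pl)
  if (n_peaks(pl) < 2) {
    stop("distance_matrix needs at least 2 peaks", call. = FALSE)
  }
  x <- shift_matrix(pl)[, comparable_dims(pl), drop = FALSE]
  as.matrix(stats::dist(x, method = "euclidean"))
}

#' Chi-square statistic for a difference of peak differences
#'
#' For candidate mappings i -> j and m -> n between an input and a root peak
#' list, computes the chi-square statistic of the difference-of-differences
#' `(input_i - input_m) - (root_j - root_n)` over the comparable dimensions,
#' each term scaled by `std * std_factor`, together with its upper-tail
#' probability under a chi-square distribution with `df` = number of
#' comparable dimensions. Concordant mapping pairs score probabilities near 1.
#'
#' @param input_pl,root_pl Peak lists sharing comparable dimensionality.
#' @param i,j,m,n Peak indices (rows): `i`, `m` in the input list, `j`, `n` in
#'   the root list.
#' @param stds Positive standard deviations (ppm), one per comparable
#'   dimension (the working match-tolerance scale).
#' @param std_factor Scaling factor applied to `stds` (default 2).
#' @return A named list with elements `stat` and `prob`.
#' @export
chi_square_pair <- function(input_pl, root_pl, i, j, m, n, stds,
                            std_factor = 2) {
  cd_in <- comparable_dims(input_pl)
  cd_rt <- comparable_dims(root_pl)
  if (length(cd_in) != length(cd_rt)) {
    stop("peak lists have different numbers of comparable dimensions",
         call. = FALSE)
  }
  if (any(stds <= 0)) {
    stop("all stds must be > 0; apply a minimum-std floor (see ",
         "registration_config()$std_floor) before calling", call. = FALSE)
  }
  x <- shift_matrix(input_pl)[, cd_in, drop = FALSE]
  y <- shift_matrix(root_pl)[, cd_rt, drop = FALSE]
  delta <- (x[i, ] - x[m, ]) - (y[j, ] - y[n, ])
  stat <- sum((delta / (stds * std_factor))^2)
  list(stat = stat,
       prob = stats::pchisq(stat, df = length(cd_in), lower.tail = FALSE))
}

#' Build the support matrix between two peak lists
#'
#' For every candidate peak mapping (i, j) -- input peak i mapped onto root
#' peak j -- collects its support set: all peak-mapping pairs (m, n) whose
#' difference vector agrees with that of (i, j) within `tolerance_units *
#' stds` in every comparable dimension. In self mode (a peak list registered
#' against itself) identical peak mappings are excluded: cells with `i == j`,
#' members with `m == n`, and the trivial member `(m, n) == (i, j)`.
#'
#' This is the reference R implementation, quadratic in the number of peak
#' pairs; [register()] uses an equivalent accelerated engine internally.
#'
#' @param input_pl,root_pl Peak lists sharing comparable dimensionality. Pass
#'   the same object twice for self mode.
#' @param stds Working standard deviations (ppm) per comparable dimension.
#' @param config A [registration_config()].
#' @param mode `"pairwise"` or `"self"`.
#' @return A tibble of class `support_matrix` with columns `i`, `j`, `m`, `n`,
#'   `stat`, `prob` (one row per support-set member), carrying the inputs as
#'   attributes.
#' @export
build_support_matrix <- function(input_pl, root_pl, stds,
                                 config = registration_config(),
                                 mode = c("pairwise", "self")) {
  mode <- match.arg(mode)
  stds <- pmax(stds, config$std_floor)
  cd_in <- comparable_dims(input_pl)
  cd_rt <- comparable_dims(root_pl)
  stopifnot(length(cd_in) == length(cd_rt), length(stds) == length(cd_in))
  x <- shift_matrix(input_pl)[, cd_in, drop = FALSE]
  y <- shift_matrix(root_pl)[, cd_rt, drop = FALSE]
  n_in <- nrow(x); n_rt <- nrow(y); k <- ncol(x)
  tol <- config$tolerance_units * stds
  df <- k

  # difference vectors d_mn = x_m - y_n for every pair, ordered by (m, n)
  D <- matrix(0, n_in * n_rt, k)
  for (l in seq_len(k)) {
    D[, l] <- as.vector(t(outer(x[, l], y[, l], "-")))
  }
  mm <- rep(seq_len(n_in), each = n_rt)
  nn <- rep(seq_len(n_rt), times = n_in)

  rows <- vector("list", n_in * n_rt)
  idx <- 0L
  for (i in seq_len(n_in)) {
    for (j in seq_len(n_rt)) {
      if (mode == "self" && i == j) next
      d_ij <- x[i, ] - y[j, ]
      delta2 <- matrix(rep(d_ij, each = n_in * n_rt), ncol = k) - D
      ok <- rep(TRUE, n_in * n_rt)
      for (l in seq_len(k)) ok <- ok & (abs(delta2[, l]) <= tol[l])
      drop <- (mm == i & nn == j)
      if (mode == "self") drop <- drop | (mm == nn)
      ok <- ok & !drop
      if (any(ok)) {
        stat <- rowSums((delta2[ok, , drop = FALSE] /
                           rep(stds * config$std_factor, each = sum(ok)))^2)
        idx <- idx + 1L
        rows[[idx]] <- tibble::tibble(
          i = i, j = j, m = mm[ok], n = nn[ok], stat = stat,
          prob = stats::pchisq(stat, df = df, lower.tail = FALSE))
      }
    }
  }
  out <- if (idx > 0) dplyr::bind_rows(rows[seq_len(idx)]) else
    tibble::tibble(i = integer(), j = integer(), m = integer(),
                   n = integer(), stat = numeric(), prob = numeric())
  structure(out, class = c("support_matrix", class(tibble::tibble())),
            mode = mode, stds = stds, tolerance_units = config$tolerance_units,
            std_factor = config$std_factor, n_input = n_in, n_root = n_rt)
}

support_set <- function(sm, i, j) {
  sel <- sm$i == i & sm$j == j
  cbind(m = sm$m[sel], n = sm$n[sel])
}

#' Robustness score of a candidate peak mapping
#'
#' Scores the mapping (i, j) by summing, over every member (m, n) of its
#' support set, the Jaccard similarity between the support sets of (i, j) and
#' of (m, n), weighted by the chi-square upper-tail probability of the
#' corresponding difference of peak differences. Each support set enters the
#' Jaccard comparison together with its defining mapping pair (a mapping
#' always supports itself), so two mutually supporting mappings with
#' identical support otherwise have similarity 1: a single-member support
#' set with zero differences scores exactly 1. An empty support set scores
#' 0; the higher the score, the larger (and more internally concordant) the
#' set of peak mappings agreeing with (i, j).
#'
#' @param sm A [build_support_matrix()] result.
#' @param i,j Candidate mapping: input peak `i` onto root peak `j`.
#' @param chi_probs Optional numeric vector of chi-square probabilities for
#'   the members of the support set of (i, j), in the row order they appear in
#'   `sm`; defaults to the stored `prob` column.
#' @return A non-negative number.
#' @export
robustness <- function(sm, i, j, chi_probs = NULL) {
  sel <- which(sm$i == i & sm$j == j)
  if (length(sel) == 0) return(0)
  probs <- if (is.null(chi_probs)) sm$prob[sel] else chi_probs
  stopifnot(length(probs) == length(sel))
  n_rt <- attr(sm, "n_root")
  enc <- function(m, n) (m - 1) * n_rt + n
  ss_ij <- sort(c(enc(i, j), enc(sm$m[sel], sm$n[sel])))
  total <- 0
  for (r in seq_along(sel)) {
    mm <- sm$m[sel[r]]; nn <- sm$n[sel[r]]
    sel_mn <- which(sm$i == mm & sm$j == nn)
    ss_mn <- sort(c(enc(mm, nn), enc(sm$m[sel_mn], sm$n[sel_mn])))
    inter <- length(intersect(ss_ij, ss_mn))
    uni <- length(ss_ij) + length(ss_mn) - inter
    jac <- if (uni == 0) 0 else inter / uni
    total <- total + jac * probs[r]
  }
  total
}

# Pick the best cell from an R support matrix (reference engine).
best_cell_r <- function(sm) {
  cells <- dplyr::distinct(tibble::as_tibble(sm)[c("i", "j")])
  if (nrow(cells) == 0) return(NULL)
  rob <- purrr::map_dbl(seq_len(nrow(cells)),
                        function(r) robustness(sm, cells$i[r], cells$j[r]))
  size <- purrr::map_int(seq_len(nrow(cells)), function(r) {
    sum(sm$i == cells$i[r] & sm$j == cells$j[r])
  })
  ord <- order(-rob, -size, cells$i, cells$j)
  b <- ord[1]
  if (rob[b] <= 0) return(NULL)
  sel <- which(sm$i == cells$i[b] & sm$j == cells$j[b])
  list(i = cells$i[b], j = cells$j[b], robustness = rob[b],
       members = cbind(m = sm$m[sel], n = sm$n[sel]), probs = sm$prob[sel])
}

# Resolve the best cell's support list into a one-to-one peak mapping.
# The cell (i, j) itself enters with probability 1 (zero difference by
# construction). Conflicts are resolved greedily by descending chi-square
# probability; in self mode pairs are first canonicalized to m < n (each
# within-spin-system pair appears in both orders) and each peak may appear in
# at most one mapped pair overall.
resolve_mapping <- function(best, mode) {
  pairs <- rbind(c(best$i, best$j), best$members)
  probs <- c(1, best$probs)
  if (mode == "self") {
    a <- pmin(pairs[, 1], pairs[, 2])
    b <- pmax(pairs[, 1], pairs[, 2])
    pairs <- cbind(a, b)
  }
  ord <- order(-probs, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  probs <- probs[ord]
  keep <- logical(nrow(pairs))
  if (mode == "self") {
    used <- integer(0)
    for (r in seq_len(nrow(pairs))) {
      if (!(pairs[r, 1] %in% used) && !(pairs[r, 2] %in% used)) {
        keep[r] <- TRUE
        used <- c(used, pairs[r, 1], pairs[r, 2])
      }
    }
  } else {
    used_in <- integer(0); used_rt <- integer(0)
    for (r in seq_len(nrow(pairs))) {
      if (!(pairs[r, 1] %in% used_in) && !(pairs[r, 2] %in% used_rt)) {
        keep[r] <- TRUE
        used_in <- c(used_in, pairs[r, 1])
        used_rt <- c(used_rt, pairs[r, 2])
      }
    }
  }
  tibble::tibble(input = pairs[keep, 1], root = pairs[keep, 2],
                 prob = probs[keep])
}

#' Register an input peak list against a root peak list
#'
#' Finds the best mapping of peaks from the input list onto the root list and
#' derives per-dimension registration statistics, iterating until they
#' converge. Each iteration builds the support matrix under the current
#' working standard deviations, scores every candidate mapping by its
#' [robustness()], takes the support list of the best-scoring mapping as the
#' mapped peak pairs, and recomputes the statistics from those pairs:
#'
#' * pairwise mode: `offsets` = per-dimension mean of (input - root)
#'   differences over mapped pairs; `stds` = per-dimension standard deviation
#'   of those differences;
#' * self mode (a single peak list registered against itself, identical peak
#'   mappings ignored): offsets are fixed at zero and `stds` is the
#'   per-dimension standard deviation of within-list mapped-pair differences
#'   about zero.
#'
#' `stds` is therefore on the *matched-difference* scale. Since a difference
#' of two peaks that each carry positional noise `sigma` has standard
#' deviation `sqrt(2)*sigma`, the result also reports
#' `sigma = stds / sqrt(2)`, the per-peak positional standard deviation
#' estimate (the quantity recovered in parameter-recovery checks).
#'
#' @param input_pl Input peak list.
#' @param root_pl Root (reference) peak list; defaults to `input_pl`.
#' @param mode `"auto"` (self if `root_pl` is missing or identical to
#'   `input_pl`), `"pairwise"` or `"self"`.
#' @param config A [registration_config()].
#' @param engine `"cpp"` (default, accelerated) or `"r"` (reference
#'   implementation via [build_support_matrix()]; use only on small lists).
#' @return An object of class `registration`: a list with elements `mode`,
#'   `offsets`, `stds`, `sigma`, `n_matched`, `iterations`, `best_pair`,
#'   `robustness_best`, `mapped_pairs` (tibble), `trace` (tibble of
#'   per-iteration stds), `converged`, `low_confidence`, `failed`.
#' @examples
#' pl <- simulate_peaklist(synth_assignments(40, seed = 1),
#'                         noise = noise_model(c(0.002, 0.02, 0.02)), seed = 2)
#' reg <- register(pl)
#' tidy(reg)
#' @export
register <- function(input_pl, root_pl = NULL,
                     mode = c("auto", "pairwise", "self"),
                     config = registration_config(),
                     engine = c("cpp", "r")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  validate_peak_list(input_pl)
  self_mode <- is.null(root_pl) || identical(root_pl, input_pl)
  if (mode == "auto") mode <- if (self_mode) "self" else "pairwise"
  if (mode == "self" && !self_mode) {
    stop("mode = 'self' requires registering a peak list against itself",
         call. = FALSE)
  }
  if (is.null(root_pl)) root_pl <- input_pl
  validate_peak_list(root_pl)
  cd_in <- comparable_dims(input_pl)
  cd_rt <- comparable_dims(root_pl)
  if (length(cd_in) != length(cd_rt)) {
    stop("peak lists have different numbers of comparable dimensions",
         call. = FALSE)
  }
  k <- length(cd_in)
  labs <- dim_labels(input_pl)[cd_in]
  stds <- config$initial_stds
  if (is.null(stds)) stds <- default_initial_stds(input_pl)
  stopifnot(length(stds) == k)
  stds <- pmax(stds, config$std_floor)

  x <- shift_matrix(input_pl)[, cd_in, drop = FALSE]
  y <- shift_matrix(root_pl)[, cd_rt, drop = FALSE]

  trace <- list()
  result_stats <- NULL
  converged <- FALSE
  failed <- FALSE
  iter <- 0L
  best <- NULL
  mapping <- NULL

  while (iter < config$max_iterations) {
    iter <- iter + 1L
    best <- find_best_cell(x, y, stds, config, mode, engine,
                           input_pl, root_pl)
    if (is.null(best)) {
      failed <- iter == 1L
      iter <- iter - 1L
      break
    }
    mapping <- resolve_mapping(best, mode)
    d <- x[mapping$input, , drop = FALSE] - y[mapping$root, , drop = FALSE]
    nm <- nrow(d)
    if (mode == "self") {
      offsets <- rep(0, k)
      new_stds <- if (config$estimator == "mad") {
        apply(d, 2, function(v) 1.4826 * stats::median(abs(v)))
      } else {
        sqrt(colSums(d^2) / max(1, nm - 1))
      }
    } else {
      offsets <- colMeans(d)
      new_stds <- if (nm < 2) rep(0, k)
      else if (config$estimator == "mad") apply(d, 2, stats::mad)
      else apply(d, 2, stats::sd)
    }
    offsets <- unname(offsets)
    new_stds <- unname(new_stds)
    new_stds <- pmax(new_stds, config$std_floor)
    trace[[iter]] <- tibble::tibble(iteration = iter, dim = seq_len(k),
                                    dim_label = labs, std = new_stds)
    rel <- abs(new_stds - stds) / pmax(stds, config$std_floor)
    result_stats <- list(offsets = offsets, stds = new_stds, n_matched = nm)
    stds <- new_stds
    if (max(rel) < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }

  if (is.null(result_stats)) {
    result_stats <- list(offsets = rep(0, k),
                         stds = pmax(if (is.null(config$initial_stds))
                           default_initial_stds(input_pl) else
                             config$initial_stds, config$std_floor),
                         n_matched = 0L)
    failed <- TRUE
  }

  structure(list(
    mode = mode,
    dim_labels = labs,
    offsets = result_stats$offsets,
    stds = result_stats$stds,
    sigma = result_stats$stds / sqrt(2),
    n_matched = result_stats$n_matched,
    iterations = iter,
    best_pair = if (!is.null(best)) c(input = best$i, root = best$j) else
      c(input = NA_integer_, root = NA_integer_),
    robustness_best = if (!is.null(best)) best$robustness else 0,
    mapped_pairs = if (!is.null(mapping)) mapping else
      tibble::tibble(input = integer(), root = integer(), prob = numeric()),
    trace = if (length(trace) > 0) dplyr::bind_rows(trace) else
      tibble::tibble(iteration = integer(), dim = integer(),
                     dim_label = character(), std = numeric()),
    converged = converged,
    low_confidence = result_stats$n_matched < 3,
    failed = failed,
    config = config),
    class = "registration")
}

# The working `stds` are on the matched-difference scale; the match
# tolerance is expressed in per-peak standard-deviation units (sigma =
# std / sqrt(2)), hence the sqrt(2) conversion when calling the engines.
find_best_cell <- function(x, y, stds, config, mode, engine,
                           input_pl, root_pl) {
  if (engine == "cpp") {
    res <- cpp_best_cell(x, y, stds, config$tolerance_units / sqrt(2),
                         config$std_factor, mode == "self")
    if (res$i < 0) return(NULL)
    list(i = res$i, j = res$j, robustness = res$robustness,
         members = cbind(m = res$members_m, n = res$members_n),
         probs = res$probs)
  } else {
    cfg_eff <- config
    cfg_eff$tolerance_units <- config$tolerance_units / sqrt(2)
    sm <- build_support_matrix(input_pl, root_pl, stds, cfg_eff, mode)
    best_cell_r(sm)
  }
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("Registration analysis (%s mode)%s\n", x$mode,
              if (x$failed) " -- FAILED (no support found)" else ""))
  if (!x$failed) {
    cat(sprintf("  %d mapped pairs, %d iteration(s), %s\n", x$n_matched,
                x$iterations,
                if (x$converged) "converged" else "not converged"))
    for (l in seq_along(x$stds)) {
      cat(sprintf("  dim %s: offset %+.5f ppm, std %.5f ppm (sigma %.5f)\n",
                  x$dim_labels[l], x$offsets[l], x$stds[l], x$sigma[l]))
    }
    if (x$low_confidence) cat("  warning: fewer than 3 mapped pairs\n")
  }
  invisible(x)
}
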