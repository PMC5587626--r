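# Per-(residue, atom) Gaussian priors used by the synthetic assigned-shift
# generator: typical protein chemical-shift statistics (ppm). Glycine has no
# CB; proline has no amide H. Amide H and CO use global priors; amide N uses
# a lower mean for glycine.
aa_shift_priors <- local({
  ca <- c(A = 53.1, R = 56.8, N = 53.5, D = 54.7, C = 58.2, Q = 56.6,
          E = 57.3, G = 45.4, H = 56.5, I = 61.6, L = 55.6, K = 56.9,
          M = 56.1, F = 58.1, P = 63.3, S = 58.7, T = 62.2, W = 57.7,
          Y = 58.1, V = 62.5)
  ca_sd <- c(A = 1.9, R = 2.3, N = 1.9, D = 2.0, C = 3.3, Q = 2.2,
             E = 2.1, G = 1.3, H = 2.3, I = 2.7, L = 2.2, K = 2.2,
             M = 2.2, F = 2.6, P = 1.6, S = 2.1, T = 2.6, W = 2.6,
             Y = 2.6, V = 2.9)
  cb <- c(A = 19.0, R = 30.7, N = 38.7, D = 40.9, C = 32.8, Q = 29.2,
          E = 30.0, G = NA, H = 30.2, I = 38.6, L = 42.3, K = 32.8,
          M = 33.0, F = 39.9, P = 31.8, S = 63.8, T = 69.7, W = 29.9,
          Y = 39.2, V = 32.7)
  cb_sd <- c(A = 1.8, R = 1.8, N = 1.7, D = 1.6, C = 6.1, Q = 1.8,
             E = 1.7, G = NA, H = 2.1, I = 2.0, L = 1.9, K = 1.8,
             M = 2.2, F = 2.1, P = 1.2, S = 1.5, T = 1.6, W = 2.0,
             Y = 2.2, V = 1.8)
  list(ca = ca, ca_sd = ca_sd, cb = cb, cb_sd = cb_sd,
       h_mean = 8.28, h_sd = 0.60,
       n_mean = 119.8, n_sd = 4.3, n_mean_gly = 109.5, n_sd_gly = 3.8,
       co_mean = 176.3, co_sd = 2.0)
})

# background amino-acid frequencies used for random sequences
aa_background_freqs <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.059,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.065)

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic assigned chemical-shift table
#'
#' Draws a random protein sequence and assigns each residue H, N, CA, CB and
#' CO chemical shifts from per-residue-type Gaussian priors reflecting
#' typical protein shift statistics (amide H about 8.3 +/- 0.6 ppm, amide N
#' about 120 +/- 4 ppm, CA/CB per residue type). Glycine residues carry no
#' CB; proline residues carry no amide H. Reproducible under `seed`.
#'
#' @param n_res Number of residues (>= 3).
#' @param seed Optional integer seed (the global RNG state is restored
#'   afterwards).
#' @param aa_freqs Optional named numeric vector of amino-acid sampling
#'   weights (one-letter codes); defaults to background protein frequencies.
#' @param protein_id Identifier stored on the table.
#' @return A tibble of class `shift_table` with columns `res_id`, `aa`,
#'   `atom`, `shift` (long format) and attribute `protein_id`.
#' @export
synth_assignments <- function(n_res, seed = NULL, aa_freqs = NULL,
                              protein_id = "synthetic") {
  stopifnot(n_res >= 3)
  if (is.null(aa_freqs)) aa_freqs <- aa_background_freqs
  stopifnot(!is.null(names(aa_freqs)), all(aa_freqs >= 0), sum(aa_freqs) > 0)
  pr <- aa_shift_priors
  with_seed(seed, {
    seq_aa <- sample(names(aa_freqs), n_res, replace = TRUE,
                     prob = aa_freqs)
    rows <- purrr::map(seq_len(n_res), function(i) {
      aa <- seq_aa[i]
      atoms <- character(0); shifts <- numeric(0)
      if (aa != "P") {
        atoms <- c(atoms, "H")
        shifts <- c(shifts, stats::rnorm(1, pr$h_mean, pr$h_sd))
      }
      atoms <- c(atoms, "N")
      shifts <- c(shifts, if (aa == "G")
        stats::rnorm(1, pr$n_mean_gly, pr$n_sd_gly)
        else stats::rnorm(1, pr$n_mean, pr$n_sd))
      atoms <- c(atoms, "CA")
      shifts <- c(shifts, stats::rnorm(1, pr$ca[[aa]], pr$ca_sd[[aa]]))
      if (aa != "G") {
        atoms <- c(atoms, "CB")
        shifts <- c(shifts, stats::rnorm(1, pr$cb[[aa]], pr$cb_sd[[aa]]))
      }
      atoms <- c(atoms, "CO")
      shifts <- c(shifts, stats::rnorm(1, pr$co_mean, pr$co_sd))
      tibble::tibble(res_id = i, aa = aa, atom = atoms, shift = shifts)
    })
    tbl <- dplyr::bind_rows(rows)
    structure(tbl, class = c("shift_table", class(tibble::tibble())),
              protein_id = protein_id)
  })
}

#' @rdname synth_assignments
#' @param table A `shift_table`.
#' @export
sequence_of <- function(table) {
  res <- dplyr::distinct(tibble::as_tibble(table)[c("res_id", "aa")])
  res <- dplyr::arrange(res, .data$res_id)
  paste(res$aa, collapse = "")
}

lookup_shift <- function(shift_env, res_id, atom) {
  key <- paste0(res_id, ".", atom)
  if (!is.null(shift_env[[key]])) shift_env[[key]] else NA_real_
}

build_shift_env <- function(table) {
  env <- new.env(parent = emptyenv(), size = nrow(table) * 2)
  for (r in seq_len(nrow(table))) {
    env[[paste0(table$res_id[r], ".", table$atom[r])]] <- table$shift[r]
  }
  env
}

default_hncocacb <- function() {
  spectrum_description("HNcoCACB", list(
    list(classes = "H", position = 0L, label = "H"),
    list(classes = "N", position = 0L, label = "N"),
    list(classes = c("CA", "CB"), position = -1L, label = "CA/CB")))
}

#' Build an ideal (zero-variance) peak list from an assigned shift table
#'
#' Walks the sequence and, for each anchor residue, emits one peak per
#' combination of resonance-class alternatives declared by the spectrum
#' description, reading each dimension's shift from the residue at the
#' declared relative position. Combinations touching a missing shift (e.g.
#' CB of a glycine, amide H of a proline, or a predecessor that does not
#' exist) are skipped. For HN(CO)CACB this yields, for every residue i with
#' an amide H whose predecessor exists, the peaks (H_i, N_i, CA_{i-1}) and --
#' when residue i-1 has a CB -- (H_i, N_i, CB_{i-1}). Each peak's
#' `truth_group` is the anchor residue index, i.e. its true spin system.
#'
#' @param table A [synth_assignments()] shift table (or any tibble with
#'   columns `res_id`, `aa`, `atom`, `shift`).
#' @param spec A [spectrum_description()]; defaults to HN(CO)CACB.
#' @return A [peak_list()] with `truth_group` set and comparable dimensions
#'   taken from the spectrum description.
#' @export
ideal_peaklist <- function(table, spec = NULL) {
  if (is.null(spec)) spec <- default_hncocacb()
  stopifnot(inherits(spec, "spectrum_description"))
  res <- dplyr::arrange(
    dplyr::distinct(tibble::as_tibble(table)[c("res_id", "aa")]),
    .data$res_id)
  env <- build_shift_env(table)
  k <- length(spec$dimensions)
  shifts <- list(); labels <- character(0); groups <- integer(0)

  for (i in res$res_id) {
    # expand class alternatives per dimension into available (atom, shift)
    dim_opts <- vector("list", k)
    ok <- TRUE
    for (d in seq_len(k)) {
      dm <- spec$dimensions[[d]]
      target <- i + dm$position
      opts <- list()
      if (target >= min(res$res_id) && target <= max(res$res_id)) {
        for (cl in expand_classes(dm$classes)) {
          val <- lookup_shift(env, target, cl)
          if (!is.na(val)) opts[[length(opts) + 1L]] <-
              list(atom = cl, res = target, shift = val)
        }
      }
      if (length(opts) == 0) { ok <- FALSE; break }
      dim_opts[[d]] <- opts
    }
    if (!ok) next
    combos <- expand.grid(lapply(dim_opts, seq_along))
    aa_i <- res$aa[res$res_id == i]
    for (r in seq_len(nrow(combos))) {
      sel <- purrr::map2(dim_opts, as.integer(combos[r, ]),
                         function(opts, ix) opts[[ix]])
      shifts[[length(shifts) + 1L]] <- vapply(sel, `[[`, numeric(1), "shift")
      comp <- vapply(sel, function(s) {
        if (s$res == i) s$atom else paste0(s$atom, s$res)
      }, character(1))
      labels <- c(labels, paste0(aa_i, i, ":", paste(comp, collapse = "-")))
      groups <- c(groups, i)
    }
  }
  shift_mat <- if (length(shifts) > 0) do.call(rbind, shifts) else
    matrix(numeric(0), 0, k)
  peak_list(shift_mat, label = labels, truth_group = groups,
            name = attr(table, "protein_id") %||% "ideal",
            spectrum_type = spec$name,
            dim_labels = vapply(spec$dimensions, `[[`, character(1), "label"),
            comparable_dims = spec$comparable_dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian positional-noise model for simulated peak lists
#'
#' Describes zero-mean Gaussian noise added independently to each peak
#' coordinate: a base standard deviation per dimension, optionally mixed with
#' a high-variance subpopulation (two sources of variance: a fraction of the
#' peaks receives noise with a multiplied standard deviation in the
#' designated dimensions, defaults 20% of peaks at 5x).
#'
#' @param sigma Numeric vector of base standard deviations (ppm), one per
#'   spectral dimension (values may be 0).
#' @param fraction_high Fraction of peaks in the high-variance subpopulation;
#'   `NULL` (default) for a single source of variance.
#' @param multiplier Standard-deviation multiplier for the high-variance
#'   subpopulation (default 5).
#' @param dims Dimensions (1-based) to which the multiplier applies; default
#'   all dimensions.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma, fraction_high = NULL, multiplier = 5,
                        dims = NULL) {
  stopifnot(all(sigma >= 0))
  if (!is.null(fraction_high)) {
    stopifnot(fraction_high > 0, fraction_high < 1, multiplier > 0)
  }
  structure(list(sigma = as.numeric(sigma),
                 fraction_high = fraction_high,
                 multiplier = multiplier,
                 dims = if (!is.null(dims)) as.integer(dims) else NULL),
            class = "noise_model")
}

#' Add positional noise to a peak list
#'
#' Perturbs every peak coordinate with independent zero-mean Gaussian noise
#' according to a [noise_model()]. With a two-source model, exactly
#' `round(fraction_high * n)` peaks (a simple random sample, drawn per peak,
#' not per spin system) receive `multiplier * sigma` noise in the designated
#' dimensions; all other peaks (and dimensions) receive base-`sigma` noise.
#' Labels, order and `truth_group` are preserved.
#'
#' @param pl A [peak_list()].
#' @param noise A [noise_model()] whose `sigma` has one entry per dimension
#'   of `pl`.
#' @param seed Optional integer seed (global RNG state restored afterwards).
#' @return A `peak_list` with perturbed shifts and a logical attribute
#'   `high_variance` marking the high-variance peaks (if a mixture was used).
#' @export
add_noise <- function(pl, noise, seed = NULL) {
  validate_peak_list(pl)
  stopifnot(inherits(noise, "noise_model"))
  k <- n_dims(pl)
  if (length(noise$sigma) != k) {
    stop("`noise$sigma` must have one entry per dimension", call. = FALSE)
  }
  n <- n_peaks(pl)
  with_seed(seed, {
    sm <- shift_matrix(pl)
    high <- rep(FALSE, n)
    if (!is.null(noise$fraction_high) && n > 0) {
      n_high <- round(noise$fraction_high * n)
      high[sample(n, n_high)] <- TRUE
    }
    hdims <- noise$dims %||% seq_len(k)
    for (l in seq_len(k)) {
      s <- rep(noise$sigma[l], n)
      if (l %in% hdims) s[high] <- s[high] * noise$multiplier
      sm[, l] <- sm[, l] + stats::rnorm(n, 0, s)
    }
    out <- peak_list(sm, label = pl$label, truth_group = pl$truth_group,
                     name = attr(pl, "pl_name"),
                     spectrum_type = attr(pl, "spectrum_type"),
                     dim_labels = dim_labels(pl),
                     comparable_dims = comparable_dims(pl))
    attr(out, "high_variance") <- high
    out
  })
}

#' Simulate an assigned peak list in one call
#'
#' Convenience wrapper: [ideal_peaklist()] followed by [add_noise()].
#'
#' @param table A shift table from [synth_assignments()].
#' @param spec A [spectrum_description()]; defaults to HN(CO)CACB.
#' @param noise A [noise_model()], or `NULL` for a zero-variance list.
#' @param seed Optional seed for the noise draw.
#' @return A [peak_list()].
#' @export
simulate_peaklist <- function(table, spec = NULL, noise = NULL, seed = NULL) {
  pl <- ideal_peaklist(table, spec)
  if (is.null(noise)) return(pl)
  add_noise(pl, noise, seed = seed)
}

#' Filter shift tables whose ideal peak lists are unusable
#'
#' Applies the two rejection rules used when preparing simulated cohorts:
#' a table is rejected if (a) its ideal peak list contains two peaks with
#' exactly identical coordinates in every dimension (duplicate peaks create
#' inherently overlapped spin systems regardless of variance), or (b) a
#' non-glycine residue that contributes to a carbon dimension lacks CA or CB
#' (missing data would depress grouping accuracy for reasons unrelated to
#' positional variance).
#'
#' @param tables A list of shift tables.
#' @param spec A [spectrum_description()]; defaults to HN(CO)CACB.
#' @return A list with `kept` (list of tables) and `rejected` (tibble with
#'   `protein_id` and `reason`).
#' @export
filter_peaklists <- function(tables, spec = NULL) {
  if (is.null(spec)) spec <- default_hncocacb()
  kept <- list()
  rejected <- list()
  carbon_dims <- which(vapply(spec$dimensions, function(d) {
    any(expand_classes(d$classes) %in% c("CA", "CB"))
  }, logical(1)))
  for (tb in tables) {
    pid <- attr(tb, "protein_id") %||% "unknown"
    reason <- NULL
    res <- dplyr::arrange(
      dplyr::distinct(tibble::as_tibble(tb)[c("res_id", "aa")]), .data$res_id)
    env <- build_shift_env(tb)
    # (b) missing CA/CB on contributing non-glycine residues
    for (i in res$res_id) {
      for (d in carbon_dims) {
        target <- i + spec$dimensions[[d]]$position
        sel <- res$aa[res$res_id == target]
        if (length(sel) == 0 || sel == "G") next
        # residue contributes only if the anchor actually yields peaks
        anchor_ok <- TRUE
        for (d2 in setdiff(seq_along(spec$dimensions), d)) {
          t2 <- i + spec$dimensions[[d2]]$position
          cls <- expand_classes(spec$dimensions[[d2]]$classes)
          if (!any(!is.na(vapply(cls, function(cl)
            lookup_shift(env, t2, cl), numeric(1))))) anchor_ok <- FALSE
        }
        if (!anchor_ok) next
        if (is.na(lookup_shift(env, target, "CA")) ||
            is.na(lookup_shift(env, target, "CB"))) {
          reason <- "missing CA/CB"
        }
      }
      if (!is.null(reason)) break
    }
    # (a) exact duplicate peaks in all dimensions
    if (is.null(reason)) {
      pl <- ideal_peaklist(tb, spec)
      if (anyDuplicated(shift_matrix(pl)) > 0) reason <- "duplicate peaks"
    }
    if (is.null(reason)) {
      kept[[length(kept) + 1L]] <- tb
    } else {
      rejected[[length(rejected) + 1L]] <-
        tibble::tibble(protein_id = pid, reason = reason)
    }
  }
  list(kept = kept,
       rejected = if (length(rejected) > 0) dplyr::bind_rows(rejected) else
         tibble::tibble(protein_id = character(), reason = character()))
}

#' Define and run a grid of simulated peak lists
#'
#' `simulation_grid()` declares per-dimension standard-deviation ranges and a
#' variance-source condition; defaults mirror the standard simulated
#' HN(CO)CACB design (H: 0.001--0.050 ppm, C and N: 0.01--0.50 ppm; the
#' two-source conditions use half-range maxima with 20% of peaks at 5x).
#' `run_grid()` writes one simulated peak list file per (protein x step) plus
#' a manifest CSV recording file, condition, sigma values and seed;
#' re-running with the same seed reproduces identical files.
#'
#' @param h_range,c_range,n_range Length-2 numeric ranges of base standard
#'   deviations (ppm) for H-, C- and N-class dimensions.
#' @param steps Number of grid steps (linear).
#' @param source `"single"` (one source of variance in all dimensions),
#'   `"two_all"` (two sources in all dimensions) or `"two_n"` (two sources in
#'   the N dimension only).
#' @param fraction_high,multiplier Two-source mixture parameters.
#' @return `simulation_grid()`: a list of class `simulation_grid`.
#' @export
simulation_grid <- function(h_range = c(0.001, 0.050),
                            c_range = c(0.01, 0.50),
                            n_range = c(0.01, 0.50),
                            steps = 10L,
                            source = c("single", "two_all", "two_n"),
                            fraction_high = 0.2, multiplier = 5) {
  source <- match.arg(source)
  stopifnot(length(h_range) == 2, length(c_range) == 2, length(n_range) == 2,
            steps >= 1)
  structure(list(h = seq(h_range[1], h_range[2], length.out = steps),
                 c = seq(c_range[1], c_range[2], length.out = steps),
                 n = seq(n_range[1], n_range[2], length.out = steps),
                 steps = as.integer(steps), source = source,
                 fraction_high = fraction_high, multiplier = multiplier),
            class = "simulation_grid")
}

dim_noise_class <- function(spec) {
  vapply(spec$dimensions, function(d) {
    cl <- expand_classes(d$classes)[1]
    if (substr(cl, 1, 1) == "H") "H" else if (substr(cl, 1, 1) == "N") "N"
    else "C"
  }, character(1))
}

#' @rdname simulation_grid
#' @param tables List of shift tables (e.g. from [synth_assignments()]).
#' @param grid A `simulation_grid`.
#' @param outdir Output directory (created if needed).
#' @param spec A [spectrum_description()]; defaults to HN(CO)CACB.
#' @param format Peak list file format; JSON retains truth groups.
#' @param seed Base integer seed; each file uses a distinct derived seed.
#' @return `run_grid()`: the manifest tibble (also written to
#'   `manifest.csv` in `outdir`), invisibly.
#' @export
run_grid <- function(tables, grid, outdir, spec = NULL,
                     format = c("json", "sparky", "autoassign"),
                     seed = 1L) {
  format <- match.arg(format)
  if (is.null(spec)) spec <- default_hncocacb()
  stopifnot(inherits(grid, "simulation_grid"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  classes <- dim_noise_class(spec)
  ext <- switch(format, json = "json", sparky = "list", autoassign = "pks")
  rows <- list()
  file_idx <- 0L
  for (ti in seq_along(tables)) {
    pid <- attr(tables[[ti]], "protein_id") %||% paste0("protein", ti)
    ideal <- ideal_peaklist(tables[[ti]], spec)
    for (si in seq_len(grid$steps)) {
      file_idx <- file_idx + 1L
      sig <- c(H = grid$h[si], C = grid$c[si], N = grid$n[si])[classes]
      nm <- switch(grid$source,
        single = noise_model(sig),
        two_all = noise_model(sig, fraction_high = grid$fraction_high,
                              multiplier = grid$multiplier),
        two_n = noise_model(sig, fraction_high = grid$fraction_high,
                            multiplier = grid$multiplier,
                            dims = which(classes == "N")))
      fseed <- (seed * 10000L + file_idx) %% .Machine$integer.max
      noisy <- add_noise(ideal, nm, seed = fseed)
      fname <- sprintf("%s_step%02d.%s", pid, si, ext)
      write_peaklist(noisy, file.path(outdir, fname), format = format)
      rows[[file_idx]] <- tibble::tibble(
        file = fname, protein_id = pid, step = si, source = grid$source,
        sigma_h = grid$h[si], sigma_c = grid$c[si], sigma_n = grid$n[si],
        seed = fseed)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
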