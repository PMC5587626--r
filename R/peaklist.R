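#' Construct a peak list
#'
#' A peak list is the basic container of the package: a tibble with one row per
#' peak, one chemical-shift column per spectral dimension (named `w1`, `w2`,
#' ...) plus `peak_id`, `label` and `truth_group` columns, and spectrum
#' metadata stored as attributes. Chemical shifts are always in ppm.
#'
#' @param shifts A numeric matrix or data frame of chemical shifts in ppm, one
#'   row per peak and one column per spectral dimension (2--4 dimensions).
#' @param label Optional character vector of assignment labels, one per peak.
#'   Unassigned peaks use the Sparky convention `"?-?-?"`.
#' @param truth_group Optional integer vector of true spin-system identifiers,
#'   present for simulated or assigned peaks and `NA` otherwise.
#' @param name Name of the peak list (e.g. the protein or file stem).
#' @param spectrum_type Spectrum type string, e.g. `"HNcoCACB"` or `"NCACX"`.
#' @param dim_labels Character vector naming each dimension (e.g.
#'   `c("H", "N", "CA/CB")`). Defaults to `w1`, `w2`, ...
#' @param comparable_dims Integer indices (1-based) of the dimensions used for
#'   matching and grouping -- the dimensions shared by peaks of one spin
#'   system. Defaults to all dimensions.
#'
#' @return A tibble of class `peak_list`.
#' @examples
#' pl <- peak_list(rbind(c(8.21, 118.3, 55.1), c(8.21, 118.3, 31.2)),
#'                 dim_labels = c("H", "N", "CA/CB"), comparable_dims = 1:2)
#' n_peaks(pl)
#' @export
peak_list <- function(shifts, label = NULL, truth_group = NULL,
                      name = "", spectrum_type = "",
                      dim_labels = NULL, comparable_dims = NULL) {
  shifts <- as.matrix(shifts)
  if (!is.numeric(shifts)) {
    stop("`shifts` must be numeric (ppm values)", call. = FALSE)
  }
  storage.mode(shifts) <- "double"
  n <- nrow(shifts)
  k <- ncol(shifts)
  if (n > 0 && any(!is.finite(shifts))) {
    stop("all chemical shifts must be finite", call. = FALSE)
  }
  if (is.null(dim_labels)) dim_labels <- paste0("w", seq_len(k))
  if (length(dim_labels) != k) {
    stop("`dim_labels` must have one entry per dimension", call. = FALSE)
  }
  if (is.null(comparable_dims)) comparable_dims <- seq_len(k)
  comparable_dims <- as.integer(comparable_dims)
  if (length(comparable_dims) == 0L || anyDuplicated(comparable_dims) ||
      any(comparable_dims < 1L) || any(comparable_dims > k)) {
    stop("`comparable_dims` must be distinct dimension indices in 1..", k,
         call. = FALSE)
  }
  if (is.null(label)) label <- rep("?-?-?", n)
  if (is.null(truth_group)) truth_group <- rep(NA_integer_, n)
  stopifnot(length(label) == n, length(truth_group) == n)

  out <- tibble::tibble(peak_id = seq_len(n),
                        label = as.character(label),
                        truth_group = as.integer(truth_group))
  colnames(shifts) <- paste0("w", seq_len(k))
  out <- dplyr::bind_cols(out, tibble::as_tibble(shifts))
  new_peak_list(out, name = name, spectrum_type = spectrum_type,
                dim_labels = dim_labels, comparable_dims = comparable_dims)
}

new_peak_list <- function(tbl, name, spectrum_type, dim_labels,
                          comparable_dims) {
  structure(tbl,
            class = c("peak_list", class(tibble::tibble())),
            pl_name = name,
            spectrum_type = spectrum_type,
            dim_labels = dim_labels,
            comparable_dims = as.integer(comparable_dims))
}

#' Peak list accessors
#'
#' Small helpers for extracting the pieces of a [peak_list()]: the shift
#' matrix, the number of peaks and dimensions, and the comparable-dimension
#' indices (whose count is the degrees of freedom `df` used by the chi-square
#' statistics).
#'
#' @param pl A `peak_list`.
#' @return `shift_matrix()` a numeric matrix (peaks x dimensions);
#'   `n_peaks()`/`n_dims()` integers; `comparable_dims()` an integer vector;
#'   `dim_labels()` a character vector.
#' @export
shift_matrix <- function(pl) {
  k <- length(attr(pl, "dim_labels"))
  m <- as.matrix(as.data.frame(pl)[paste0("w", seq_len(k))])
  rownames(m) <- NULL
  m
}

#' @rdname shift_matrix
#' @export
n_peaks <- function(pl) nrow(pl)

#' @rdname shift_matrix
#' @export
n_dims <- function(pl) length(attr(pl, "dim_labels"))

#' @rdname shift_matrix
#' @export
comparable_dims <- function(pl) attr(pl, "comparable_dims")

#' @rdname shift_matrix
#' @export
dim_labels <- function(pl) attr(pl, "dim_labels")

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("# A peak list: %d peaks x %d dims (%s)%s\n",
              n_peaks(x), n_dims(x),
              paste(dim_labels(x), collapse = ", "),
              if (nzchar(attr(x, "pl_name"))) paste0(" -- ", attr(x, "pl_name"))
              else ""))
  cat(sprintf("# comparable dims: %s\n",
              paste(comparable_dims(x), collapse = ", ")))
  NextMethod()
}

validate_peak_list <- function(pl) {
  stopifnot(inherits(pl, "peak_list"))
  k <- n_dims(pl)
  cd <- comparable_dims(pl)
  if (length(cd) == 0L || anyDuplicated(cd) || any(cd < 1L | cd > k)) {
    stop("invalid comparable_dims", call. = FALSE)
  }
  if (n_peaks(pl) > 0 && any(!is.finite(shift_matrix(pl)))) {
    stop("non-finite chemical shifts", call. = FALSE)
  }
  invisible(pl)
}

# keep attributes through dplyr verbs that return data frames
#' @export
`[.peak_list` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(paste0("w", seq_len(n_dims(x))) %in% names(out))) {
    out <- new_peak_list(tibble::as_tibble(out),
                         name = attr(x, "pl_name"),
                         spectrum_type = attr(x, "spectrum_type"),
                         dim_labels = dim_labels(x),
                         comparable_dims = comparable_dims(x))
  }
  out
}

#' Subset a peak list by peak position
#'
#' Returns a new `peak_list` containing the peaks at the given row positions,
#' renumbering `peak_id` consecutively while keeping labels, shifts and truth
#' groups. Used by the iterative pipeline to carve out the unclustered subset.
#'
#' @param pl A `peak_list`.
#' @param idx Integer row positions to keep.
#' @return A `peak_list`.
#' @export
subset_peaks <- function(pl, idx) {
  tbl <- tibble::as_tibble(as.data.frame(pl))[idx, , drop = FALSE]
  tbl$peak_id <- seq_len(nrow(tbl))
  new_peak_list(tbl, name = attr(pl, "pl_name"),
                spectrum_type = attr(pl, "spectrum_type"),
                dim_labels = dim_labels(pl),
                comparable_dims = comparable_dims(pl))
}

# ---------------------------------------------------------------------------
# File formats
#
# Sparky: whitespace columns, header "Assignment w1 w2 [w3 [w4]]"; label first.
# AutoAssign-style: tab-separated with one-line header
#   "Index\tw1\t...\twk\tAssignment"; peak index first, label last.
# JSON: {"name":..., "spectrum_type":..., "dims":[...], "comparable_dims":[...],
#        "peaks":[{"shifts":[...], "label":..., "truth_group":...}, ...]}
# Text formats round ppm values to 4 decimals; JSON keeps full precision.
# ---------------------------------------------------------------------------

#' Read a peak list file
#'
#' Parses a peak list in one of three dialects: Sparky (`Assignment w1 w2
#' [w3 [w4]]` whitespace columns), an AutoAssign-style tab-separated table with
#' a one-line header (`Index`, shift columns, `Assignment`), or this package's
#' JSON dialect (which also carries spectrum metadata and truth groups).
#'
#' @param path Path to the file.
#' @param format One of `"sparky"`, `"autoassign"`, `"json"`.
#' @param name Optional peak list name; defaults to the file stem (text
#'   formats) or the stored name (JSON).
#' @param comparable_dims Optional comparable-dimension indices to set on the
#'   result (text formats carry no metadata; default all dimensions).
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, format = c("sparky", "autoassign", "json"),
                          name = NULL, comparable_dims = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
         sparky = read_sparky(path, name, comparable_dims),
         autoassign = read_autoassign(path, name, comparable_dims),
         json = read_json_peaklist(path, name, comparable_dims))
}

parse_shift_fields <- function(fields, path, line_no) {
  x <- suppressWarnings(as.numeric(fields))
  if (any(is.na(x))) {
    stop(sprintf("%s: cannot parse chemical shift on line %d", path, line_no),
         call. = FALSE)
  }
  x
}

read_sparky <- function(path, name, cdims) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    stop(path, ": empty Sparky peak list (missing header)", call. = FALSE)
  }
  header <- strsplit(trimws(lines[keep[1]]), "\\s+")[[1]]
  if (tolower(header[1]) != "assignment") {
    stop(path, ": line ", keep[1],
         ": expected Sparky header starting with 'Assignment'", call. = FALSE)
  }
  k <- length(header) - 1L
  body <- keep[-1]
  labels <- character(0)
  shifts <- matrix(numeric(0), 0, max(k, 1L))
  for (ln in body) {
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) != k + 1L) {
      stop(sprintf("%s: line %d has %d fields, expected %d (inconsistent dimensionality)",
                   path, ln, length(fields), k + 1L), call. = FALSE)
    }
    labels <- c(labels, fields[1])
    shifts <- rbind(shifts, parse_shift_fields(fields[-1], path, ln))
  }
  peak_list(shifts, label = labels, name = name,
            comparable_dims = cdims)
}

read_autoassign <- function(path, name, cdims) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    stop(path, ": empty AutoAssign peak table (missing header)", call. = FALSE)
  }
  header <- strsplit(lines[keep[1]], "\t")[[1]]
  if (tolower(trimws(header[1])) != "index") {
    stop(path, ": line ", keep[1],
         ": expected tab-separated header starting with 'Index'", call. = FALSE)
  }
  k <- length(header) - 2L
  if (k < 1L) stop(path, ": header declares no shift columns", call. = FALSE)
  labels <- character(0)
  shifts <- matrix(numeric(0), 0, k)
  for (ln in keep[-1]) {
    fields <- strsplit(lines[ln], "\t")[[1]]
    if (length(fields) != k + 2L) {
      stop(sprintf("%s: line %d has %d fields, expected %d (inconsistent dimensionality)",
                   path, ln, length(fields), k + 2L), call. = FALSE)
    }
    labels <- c(labels, trimws(fields[k + 2L]))
    shifts <- rbind(shifts, parse_shift_fields(fields[2:(k + 1L)], path, ln))
  }
  peak_list(shifts, label = labels, name = name, comparable_dims = cdims)
}

read_json_peaklist <- function(path, name, cdims) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$peaks)) stop(path, ": JSON peak list missing 'peaks'", call. = FALSE)
  n <- length(obj$peaks)
  dims <- unlist(obj$dims)
  get_len <- function(p) length(p$shifts)
  k <- if (!is.null(dims)) length(dims) else if (n > 0) get_len(obj$peaks[[1]]) else 0L
  shifts <- matrix(NA_real_, n, k)
  labels <- rep("?-?-?", n)
  tg <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- obj$peaks[[i]]
    if (get_len(p) != k) {
      stop(sprintf("%s: peak %d has %d dimensions, expected %d",
                   path, i, get_len(p), k), call. = FALSE)
    }
    shifts[i, ] <- unlist(p$shifts)
    if (!is.null(p$label)) labels[i] <- p$label
    if (!is.null(p$truth_group)) tg[i] <- as.integer(p$truth_group)
  }
  peak_list(shifts, label = labels, truth_group = tg,
            name = if (!is.null(obj$name)) obj$name else name,
            spectrum_type = if (!is.null(obj$spectrum_type)) obj$spectrum_type else "",
            dim_labels = if (!is.null(dims)) as.character(dims) else NULL,
            comparable_dims = if (!is.null(cdims)) cdims
                              else if (!is.null(obj$comparable_dims))
                                as.integer(unlist(obj$comparable_dims))
                              else NULL)
}

#' Write a peak list file
#'
#' Writes a [peak_list()] in Sparky, AutoAssign-style or JSON dialect (see
#' [read_peaklist()] for the layouts). Text formats emit shifts with four
#' decimal places so that a write/read round trip reproduces shifts to within
#' 1e-4 ppm; JSON stores full precision plus spectrum metadata and truth
#' groups.
#'
#' @param pl A `peak_list`.
#' @param path Output file path.
#' @param format One of `"sparky"`, `"autoassign"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path, format = c("sparky", "autoassign", "json")) {
  format <- match.arg(format)
  validate_peak_list(pl)
  k <- n_dims(pl)
  sm <- shift_matrix(pl)
  switch(format,
    sparky = {
      header <- paste(c("Assignment", paste0("w", seq_len(k))), collapse = "  ")
      rows <- vapply(seq_len(n_peaks(pl)), function(i) {
        paste(c(pl$label[i], sprintf("%.4f", sm[i, ])), collapse = "  ")
      }, character(1))
      writeLines(c(header, rows), path)
    },
    autoassign = {
      header <- paste(c("Index", paste0("w", seq_len(k)), "Assignment"),
                      collapse = "\t")
      rows <- vapply(seq_len(n_peaks(pl)), function(i) {
        paste(c(pl$peak_id[i], sprintf("%.4f", sm[i, ]), pl$label[i]),
              collapse = "\t")
      }, character(1))
      writeLines(c(header, rows), path)
    },
    json = {
      peaks <- purrr::map(seq_len(n_peaks(pl)), function(i) {
        p <- list(shifts = unname(sm[i, ]), label = pl$label[i])
        if (!is.na(pl$truth_group[i])) p$truth_group <- pl$truth_group[i]
        p
      })
      obj <- list(name = attr(pl, "pl_name"),
                  spectrum_type = attr(pl, "spectrum_type"),
                  dims = dim_labels(pl),
                  comparable_dims = comparable_dims(pl),
                  peaks = peaks)
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    })
  invisible(path)
}
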