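#' Spectrum descriptions
#'
#' A spectrum description declares, for each spectral dimension of an
#' experiment, which resonance classes can appear there (e.g. `CA`, `CB`, `N`)
#' and at which relative residue position (-1 = preceding residue, 0 = the
#' anchor residue, +1 = following residue, ...). A dimension may admit
#' alternative classes -- e.g. the carbon dimension of HN(CO)CACB is
#' `CA` *or* `CB` of residue i-1 -- in which case one peak is emitted per
#' available alternative. The pseudo-class `CX` expands to `CA`, `CB` and `CO`.
#'
#' The comparable dimensions (those shared by all peaks of one spin system,
#' used for matching and grouping) default to the dimensions with a single
#' resonance-class alternative: `H` and `N` for HN(CO)CACB-like spectra,
#' `N` and `CA` for NCACX-like spectra.
#'
#' @param name Spectrum name, e.g. `"HNcoCACB"`.
#' @param dimensions A list with one entry per dimension, each a list with
#'   elements `classes` (character vector of resonance-class tokens),
#'   `position` (integer relative residue position) and optionally `label`.
#' @param comparable_dims Optional integer indices of the comparable
#'   dimensions (1-based); derived from the dimension structure if omitted.
#' @return An object of class `spectrum_description`.
#' @examples
#' hncocacb <- spectrum_description("HNcoCACB", list(
#'   list(classes = "H", position = 0),
#'   list(classes = "N", position = 0),
#'   list(classes = c("CA", "CB"), position = -1)))
#' @export
spectrum_description <- function(name, dimensions, comparable_dims = NULL) {
  known <- c("H", "HN", "HA", "N", "C", "CA", "CB", "CG", "CD", "CO", "CX")
  if (length(dimensions) < 1) {
    stop("a spectrum description needs at least one dimension", call. = FALSE)
  }
  dims <- purrr::map(dimensions, function(d) {
    if (is.null(d$classes) || is.null(d$position)) {
      stop("each dimension needs 'classes' and 'position'", call. = FALSE)
    }
    cl <- toupper(as.character(unlist(d$classes)))
    bad <- setdiff(cl, known)
    if (length(bad) > 0) {
      stop("unknown resonance class token(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    pos <- as.integer(d$position)
    if (length(pos) != 1L || is.na(pos) || abs(pos) > 4L) {
      stop("relative position must be a small integer", call. = FALSE)
    }
    list(classes = cl, position = pos,
         label = if (!is.null(d$label)) as.character(d$label)
                 else paste(cl, collapse = "/"))
  })
  if (is.null(comparable_dims)) {
    comparable_dims <- which(vapply(dims, function(d) length(d$classes) == 1L,
                                    logical(1)))
    if (length(comparable_dims) == 0L) comparable_dims <- seq_along(dims)
  }
  comparable_dims <- as.integer(comparable_dims)
  if (any(comparable_dims < 1L | comparable_dims > length(dims)) ||
      anyDuplicated(comparable_dims) || length(comparable_dims) == 0L) {
    stop("invalid comparable_dims for this spectrum description", call. = FALSE)
  }
  structure(list(name = name, dimensions = dims,
                 comparable_dims = comparable_dims),
            class = "spectrum_description")
}

#' @export
print.spectrum_description <- function(x, ...) {
  cat(sprintf("Spectrum description: %s (%d dimensions)\n",
              x$name, length(x$dimensions)))
  for (i in seq_along(x$dimensions)) {
    d <- x$dimensions[[i]]
    cat(sprintf("  dim %d: %s at position %+d%s\n", i,
                paste(d$classes, collapse = "|"), d$position,
                if (i %in% x$comparable_dims) "  [comparable]" else ""))
  }
  invisible(x)
}

#' Load a spectrum description from a JSON configuration file
#'
#' Reads a declarative spectrum configuration of the form
#' `{"name": ..., "dimensions": [{"classes": [...], "position": ...}, ...],
#' "comparable_dims": [...]}`. Bundled configurations for HN(CO)CACB, NCACX
#' and NCOCX live under `system.file("extdata", package = "spinsys")`.
#'
#' @param path Path to the JSON config.
#' @return A [spectrum_description()].
#' @examples
#' cfg <- system.file("extdata", "hncocacb.json", package = "spinsys")
#' load_spectrum_description(cfg)
#' @export
load_spectrum_description <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$dimensions)) {
    stop(path, ": spectrum description missing 'dimensions'", call. = FALSE)
  }
  spectrum_description(
    name = if (!is.null(obj$name)) obj$name else "unnamed",
    dimensions = obj$dimensions,
    comparable_dims = if (!is.null(obj$comparable_dims))
      as.integer(unlist(obj$comparable_dims)) else NULL)
}

expand_classes <- function(classes) {
  out <- unlist(lapply(classes, function(cl) {
    if (cl == "CX") c("CA", "CB", "CO") else cl
  }))
  unique(out)
}
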