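#' EPR spectrum container
#'
#' A first-derivative EPR spectrum: a strictly increasing magnetic-field axis
#' (mT), the first-derivative intensity (arbitrary units) and acquisition
#' metadata. This is the object every simulator returns and every extractor
#' consumes.
#'
#' @param field Numeric vector of magnetic-field values in mT, strictly
#'   increasing and (for feature extraction) uniformly spaced.
#' @param intensity Numeric vector of first-derivative intensities, same
#'   length as `field`.
#' @param metadata Named list of acquisition metadata. Recognised keys:
#'   `spin_label` ("5-SASL" or "16-SASL"), `measurement_temperature_C`,
#'   `genotype`, `growth_temperature_C`, `replicate_id`. Other keys are kept
#'   as-is.
#' @return An object of class `epr_spectrum`: a list with elements `field`,
#'   `intensity`, `metadata`.
#' @examples
#' grid <- field_grid(329, 341, 512)
#' sp <- epr_spectrum(grid$field, sin(grid$field), list(spin_label = "16-SASL"))
#' @export
epr_spectrum <- function(field, intensity, metadata = list()) {
  field <- as.numeric(field)
  intensity <- as.numeric(intensity)
  if (length(field) != length(intensity)) {
    stop("`field` and `intensity` must have equal length")
  }
  if (length(field) < 2L || any(diff(field) <= 0)) {
    stop("`field` must be strictly increasing with at least two points")
  }
  if (anyNA(field) || anyNA(intensity)) stop("NA values are not allowed")
  stopifnot(is.list(metadata))
  structure(list(field = field, intensity = intensity, metadata = metadata),
            class = "epr_spectrum")
}

#' @export
print.epr_spectrum <- function(x, ...) {
  md <- x$metadata
  lbl <- if (!is.null(md$spin_label)) md$spin_label else "unlabelled"
  cat(sprintf("<epr_spectrum> %s, %d points, %.3f-%.3f mT\n",
              lbl, length(x$field), min(x$field), max(x$field)))
  if (!is.null(md$measurement_temperature_C)) {
    cat(sprintf("  measured at %g degC", md$measurement_temperature_C))
    if (!is.null(md$genotype)) cat(sprintf(", genotype %s", md$genotype))
    if (!is.null(md$growth_temperature_C)) {
      cat(sprintf(", grown at %g degC", md$growth_temperature_C))
    }
    cat("\n")
  }
  invisible(x)
}

#' Uniform magnetic-field grid
#'
#' @param start,stop Field window in mT (`start < stop`).
#' @param n_points Number of samples (>= 64).
#' @return A list with `field` (the grid), `start`, `stop`, `n_points`,
#'   `step` (grid spacing, mT).
#' @examples
#' g <- field_grid(329, 341, 1024)
#' g$step
#' @export
field_grid <- function(start = 329, stop = 341, n_points = 2048L) {
  if (!(is.numeric(start) && is.numeric(stop) && start < stop)) {
    stop("`start` must be < `stop`")
  }
  n_points <- as.integer(n_points)
  if (n_points < 64L) stop("`n_points` must be >= 64")
  field <- seq(start, stop, length.out = n_points)
  list(field = field, start = start, stop = stop, n_points = n_points,
       step = field[2L] - field[1L])
}

is_uniform_grid <- function(field, rtol = 1e-6) {
  d <- diff(field)
  max(abs(d - d[1L])) <= rtol * abs(d[1L])
}

# Evaluate `code` under a locally fixed RNG state; the caller's stream is
# untouched. seed = NULL means "use the ambient stream".
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Write a spectrum to a plain-text file
#'
#' Two whitespace-separated columns (`field_mT`, `intensity`) preceded by a
#' `#`-prefixed metadata header (`# key: value` lines). Values are written at
#' full double precision, so [read_spectrum()] round-trips exactly.
#'
#' @param spectrum An [epr_spectrum()].
#' @param path Output file path.
#' @param json_sidecar If `TRUE`, also write the metadata to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, json_sidecar = FALSE) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  md <- spectrum$metadata
  hdr <- character(0)
  if (length(md)) {
    hdr <- sprintf("# %s: %s", names(md),
                   vapply(md, function(v) paste(format(v, digits = 17),
                                                collapse = ","), ""))
  }
  body <- sprintf("%.17g %.17g", spectrum$field, spectrum$intensity)
  writeLines(c(hdr, "# field_mT intensity", body), path)
  if (json_sidecar) {
    jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path File path.
#' @return An [epr_spectrum()]. Numeric-looking metadata values are converted
#'   back to numbers.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  md <- list()
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) {
      key <- trimws(m[2L])
      val <- trimws(m[3L])
      num <- suppressWarnings(as.numeric(val))
      md[[key]] <- if (!is.na(num)) num else val
    }
  }
  dat <- utils::read.table(text = lines[!is_hdr], col.names = c("field", "intensity"))
  epr_spectrum(dat$field, dat$intensity, metadata = md)
}
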