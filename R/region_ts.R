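#' Region-by-time signal container
#'
#' A `region_ts` holds a frames x regions matrix of signal values sampled at a
#' fixed interval, the canonical container for parcellated BOLD runs or
#' band-limited power time courses.
#'
#' @param data Numeric matrix, frames in rows, regions in columns.
#' @param dt Sampling interval in seconds per frame (e.g. 0.72 for HCP rfMRI).
#' @param region_ids Optional character vector of region labels; defaults to
#'   the matrix column names or `"r1" ... "rn"`.
#'
#' @return An object of class `region_ts` with elements `data`, `dt`,
#'   `region_ids`.
#' @export
region_ts <- function(data, dt, region_ids = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("'data' must be a numeric matrix")
  if (nrow(data) < 2L) stop("'data' must have at least 2 frames (rows)")
  if (!all(is.finite(data))) stop("'data' must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number (seconds per frame)")
  if (is.null(region_ids)) {
    region_ids <- colnames(data)
    if (is.null(region_ids)) region_ids <- paste0("r", seq_len(ncol(data)))
  }
  if (length(region_ids) != ncol(data))
    stop("'region_ids' length must match the number of regions")
  colnames(data) <- region_ids
  structure(list(data = data, dt = dt, region_ids = as.character(region_ids)),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("region_ts: %d frames x %d regions, dt = %g s (%.1f s total)\n",
              nrow(x$data), ncol(x$data), x$dt, nrow(x$data) * x$dt))
  invisible(x)
}

#' @export
dim.region_ts <- function(x) dim(x$data)

n_frames <- function(ts) nrow(ts$data)
n_regions <- function(ts) ncol(ts$data)

as_region_ts <- function(x, template) {
  region_ts(x, dt = template$dt, region_ids = template$region_ids)
}

#' Amplitude map container
#'
#' Per-region scalar summary of fluctuation amplitude (SD, ALFF or fALFF),
#' optionally z-normalized across regions.
#'
#' @param values Named (or unnamed) numeric vector, one value per region.
#' @param kind One of `"sd"`, `"alff"`, `"falff"`.
#' @param band Two-element numeric, the frequency band in Hz, or `NULL`.
#' @param znorm Logical; `TRUE` once the map has been z-normalized.
#' @return An object of class `amp_map`.
#' @export
amp_map <- function(values, kind = c("sd", "alff", "falff"), band = NULL,
                    znorm = FALSE) {
  kind <- match.arg(kind)
  values <- as.numeric_named(values)
  structure(list(values = values, kind = kind, band = band, znorm = znorm),
            class = "amp_map")
}

as.numeric_named <- function(x) {
  nm <- names(x)
  x <- as.numeric(x)
  names(x) <- nm
  x
}

#' @export
print.amp_map <- function(x, ...) {
  cat(sprintf("amp_map (%s%s): %d regions, range [%.3g, %.3g]\n",
              x$kind, if (x$znorm) ", z-normalized" else "",
              length(x$values), min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

# Extract plain numeric values from an amp_map or pass a numeric through.
map_values <- function(x) {
  if (inherits(x, "amp_map")) x$values
  else if (inherits(x, "gradient_map")) x$loadings[, 1L]
  else as.numeric_named(x)
}
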