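# Interchange formats: TSV matrices with JSON sidecars. Frame indices in
# on-disk artifacts are 0-based half-open (the format convention); the R
# API is 1-based, and this layer converts.

#' Write a region time series as TSV + JSON sidecar
#'
#' Frames as rows, header of region ids; the sidecar (`<path>.json`) holds
#' `dt` and any extra provenance fields.
#'
#' @param ts A [region_ts()].
#' @param path Output TSV path.
#' @param meta Named list of extra sidecar fields (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
write_region_ts <- function(ts, path, meta = list()) {
  stopifnot(inherits(ts, "region_ts"))
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  side <- c(list(dt = ts$dt, n_frames = n_frames(ts),
                 n_regions = n_regions(ts)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a region time series written by [write_region_ts()]
#'
#' @param path TSV path; `dt` is taken from the JSON sidecar unless given.
#' @param dt Optional sampling interval override.
#' @return A [region_ts()].
#' @export
read_region_ts <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != length(header)))
    stop("ragged TSV: line ", which(widths != length(header))[1L] + 1L,
         " has ", widths[widths != length(header)][1L], " fields, expected ",
         length(header))
  x <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              nrow = length(rows), byrow = TRUE)
  if (anyNA(x)) {
    bad <- which(apply(is.na(x), 1L, any))[1L]
    stop("non-numeric cell at line ", bad + 1L)
  }
  if (is.null(dt)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("no sidecar ", side, " and no 'dt' supplied")
    dt <- jsonlite::read_json(side)$dt
  }
  region_ts(x, dt = dt, region_ids = header)
}

#' Write a per-region map as two-column TSV
#'
#' @param values Named numeric vector, [amp_map()] or `gradient_map`
#'   component.
#' @param path Output TSV path.
#' @param meta Optional JSON sidecar fields.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, path, meta = list()) {
  v <- map_values(values)
  ids <- names(v)
  if (is.null(ids)) ids <- paste0("r", seq_along(v))
  utils::write.table(data.frame(region_id = ids, value = v), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a two-column region map TSV
#'
#' @param path TSV with columns `region_id`, `value`.
#' @return Named numeric vector.
#' @export
read_map <- function(path) {
  d <- utils::read.delim(path)
  stats::setNames(as.numeric(d$value), d$region_id)
}

#' Write detected events (0-based on disk)
#'
#' @param events A `qpp_events`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(data.frame(onset = events$onsets - 1L, r = events$r),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read events written by [write_events()]
#'
#' @param path TSV path.
#' @param threshold Threshold annotation to carry.
#' @return A `qpp_events` (onsets converted back to 1-based).
#' @export
read_events <- function(path, threshold = NA_real_) {
  d <- utils::read.delim(path)
  structure(list(onsets = as.integer(d$onset) + 1L, r = as.numeric(d$r),
                 threshold = threshold),
            class = "qpp_events")
}

#' Run the simulation-to-trajectory pipeline from a config
#'
#' Thin orchestration over the package stages: simulate a run (or read
#' one), compute the windowed hierarchical-index trajectory against the
#' planted or supplied gradient, and optionally write outputs with a JSON
#' provenance block (version, seed, parameters).
#'
#' @param config Named list: `seed`, `n_regions`, `n_frames`, `dt`,
#'   `beta`, `window_len`, optional `ts_file` (read instead of simulate),
#'   optional `gradient_file`, optional `out_dir`.
#' @return List: `ts`, `gradient`, `trajectory`, `trend`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(seed = 1L, n_regions = 200L,
                                n_frames = 1200L, dt = 0.72, beta = 1,
                                window_len = 50L), config)
  if (!is.null(cfg$ts_file)) {
    ts <- read_region_ts(cfg$ts_file)
    if (is.null(cfg$gradient_file))
      stop("pipeline stage 'hindex' needs a gradient: supply 'gradient_file' with 'ts_file'")
    gradient <- read_map(cfg$gradient_file)
  } else {
    spec <- synth_spec(n_regions = cfg$n_regions, n_frames = cfg$n_frames,
                       dt = cfg$dt, beta = cfg$beta, seed = cfg$seed)
    sim <- simulate_rest(spec)
    ts <- sim$ts
    gradient <- sim$truth$gradient
  }
  traj <- hier_trajectory(ts, gradient, window_len = cfg$window_len)
  trend <- trend_test(traj)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- list(package = "hierdyn",
                 version = as.character(utils::packageVersion("hierdyn")),
                 seed = cfg$seed, config = cfg[order(names(cfg))])
    tf <- file.path(cfg$out_dir, "trajectory.tsv")
    utils::write.table(data.frame(window = seq_along(traj$rho) - 1L,
                                  rho = traj$rho),
                       tf, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ts = ts, gradient = gradient, trajectory = traj, trend = trend,
       config = cfg)
}
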