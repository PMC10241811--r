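# The hierarchical index: rank correlation between a spatial fluctuation
# amplitude map and the principal connectome gradient, plus its windowed
# dynamics and the state-contrast map constructions.

# Spearman rho with average-rank ties; NA if either side is constant.
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(rank(x), rank(y))
}

#' Hierarchical index of an amplitude map
#'
#' Spearman rank correlation between a spatial amplitude map and the
#' gradient: positive values mean fluctuations concentrate in high-gradient
#' (transmodal) cortex, the signature of vivid wakefulness. Invariant to
#' monotone transforms of either map, so prior z-normalization does not
#' change it.
#'
#' @param amp An [amp_map()] or numeric vector per region.
#' @param gradient A `gradient_map` (component 1 used) or numeric vector.
#' @return Spearman rho in `[-1, 1]`; `NA` (with a warning) if either map is
#'   constant.
#' @export
hier_index <- function(amp, gradient) {
  a <- map_values(amp)
  g <- map_values(gradient)
  if (length(a) != length(g)) stop("amplitude map and gradient differ in regions")
  if (length(a) < 4L) stop("need at least 4 regions")
  r <- spearman(a, g)
  if (is.na(r)) warning("hierarchical index undefined (constant map)")
  r
}

#' Windowed hierarchical-index trajectory
#'
#' The run is bandpass-filtered once (unless `filter = FALSE`, e.g. for
#' already-filtered input), divided into nonoverlapping windows, and each
#' window's per-region SD map is z-normalized and rank-correlated with the
#' gradient. 1200 frames with 50-frame windows give a 24-point trajectory.
#'
#' @param ts A [region_ts()].
#' @param gradient Gradient map or numeric vector.
#' @param window_len Frames per window (>= 10), default 50.
#' @param stride Step between windows, default `window_len`.
#' @param filter Apply the 0.01-0.08 Hz zero-phase bandpass first?
#' @param band Filter band used when `filter = TRUE`.
#' @return Object of class `hier_traj`: `rho` (per window), `windows`
#'   (the [make_windows()] scheme), `window_len`.
#' @export
hier_trajectory <- function(ts, gradient, window_len = 50L,
                            stride = window_len, filter = TRUE,
                            band = c(0.01, 0.08)) {
  stopifnot(inherits(ts, "region_ts"))
  if (window_len < 10L) stop("'window_len' must be at least 10 frames")
  g <- map_values(gradient)
  if (length(g) != n_regions(ts)) stop("gradient does not match regions")
  fts <- if (filter) bandpass(ts, band[1], band[2]) else ts
  ws <- make_windows(n_frames(fts), window_len, stride)
  rho <- vapply(seq_along(ws$starts), function(w) {
    seg <- fts$data[window_frames(ws, w), , drop = FALSE]
    spearman(apply(seg, 2L, stats::sd), g)
  }, numeric(1))
  structure(list(rho = rho, windows = ws, window_len = as.integer(window_len)),
            class = "hier_traj")
}

#' @export
print.hier_traj <- function(x, ...) {
  cat(sprintf("hier_traj: %d windows of %d frames; rho range [%.3f, %.3f]\n",
              length(x$rho), x$window_len, min(x$rho, na.rm = TRUE),
              max(x$rho, na.rm = TRUE)))
  invisible(x)
}

#' Pearson trend test on a hierarchical-index trajectory
#'
#' Correlates the per-window index against window order; the two-sided p
#' comes from the t transform `t = r * sqrt((n-2)/(1-r^2))`.
#'
#' @param traj A `hier_traj` or numeric vector of per-window values.
#' @return List with `r`, `p`, `n`. Degenerate (constant) trajectories give
#'   `r = NA` with a warning.
#' @export
trend_test <- function(traj) {
  v <- if (inherits(traj, "hier_traj")) traj$rho else as.numeric(traj)
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 5L) stop("trend test needs at least 5 windows")
  if (stats::sd(v) == 0) {
    warning("trend undefined on a constant trajectory")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(seq_len(n), v)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Paired-t contrast map between two conditions
#'
#' Per-region paired t statistic (A - B) across subjects, e.g. wakefulness
#' versus sedation maps. Rows are subjects (paired), columns regions.
#'
#' @param maps_a,maps_b Subject x region matrices of (z-normalized)
#'   amplitude values, identically ordered subjects and regions.
#' @return List of class `state_map`: `stat` per region, `kind = "paired_t"`,
#'   `n`. Regions with zero difference variance but nonzero mean difference
#'   are `+/-Inf`, flagged by a warning.
#' @export
paired_t_map <- function(maps_a, maps_b) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (!identical(dim(maps_a), dim(maps_b)))
    stop("condition matrices must be subject x region with matching shapes")
  n <- nrow(maps_a)
  if (n < 3L) stop("need at least 3 subject pairs")
  d <- maps_a - maps_b
  md <- colMeans(d)
  sdd <- apply(d, 2L, stats::sd)
  tstat <- md / (sdd / sqrt(n))
  if (any(sdd == 0 & md != 0))
    warning("degenerate regions with zero paired variance: t is infinite there")
  tstat[sdd == 0 & md == 0] <- 0
  structure(list(stat = tstat, kind = "paired_t", n = n), class = "state_map")
}

#' Per-region correlation map against a state variable
#'
#' Spearman correlation, per region, between its amplitude across
#' windows/observations and a state code (sleep stage levels 0/-1/-2/-3,
#' window time intervals, ...).
#'
#' @param window_maps Observation x region matrix of amplitude values.
#' @param state_values Numeric state code per observation.
#' @return A `state_map` with `kind = "spearman"`. Constant regions give
#'   `NA` (flagged), a constant state vector is an error.
#' @export
state_corr_map <- function(window_maps, state_values) {
  window_maps <- as.matrix(window_maps)
  if (nrow(window_maps) != length(state_values))
    stop("state vector length must equal the number of observations (rows)")
  if (nrow(window_maps) < 5L) stop("need at least 5 observations")
  if (stats::sd(state_values) == 0) stop("state vector is constant")
  rho <- apply(window_maps, 2L, spearman, y = state_values)
  if (anyNA(rho)) warning("constant regions flagged NA in the correlation map")
  structure(list(stat = rho, kind = "spearman", n = nrow(window_maps)),
            class = "state_map")
}

#' @export
print.state_map <- function(x, ...) {
  cat(sprintf("state_map (%s, n = %d): %d regions\n", x$kind, x$n,
              length(x$stat)))
  invisible(x)
}

#' All unordered window pairs with their time interval
#'
#' 24 windows give 276 pairs with intervals 1..23; paired amplitude
#' differences against interval form the vigilance-drift map.
#'
#' @param n_windows Number of windows (>= 2).
#' @return data.frame with columns `i`, `j` (1-based, `i < j`) and
#'   `interval = j - i`.
#' @export
window_pairs <- function(n_windows) {
  if (n_windows < 2L) stop("need at least 2 windows")
  idx <- utils::combn(n_windows, 2L)
  data.frame(i = idx[1L, ], j = idx[2L, ], interval = idx[2L, ] - idx[1L, ])
}

#' Interval-correlation map from windowed amplitude maps
#'
#' Pools all pairwise window amplitude differences (later minus earlier)
#' against the pair's time interval, per region, with equal pair weights:
#' the within-run construction behind the vigilance-drift topography.
#'
#' @param window_maps Window x region matrix of z-normalized amplitudes.
#' @return A `state_map` (`kind = "spearman"`) over pooled pairs.
#' @export
interval_corr_map <- function(window_maps) {
  window_maps <- as.matrix(window_maps)
  wp <- window_pairs(nrow(window_maps))
  dmaps <- window_maps[wp$j, , drop = FALSE] - window_maps[wp$i, , drop = FALSE]
  state_corr_map(dmaps, wp$interval)
}
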