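# Quasiperiodic-pattern (QPP) analysis: sliding spatiotemporal template
# matching, event detection, recursive template building, and event-level
# summaries. The primary QPP is an infra-slow (~20 s) wave propagating
# along the connectome gradient.

#' QPP template container
#'
#' @param data region x L numeric matrix (L frames).
#' @param dt Seconds per frame.
#' @param threshold Match threshold the template was built with (or NA).
#' @param iterations Iterations the build took (or NA).
#' @return Object of class `qpp_template`.
#' @export
qpp_template <- function(data, dt, threshold = NA_real_,
                         iterations = NA_integer_) {
  data <- as.matrix(data)
  if (ncol(data) < 5L) stop("template must span at least 5 frames")
  if (!all(is.finite(data))) stop("template must be finite")
  structure(list(data = data, dt = dt, threshold = threshold,
                 iterations = iterations),
            class = "qpp_template")
}

#' @export
print.qpp_template <- function(x, ...) {
  cat(sprintf("qpp_template: %d regions x %d frames (%.1f s at dt = %g s)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) * x$dt, x$dt))
  invisible(x)
}

#' Sliding spatiotemporal template match
#'
#' For each start lag, the Pearson correlation between the flattened
#' region x L segment and the flattened template (step of one frame, no
#' wrap-around). Invariant to common affine rescaling of the series.
#'
#' @param ts A [region_ts()] with the template's regions.
#' @param template A [qpp_template()] or region x L matrix.
#' @return Numeric correlation series of length `T - L + 1`.
#' @export
sliding_match <- function(ts, template) {
  tpl <- if (inherits(template, "qpp_template")) template$data else as.matrix(template)
  X <- ts$data                             # T x n
  n <- ncol(X); T <- nrow(X); L <- ncol(tpl)
  if (nrow(tpl) != n) stop("template regions do not match the time series")
  if (T < L) stop("time series shorter than the template")
  nl <- n * L
  tv <- as.numeric(tpl)
  tsum <- sum(tv); tss <- sum(tv^2) - tsum^2 / nl
  FD <- X %*% tpl                          # FD[t, l] = sum_i X[t,i] tpl[i,l]
  nlag <- T - L + 1L
  dot <- numeric(nlag)
  for (l in seq_len(L)) dot <- dot + FD[seq_len(nlag) + l - 1L, l]
  fs <- rowSums(X); fss <- rowSums(X^2)
  cs <- c(0, cumsum(fs)); css <- c(0, cumsum(fss))
  segsum <- cs[seq_len(nlag) + L] - cs[seq_len(nlag)]
  segss <- css[seq_len(nlag) + L] - css[seq_len(nlag)] - segsum^2 / nl
  num <- dot - segsum * tsum / nl
  den <- sqrt(pmax(segss, 0) * tss)
  r <- ifelse(den > 0, num / den, NA_real_)
  pmin(1, pmax(-1, r))
}

#' Detect QPP events from a match-correlation series
#'
#' Events are local maxima (strictly greater than both neighbours; a
#' plateau takes its leftmost frame) with correlation at or above the
#' threshold; of any two maxima closer than `min_sep` frames, the higher
#' survives.
#'
#' @param corr_series Per-lag correlation series (e.g. [sliding_match()]).
#' @param threshold Minimum match correlation, default 0.4.
#' @param min_sep Minimum onset separation in frames (typically the
#'   template length L).
#' @return Object of class `qpp_events`: `onsets` (1-based lags, strictly
#'   increasing), `r` (match at each onset), `threshold`.
#' @export
detect_events <- function(corr_series, threshold = 0.4, min_sep = 1L) {
  v <- as.numeric(corr_series)
  v[!is.finite(v)] <- -Inf
  # run-length encode so plateaus resolve to their leftmost frame
  rl <- rle(v)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  nr <- length(rl$values)
  prev <- c(-Inf, rl$values[-nr])
  nxt <- c(rl$values[-1L], -Inf)
  is_max <- rl$values > prev & rl$values > nxt & rl$values >= threshold
  cand <- starts[is_max]
  cr <- rl$values[is_max]
  # greedy suppression: keep the strongest, drop neighbours within min_sep
  keep <- logical(length(cand))
  for (i in order(cr, decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < min_sep)) keep[i] <- TRUE
  }
  o <- order(cand[keep])
  structure(list(onsets = cand[keep][o], r = cr[keep][o],
                 threshold = threshold),
            class = "qpp_events")
}

#' @export
print.qpp_events <- function(x, ...) {
  cat(sprintf("qpp_events: %d events at threshold r >= %.2f\n",
              length(x$onsets), x$threshold))
  invisible(x)
}

#' Build a QPP template by recursive matching and averaging
#'
#' From each of `n_seeds` random starting segments: correlate the current
#' template against all lags, average the segments at super-threshold local
#' maxima into a new template, and iterate until the event set repeats or
#' `max_iter` is reached. Among converged candidates the one whose final
#' events carry the highest summed correlation wins.
#'
#' @param ts A [region_ts()] with at least `3 * L` frames.
#' @param L Template length in frames (30 at dt = 0.72 s spans ~21.6 s).
#' @param threshold Match threshold while building, default 0.4.
#' @param max_iter Iteration cap per seed, default 20.
#' @param n_seeds Random starting segments, default 20.
#' @param seed RNG seed.
#' @return A [qpp_template()]; errors if no seed yields super-threshold
#'   events.
#' @export
build_template <- function(ts, L, threshold = 0.4, max_iter = 20L,
                           n_seeds = 20L, seed = 1L) {
  X <- ts$data
  T <- nrow(X)
  if (T < 3L * L) stop("need at least 3 * L frames to build a template")
  set.seed(seed)
  starts <- sample.int(T - L + 1L, min(n_seeds, T - L + 1L))
  best <- NULL; best_score <- -Inf
  for (s in starts) {
    tpl <- t(X[s:(s + L - 1L), , drop = FALSE])
    prev_onsets <- integer(0)
    iters <- 0L
    events <- NULL
    repeat {
      iters <- iters + 1L
      cs <- sliding_match(ts, tpl)
      events <- detect_events(cs, threshold, min_sep = L)
      if (!length(events$onsets)) { events <- NULL; break }
      if (identical(events$onsets, prev_onsets) || iters >= max_iter) break
      prev_onsets <- events$onsets
      segs <- lapply(events$onsets, function(o) t(X[o:(o + L - 1L), , drop = FALSE]))
      tpl <- Reduce(`+`, segs) / length(segs)
    }
    if (is.null(events)) next
    score <- sum(events$r)
    if (score > best_score) {
      best_score <- score
      best <- qpp_template(tpl, ts$dt, threshold, iters)
    }
  }
  if (is.null(best))
    stop(sprintf("no super-threshold (r >= %g) events from any of %d seeds",
                 threshold, length(starts)))
  best
}

#' Phase-align one template to another
#'
#' Finds the circular time shift of `template_b` within
#' `[-max_shift, max_shift]` maximizing the flattened Pearson correlation
#' with `template_a`; ties prefer the smallest `|shift|`, then the negative
#' one.
#'
#' @param template_a,template_b Templates (or region x L matrices) of equal
#'   shape.
#' @param max_shift Largest shift magnitude in frames.
#' @return List: `shift` (frames `template_b` was rolled by), `aligned_b`
#'   (shifted matrix), `r` (achieved correlation).
#' @export
phase_align <- function(template_a, template_b, max_shift = 5L) {
  A <- if (inherits(template_a, "qpp_template")) template_a$data else as.matrix(template_a)
  B <- if (inherits(template_b, "qpp_template")) template_b$data else as.matrix(template_b)
  if (!identical(dim(A), dim(B))) stop("templates must have the same shape")
  L <- ncol(A)
  shifts <- (-max_shift):max_shift
  shifts <- shifts[order(abs(shifts), shifts)]   # 0, -1, 1, -2, 2, ...
  best <- list(shift = 0L, r = -Inf, aligned_b = B)
  for (s in shifts) {
    idx <- ((seq_len(L) - 1L - s) %% L) + 1L     # roll columns by s
    Bs <- B[, idx, drop = FALSE]
    r <- stats::cor(as.numeric(A), as.numeric(Bs))
    if (r > best$r) best <- list(shift = s, r = r, aligned_b = Bs)
  }
  best
}

#' Project a single frame onto the gradient
#'
#' Dot product of per-region values with the gradient loadings; the
#' trajectory of this projection across a QPP cycle traces the wave's
#' position along the hierarchy.
#'
#' @param frame_values Numeric vector per region.
#' @param gradient Gradient map or numeric vector.
#' @return Scalar projection.
#' @export
gradient_projection <- function(frame_values, gradient) {
  g <- map_values(gradient)
  if (length(frame_values) != length(g)) stop("region mismatch")
  sum(frame_values * g)
}

#' Low- and high-hierarchy traces of QPP events
#'
#' For each event, the mean time course over the bottom and the top
#' `frac` gradient-ranked regions across the event's L frames. In a
#' gradient-ordered propagating wave the high trace lags the low trace.
#'
#' @param ts A [region_ts()].
#' @param events A `qpp_events` (or integer onsets).
#' @param gradient Gradient map or numeric vector.
#' @param L Event length in frames.
#' @param frac Fraction of regions per extreme, default 0.2.
#' @return List of per-event lists with `low` and `high` traces (length L).
#' @export
event_traces <- function(ts, events, gradient, L, frac = 0.2) {
  onsets <- if (inherits(events, "qpp_events")) events$onsets else as.integer(events)
  g <- map_values(gradient)
  n <- length(g)
  k <- floor(frac * n)
  if (k < 1L) stop("frac * n_regions must be at least 1")
  ord <- order(g)
  lo <- ord[seq_len(k)]
  hi <- ord[seq.int(n - k + 1L, n)]
  if (any(onsets < 1L | onsets + L - 1L > n_frames(ts)))
    stop("event onsets out of bounds")
  lapply(onsets, function(o) {
    seg <- ts$data[o:(o + L - 1L), , drop = FALSE]
    list(low = rowMeans(seg[, lo, drop = FALSE]),
         high = rowMeans(seg[, hi, drop = FALSE]))
  })
}

#' Classify an event trajectory as typical or atypical
#'
#' An event's high-hierarchy trace is typical when its Pearson correlation
#' with the template's high-hierarchy trace reaches the threshold
#' (`r >= r_thresh`, boundary inclusive); the bifurcation of high-order
#' trajectories distinguishes vigilance states.
#'
#' @param event_trace,template_trace Equal-length numeric traces.
#' @param r_thresh Threshold, default 0.5.
#' @return `"typical"` or `"atypical"`; a constant trace is atypical with a
#'   warning.
#' @export
classify_trajectory <- function(event_trace, template_trace, r_thresh = 0.5) {
  if (length(event_trace) != length(template_trace))
    stop("traces must have equal length")
  if (stats::sd(event_trace) == 0 || stats::sd(template_trace) == 0) {
    warning("constant trace: classified atypical")
    return("atypical")
  }
  if (stats::cor(event_trace, template_trace) >= r_thresh) "typical" else "atypical"
}

#' Network-level functional connectivity within QPP events
#'
#' Per event, region time courses over the event's L frames are averaged
#' within networks and correlated (Pearson) network-by-network; the
#' event-mean matrix summarizes within-event coupling.
#'
#' @param ts A [region_ts()].
#' @param events `qpp_events` or onsets.
#' @param network_labels Integer/factor network label per region (every
#'   network nonempty).
#' @param L Event length in frames.
#' @return List: `mean_fc` (network x network), `per_event` (array
#'   net x net x event).
#' @export
event_network_fc <- function(ts, events, network_labels, L) {
  onsets <- if (inherits(events, "qpp_events")) events$onsets else as.integer(events)
  f <- if (is.factor(network_labels)) network_labels else factor(network_labels)
  labs <- as.integer(f)
  nn <- nlevels(f)
  if (any(tabulate(labs, nn) == 0L)) stop("empty network in 'network_labels'")
  per <- vapply(onsets, function(o) {
    seg <- ts$data[o:(o + L - 1L), , drop = FALSE]
    netts <- vapply(seq_len(nn), function(k)
      rowMeans(seg[, labs == k, drop = FALSE]), numeric(L))
    stats::cor(netts)
  }, matrix(0, nn, nn))
  per <- array(per, dim = c(nn, nn, length(onsets)))
  list(mean_fc = apply(per, c(1, 2), mean), per_event = per)
}

#' Edgewise contrast of network FC between two event groups
#'
#' Two-sample two-sided t statistic per network edge across events of two
#' groups (e.g. high- versus low-vigilance segments).
#'
#' @param per_event_a,per_event_b net x net x event arrays from
#'   [event_network_fc()].
#' @return List: `t` (net x net), `p` (net x net, two-sided).
#' @export
network_fc_contrast <- function(per_event_a, per_event_b) {
  if (dim(per_event_a)[3] < 2L || dim(per_event_b)[3] < 2L)
    stop("need at least 2 events per group")
  nn <- dim(per_event_a)[1]
  tmat <- pmat <- matrix(NA_real_, nn, nn)
  for (i in seq_len(nn)) for (j in seq_len(nn)) {
    if (i == j) { tmat[i, j] <- 0; pmat[i, j] <- 1; next }
    tt <- stats::t.test(per_event_a[i, j, ], per_event_b[i, j, ])
    tmat[i, j] <- unname(tt$statistic)
    pmat[i, j] <- tt$p.value
  }
  list(t = tmat, p = pmat)
}
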