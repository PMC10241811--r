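# Electrophysiology path: multitaper spectrogram, dB normalization,
# band-limited power (BLP) time courses, and the gamma/delta event
# statistics. Gamma (40-100 Hz) BLP plays the role the BOLD signal plays
# in the fMRI path.

#' Channel recording container
#'
#' @param data channel x sample numeric matrix.
#' @param fs Sampling rate in Hz (>= 250 for the 1-100 Hz analysis).
#' @param channel_ids Optional channel labels.
#' @return Object of class `channel_rec`.
#' @export
channel_rec <- function(data, fs, channel_ids = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("'data' must be finite")
  if (fs < 250) stop("'fs' must be at least 250 Hz")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channel_ids
  structure(list(data = data, fs = fs, channel_ids = channel_ids),
            class = "channel_rec")
}

#' @export
print.channel_rec <- function(x, ...) {
  cat(sprintf("channel_rec: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First `k` DPSS tapers of length `n` at time-bandwidth product `nw`,
#' computed from the standard symmetric tridiagonal formulation; each taper
#' has unit energy.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product, default 3.
#' @param k Number of tapers, default `2 * nw - 1`.
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  stopifnot(n >= 2L, k >= 1L, k <= n)
  w <- nw / n
  t <- 0:(n - 1L)
  M <- matrix(0, n, n)
  diag(M) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1L] * (n - t[-1L]) / 2
  M[cbind(2:n, 1:(n - 1L))] <- off
  M[cbind(1:(n - 1L), 2:n)] <- off
  es <- eigen(M, symmetric = TRUE)
  tap <- es$vectors[, seq_len(k), drop = FALSE]
  # conventional polarity: even-order tapers integrate positive, odd-order
  # tapers start positive
  for (j in seq_len(k)) {
    s <- if (j %% 2L == 1L) sum(tap[, j]) else tap[2L, j] - tap[1L, j]
    if (s < 0) tap[, j] <- -tap[, j]
  }
  tap / rep(sqrt(colSums(tap^2)), each = n)
}

#' Multitaper spectrogram of a recording
#'
#' Sliding-window multitaper power estimate, averaged over tapers and
#' aggregated into 1 Hz bins over 1-100 Hz. Defaults follow the ECoG
#' analysis convention: 1 s windows, 0.2 s step, 5 tapers (NW = 3).
#'
#' @param rec A [channel_rec()] (fs >= 250 so 100 Hz is resolvable).
#' @param win_s Window length in seconds, default 1.
#' @param step_s Step between windows in seconds, default 0.2.
#' @param n_tapers Number of DPSS tapers, default 5.
#' @param nw Time-bandwidth product, default 3.
#' @param f_max Highest frequency bin (Hz), default 100.
#' @return Object of class `spectrogram`: `power` (channel x freq x time,
#'   nonnegative), `freqs` (1..f_max Hz), `times` (window centers, s),
#'   `step_s`, `normalized = FALSE`.
#' @export
multitaper_spectrogram <- function(rec, win_s = 1.0, step_s = 0.2,
                                   n_tapers = 5L, nw = 3, f_max = 100L) {
  stopifnot(inherits(rec, "channel_rec"))
  if (rec$fs < 2 * f_max) stop(sprintf("fs = %g Hz cannot resolve %d Hz", rec$fs, f_max))
  win <- round(win_s * rec$fs)
  step <- round(step_s * rec$fs)
  if (win < 2 * n_tapers) stop("window too short for the requested tapers")
  ns <- ncol(rec$data)
  if (ns < win) stop("recording shorter than one window")
  starts <- seq.int(1L, ns - win + 1L, by = step)
  nt <- length(starts)
  tap <- dpss_tapers(win, nw, n_tapers)
  fft_freq <- (0:(win - 1L)) / win_s
  bin <- round(fft_freq)
  keep <- bin >= 1L & bin <= f_max & fft_freq <= rec$fs / 2
  bin_id <- bin[keep]
  nch <- nrow(rec$data)
  power <- array(0, dim = c(nch, f_max, nt),
                 dimnames = list(rec$channel_ids, NULL, NULL))
  for (ch in seq_len(nch)) {
    segs <- vapply(starts, function(s) rec$data[ch, s:(s + win - 1L)],
                   numeric(win))                       # win x nt
    segs <- sweep(segs, 2L, colMeans(segs))            # demean per window
    pw <- matrix(0, win, nt)
    for (j in seq_len(n_tapers))
      pw <- pw + Mod(stats::mvfft(segs * tap[, j]))^2
    pw <- pw / n_tapers
    agg <- rowsum(pw[keep, , drop = FALSE], group = bin_id)
    cnt <- as.numeric(table(bin_id))
    power[ch, as.integer(rownames(agg)), ] <- as.matrix(agg / cnt)
  }
  structure(list(power = power, freqs = seq_len(f_max),
                 times = (starts - 1L + win / 2) / rec$fs,
                 step_s = step_s, normalized = FALSE),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram%s: %d channels x %d freqs (1-%d Hz) x %d frames (step %g s)\n",
              if (x$normalized) " (normalized dB)" else "",
              dim(x$power)[1], dim(x$power)[2], max(x$freqs),
              dim(x$power)[3], x$step_s))
  invisible(x)
}

#' Normalize a spectrogram (dB + temporal mean removal)
#'
#' Converts power to decibels, `10 * log10(power + floor)` with a floor of
#' 1e-12 of the maximum power guarding zeros, then removes the temporal
#' mean of every channel x frequency bin. The result is invariant to a
#' global gain on the raw recording, and each bin's temporal mean is 0.
#'
#' @param spec A raw [multitaper_spectrogram()].
#' @return The spectrogram with `normalized = TRUE`.
#' @export
normalize_spectrogram <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  if (spec$normalized) stop("spectrogram is already normalized")
  floor_p <- 1e-12 * max(spec$power)
  db <- 10 * log10(spec$power + floor_p)
  mu <- apply(db, c(1, 2), mean)
  spec$power <- db - as.vector(mu)      # recycles over the time dimension
  spec$normalized <- TRUE
  spec
}

# Named band definitions, inclusive integer-Hz bins.
blp_bands <- list(delta = 1:4, alphabeta = 5:30, gamma = 40:100)

#' Band-limited power time courses
#'
#' Mean of the normalized spectrogram over a band's inclusive frequency
#' bins, per channel and frame. Bands: `delta` 1-4 Hz, `alphabeta` 5-30 Hz,
#' `gamma` 40-100 Hz.
#'
#' @param spec A normalized [normalize_spectrogram()] spectrogram.
#' @param band Band name or an integer vector of Hz bins.
#' @return Object of class `blp_series`: `data` (channel x frame), `band`,
#'   `step_s`, `times`, `filtered = FALSE`.
#' @export
band_power <- function(spec, band = "gamma") {
  stopifnot(inherits(spec, "spectrogram"))
  if (!spec$normalized) stop("normalize the spectrogram before band averaging")
  bins <- if (is.character(band)) {
    if (!band %in% names(blp_bands)) stop("unknown band: ", band)
    blp_bands[[band]]
  } else as.integer(band)
  if (!all(bins %in% spec$freqs)) stop("band bins outside the spectrogram range")
  x <- apply(spec$power[, bins, , drop = FALSE], c(1, 3), mean)
  structure(list(data = x, band = if (is.character(band)) band else "custom",
                 step_s = spec$step_s, times = spec$times, filtered = FALSE),
            class = "blp_series")
}

#' @export
print.blp_series <- function(x, ...) {
  cat(sprintf("blp_series (%s%s): %d channels x %d frames (step %g s)\n",
              x$band, if (x$filtered) ", filtered" else "",
              nrow(x$data), ncol(x$data), x$step_s))
  invisible(x)
}

#' Bandpass-filter BLP time courses
#'
#' Zero-phase Butterworth 0.01-0.08 Hz filtering of the slow BLP signal,
#' matching the fMRI band so BLP maps are directly comparable.
#'
#' @param blp A [band_power()] series.
#' @param f_lo,f_hi Band in Hz.
#' @return Filtered `blp_series`.
#' @export
blp_filter <- function(blp, f_lo = 0.01, f_hi = 0.08) {
  stopifnot(inherits(blp, "blp_series"))
  fs <- 1 / blp$step_s
  if (ncol(blp$data) * blp$step_s < 2 / f_lo)
    stop("record too short to resolve the lower band edge")
  blp$data <- t(filtfilt_matrix(t(blp$data), f_lo, f_hi, fs))
  blp$filtered <- TRUE
  blp
}

#' Hierarchical-index trajectory from gamma BLP
#'
#' Segments the (filtered) BLP into nonoverlapping fragments (default 150 s,
#' i.e. 750 frames at the 0.2 s step), computes each fragment's per-channel
#' SD map, z-normalizes it, and rank-correlates with the channel gradient.
#'
#' @param blp A (typically filtered) `blp_series`.
#' @param gradient Per-channel gradient loadings.
#' @param window_s Fragment length in seconds, default 150.
#' @return A `hier_traj` over fragments.
#' @export
blp_hier_trajectory <- function(blp, gradient, window_s = 150) {
  stopifnot(inherits(blp, "blp_series"))
  wl <- round(window_s / blp$step_s)
  ts <- region_ts(t(blp$data), dt = blp$step_s,
                  region_ids = rownames(blp$data))
  hier_trajectory(ts, gradient, window_len = wl, filter = FALSE)
}

#' Gamma peak difference and subsequent delta power of an event
#'
#' Within the initial `head_s` of an event, the peak (max) of the mean
#' gamma BLP over the top-`frac` gradient channels minus the peak of the
#' bottom-`frac` mean (`mode = "diff_of_max"`, default) or the peak of the
#' instantaneous high-minus-low difference (`mode = "max_of_diff"`); plus
#' the mean delta BLP over all channels in the following `tail_s`.
#'
#' @param gamma_event channel x frame gamma BLP over the event.
#' @param delta_event channel x frame delta BLP over the same frames.
#' @param gradient Per-channel gradient loadings.
#' @param step_s Seconds per BLP frame.
#' @param frac Fraction of channels per extreme, default 0.2.
#' @param head_s Initial window for the gamma peaks, default 12 s.
#' @param tail_s Subsequent window for the delta average, default 4 s.
#' @param mode `"diff_of_max"` or `"max_of_diff"`.
#' @return List: `peak_diff`, `later_delta`.
#' @export
peak_difference <- function(gamma_event, delta_event, gradient, step_s,
                            frac = 0.2, head_s = 12, tail_s = 4,
                            mode = c("diff_of_max", "max_of_diff")) {
  mode <- match.arg(mode)
  gamma_event <- as.matrix(gamma_event); delta_event <- as.matrix(delta_event)
  nf <- ncol(gamma_event)
  head_n <- round(head_s / step_s)
  tail_n <- round(tail_s / step_s)
  if (nf < head_n + tail_n) stop("event shorter than head_s + tail_s")
  g <- map_values(gradient)
  n <- length(g)
  k <- max(1L, floor(frac * n))
  ord <- order(g)
  lo <- ord[seq_len(k)]; hi <- ord[seq.int(n - k + 1L, n)]
  hi_tr <- colMeans(gamma_event[hi, seq_len(head_n), drop = FALSE])
  lo_tr <- colMeans(gamma_event[lo, seq_len(head_n), drop = FALSE])
  pd <- switch(mode,
               diff_of_max = max(hi_tr) - max(lo_tr),
               max_of_diff = max(hi_tr - lo_tr))
  later <- mean(delta_event[, seq.int(head_n + 1L, head_n + tail_n), drop = FALSE])
  list(peak_diff = pd, later_delta = later)
}
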