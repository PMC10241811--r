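# Temporal filtering and per-region fluctuation-amplitude maps.
#
# The slow (0.01-0.08 Hz) band is the conventional resting-state fMRI band;
# variability is summarized either in the time domain (SD of the filtered
# signal) or in the frequency domain (ALFF), which agree in rank order by
# Parseval's theorem.

#' Zero-phase Butterworth bandpass filter
#'
#' Filters every region's time course with a Butterworth bandpass applied
#' forward and backward (zero phase). The default band 0.01-0.08 Hz is the
#' standard resting-state fMRI low-frequency band.
#'
#' @param ts A [region_ts()].
#' @param f_lo,f_hi Band edges in Hz; `f_hi` must be below Nyquist
#'   (`1/(2*dt)`).
#' @param order Filter order of the underlying lowpass prototype; the
#'   bandpass has twice this polynomial order and the forward-backward pass
#'   doubles the effective attenuation. Default 2 (a 4th-order bandpass).
#' @return A filtered `region_ts` of the same shape.
#' @export
bandpass <- function(ts, f_lo = 0.01, f_hi = 0.08, order = 2L) {
  stopifnot(inherits(ts, "region_ts"))
  nyq <- 1 / (2 * ts$dt)
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < nyq))
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < f_lo < f_hi < Nyquist (%g Hz)",
                 f_lo, f_hi, nyq))
  out <- filtfilt_matrix(ts$data, f_lo, f_hi, 1 / ts$dt, order)
  as_region_ts(out, ts)
}

# Column-wise zero-phase Butterworth bandpass on a plain matrix.
filtfilt_matrix <- function(x, f_lo, f_hi, fs, order = 2L) {
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  apply(x, 2L, function(col) signal::filtfilt(bf, col))
}

#' Per-region standard deviation map
#'
#' BOLD variability: the sample SD (denominator N-1) of each region's time
#' course. Applied to band-limited data this is the time-domain analog of
#' ALFF.
#'
#' @param ts A [region_ts()] (typically already bandpass-filtered).
#' @param band Optional band annotation carried into the result.
#' @return An [amp_map()] of kind `"sd"`.
#' @export
sd_map <- function(ts, band = NULL) {
  stopifnot(inherits(ts, "region_ts"))
  v <- apply(ts$data, 2L, stats::sd)
  amp_map(v, kind = "sd", band = band)
}

# Positive-frequency discrete Fourier amplitudes of a demeaned matrix.
# Returns list(freq, a, b): a,b are (nbin x regions), with the convention
# x(t) = sum_k a_k cos(2 pi f_k t) + b_k sin(2 pi f_k t),
# a_k = (2/N) sum x cos, b_k = (2/N) sum x sin, for 0 < f_k < Nyquist.
fourier_coeffs <- function(x, dt) {
  n <- nrow(x)
  x <- sweep(x, 2L, colMeans(x))
  ft <- stats::mvfft(x)
  kmax <- if (n %% 2L == 0L) n %/% 2L - 1L else (n - 1L) %/% 2L
  k <- seq_len(kmax)
  list(freq = k / (n * dt),
       a = 2 * Re(ft[k + 1L, , drop = FALSE]) / n,
       b = -2 * Im(ft[k + 1L, , drop = FALSE]) / n,
       n = n)
}

#' Amplitude of low-frequency fluctuation (ALFF) map
#'
#' For each region, the demeaned signal is decomposed as
#' \eqn{x(t) = \sum_k a_k \cos(2\pi f_k t) + b_k \sin(2\pi f_k t)} and
#' \eqn{ALFF = \sum_{k: f_k \in band} \sqrt{(a_k^2 + b_k^2)/N}}.
#' DC and Nyquist bins are excluded.
#'
#' @param ts A [region_ts()].
#' @param band Two-element numeric band in Hz (inclusive), default
#'   `c(0.01, 0.08)`.
#' @return An [amp_map()] of kind `"alff"`.
#' @export
alff_map <- function(ts, band = c(0.01, 0.08)) {
  stopifnot(inherits(ts, "region_ts"), length(band) == 2L, band[1] < band[2])
  fc <- fourier_coeffs(ts$data, ts$dt)
  sel <- fc$freq >= band[1] & fc$freq <= band[2]
  if (!any(sel))
    stop(sprintf("no Fourier frequencies inside [%g, %g] Hz; record too short",
                 band[1], band[2]))
  ampl <- sqrt((fc$a[sel, , drop = FALSE]^2 + fc$b[sel, , drop = FALSE]^2) / fc$n)
  v <- colSums(ampl)
  names(v) <- ts$region_ids
  amp_map(v, kind = "alff", band = band)
}

#' Fractional ALFF map
#'
#' Ratio of the summed low-frequency Fourier amplitude to the summed
#' amplitude over all positive frequencies; values lie in `[0, 1]`. Regions
#' with zero total power are flagged `NA`.
#'
#' @inheritParams alff_map
#' @return An [amp_map()] of kind `"falff"`.
#' @export
falff_map <- function(ts, band = c(0.01, 0.08)) {
  stopifnot(inherits(ts, "region_ts"), length(band) == 2L, band[1] < band[2])
  fc <- fourier_coeffs(ts$data, ts$dt)
  sel <- fc$freq >= band[1] & fc$freq <= band[2]
  if (!any(sel))
    stop(sprintf("no Fourier frequencies inside [%g, %g] Hz", band[1], band[2]))
  ampl <- sqrt((fc$a^2 + fc$b^2) / fc$n)
  tot <- colSums(ampl)
  v <- colSums(ampl[sel, , drop = FALSE]) / tot
  v[tot == 0] <- NA_real_
  names(v) <- ts$region_ids
  amp_map(v, kind = "falff", band = band)
}

#' Z-normalize an amplitude map across regions
#'
#' Centers and scales (sample SD) the map to emphasize spatial heterogeneity;
#' rank order is preserved. Idempotent and affine-invariant up to sign.
#'
#' @param map An [amp_map()] or plain numeric vector.
#' @return An `amp_map` with `znorm = TRUE` (mean 0, SD 1 across regions).
#' @export
znorm <- function(map) {
  v <- map_values(map)
  ok <- is.finite(v)
  if (sum(ok) < 2L) stop("z-normalization needs at least 2 finite regions")
  s <- stats::sd(v[ok])
  if (s == 0) stop("z-normalization undefined: zero spatial variance")
  v[ok] <- (v[ok] - mean(v[ok])) / s
  if (inherits(map, "amp_map"))
    amp_map(v, kind = map$kind, band = map$band, znorm = TRUE)
  else amp_map(v, kind = "sd", znorm = TRUE)
}

#' Nonoverlapping window scheme
#'
#' Divides `n_frames` into `floor(n_frames / window_len)` consecutive
#' nonoverlapping windows starting at the first frame; remainder frames at
#' the run end are dropped. A 1200-frame HCP run with `window_len = 50`
#' yields 24 windows. A `stride < window_len` gives overlapping windows
#' (e.g. the 96-window variant used for entropy trajectories).
#'
#' @param n_frames Total number of frames.
#' @param window_len Frames per window (>= 2).
#' @param stride Step between window starts; defaults to `window_len`
#'   (nonoverlapping).
#' @return A list of class `window_scheme` with `window_len` and 1-based
#'   `starts` (each window covers `start .. start + window_len - 1`).
#' @export
make_windows <- function(n_frames, window_len, stride = window_len) {
  if (window_len < 2L) stop("'window_len' must be at least 2 frames")
  if (window_len > n_frames) stop("'window_len' exceeds the number of frames")
  if (stride < 1L) stop("'stride' must be positive")
  starts <- seq.int(1L, n_frames - window_len + 1L, by = stride)
  structure(list(window_len = as.integer(window_len),
                 starts = as.integer(starts)),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("window_scheme: %d windows of %d frames\n",
              length(x$starts), x$window_len))
  invisible(x)
}

# Frame indices (1-based) of window w.
window_frames <- function(ws, w) {
  s <- ws$starts[w]
  s:(s + ws$window_len - 1L)
}
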