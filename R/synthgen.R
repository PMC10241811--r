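# Synthetic-data generator: region x time signals with a planted gradient
# and slow state coupling, stage trajectories, injectable gradient-ordered
# wave events, structured connectomes, and ECoG-like channels. Ground truth
# is returned alongside every simulation so downstream stages are testable
# without restricted recordings. The generative model is a test fixture,
# not a claim about the brain.

#' Planted per-region gradient
#'
#' Latent hierarchy loadings in `[-1, 1]`, either equispaced or uniform
#' random (zero-mean by construction for the equispaced variant).
#'
#' @param n_regions Number of regions (>= 4).
#' @param seed RNG seed (random variant).
#' @param random Draw uniformly instead of equispaced?
#' @return Numeric vector of length `n_regions` in `[-1, 1]`.
#' @export
make_gradient <- function(n_regions, seed = 1L, random = FALSE) {
  if (n_regions < 4L) stop("'n_regions' must be at least 4")
  if (random) {
    set.seed(seed)
    stats::runif(n_regions, -1, 1)
  } else {
    seq(-1, 1, length.out = n_regions)
  }
}

#' Specification of a synthetic resting-state run
#'
#' Collects the generative parameters: per-region fluctuation amplitude is
#' `sigma0 + beta * rank(g_i) * s(t)` (normalized gradient rank in
#' `[0, 1]`), a shared global component loads on each region by a weight
#' interpolating `gs_weight_low -> gs_weight_high` with `rank * s(t)`, and
#' white measurement noise is added.
#'
#' @param n_regions Regions (>= 4), default 200 (Schaefer-like).
#' @param n_frames Frames, default 1200 (one HCP-like run).
#' @param dt Seconds per frame, default 0.72.
#' @param gradient Per-region loadings in `[-1, 1]`; default equispaced.
#' @param state_traj Per-frame slow state in `[0, 1]`; default a linear ramp
#'   0 to 1 (a drift from low to high vigilance).
#' @param beta Gradient-state coupling, default 1.
#' @param sigma0 Baseline fluctuation SD, default 1.
#' @param gs_weight_high,gs_weight_low Global-component loadings, default 0.
#' @param noise_sd White-noise SD, default 0.1.
#' @param seed RNG seed, default 1.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_regions = 200L, n_frames = 1200L, dt = 0.72,
                       gradient = make_gradient(n_regions),
                       state_traj = seq(0, 1, length.out = n_frames),
                       beta = 1, sigma0 = 1, gs_weight_high = 0,
                       gs_weight_low = 0, noise_sd = 0.1, seed = 1L) {
  if (n_regions < 4L) stop("'n_regions' must be at least 4")
  if (n_frames * dt < 2 / 0.01)
    stop("run too short: need n_frames * dt >= 200 s to resolve the 0.01 Hz band edge")
  if (length(gradient) != n_regions) stop("'gradient' length mismatch")
  if (stats::sd(gradient) == 0) stop("'gradient' must have nonzero variance")
  if (length(state_traj) != n_frames) stop("'state_traj' length mismatch")
  if (any(state_traj < 0 | state_traj > 1)) stop("'state_traj' must lie in [0, 1]")
  if (sigma0 < 0 || noise_sd < 0) stop("amplitudes must be nonnegative")
  structure(list(n_regions = as.integer(n_regions),
                 n_frames = as.integer(n_frames), dt = dt,
                 gradient = gradient, state_traj = state_traj, beta = beta,
                 sigma0 = sigma0, gs_weight_high = gs_weight_high,
                 gs_weight_low = gs_weight_low, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Normalized rank in [0, 1] (average ties).
norm_rank <- function(g) (rank(g) - 1) / (length(g) - 1)

# Band-limited unit-variance noise columns: white noise passed through the
# same zero-phase filter the analysis uses, then SD-normalized.
band_limited_noise <- function(n_frames, n_cols, dt, f_lo = 0.01, f_hi = 0.08) {
  w <- matrix(stats::rnorm(n_frames * n_cols), n_frames, n_cols)
  f <- filtfilt_matrix(w, f_lo, f_hi, 1 / dt)
  sweep(f, 2L, apply(f, 2L, stats::sd), `/`)
}

#' Simulate a resting-state run with planted hierarchical dynamics
#'
#' Generates `x_i(t) = [sigma0 + beta * rank(g_i) * s(t)] * eta_i(t) +
#' w_i(s(t)) * G(t) + eps_i(t)` with band-limited (0.01-0.08 Hz)
#' unit-variance noises `eta_i` and shared component `G`, where
#' `w_i = gs_weight_low + (gs_weight_high - gs_weight_low) * rank(g_i) * s(t)`.
#'
#' @param spec A [synth_spec()].
#' @return List: `ts` (a [region_ts()]) and `truth` (list with
#'   `state_traj`, `gradient`, `amp_schedule` frames x regions,
#'   `event_onsets`).
#' @export
simulate_rest <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_regions; T <- spec$n_frames
  rk <- norm_rank(spec$gradient)
  eta <- band_limited_noise(T, n, spec$dt)
  G <- band_limited_noise(T, 1L, spec$dt)[, 1L]
  amp <- spec$sigma0 + spec$beta * outer(spec$state_traj, rk)   # T x n
  w <- spec$gs_weight_low +
    (spec$gs_weight_high - spec$gs_weight_low) * outer(spec$state_traj, rk)
  x <- amp * eta + w * G
  if (spec$noise_sd > 0)
    x <- x + matrix(stats::rnorm(T * n, sd = spec$noise_sd), T, n)
  list(ts = region_ts(x, spec$dt),
       truth = list(state_traj = spec$state_traj, gradient = spec$gradient,
                    amp_schedule = amp, event_onsets = integer(0)))
}

#' Gradient-ordered propagating wave template
#'
#' One sinusoid cycle over `L` frames whose phase lags linearly with
#' gradient rank: a wave sweeping from low- to high-hierarchy regions, the
#' analytically checkable stand-in for the empirical QPP.
#'
#' @param gradient Per-region loadings.
#' @param L Template length in frames, default 30.
#' @param dt Seconds per frame, default 0.72.
#' @param lag_frac Fraction of a cycle by which the highest-rank region lags
#'   the lowest, default 0.25.
#' @return A [qpp_template()].
#' @export
make_wave_template <- function(gradient, L = 30L, dt = 0.72, lag_frac = 0.25) {
  rk <- norm_rank(gradient)
  ph <- 2 * pi * lag_frac * rk
  tt <- 2 * pi * (seq_len(L) - 1L) / L
  qpp_template(t(outer(tt, ph, function(a, b) sin(a - b))), dt = dt)
}

#' Inject wave events into a time series
#'
#' Adds `gain * template` at each onset; elsewhere the series is unchanged.
#' Onsets must be in bounds and separated by at least the template length.
#'
#' @param ts A [region_ts()].
#' @param template A [qpp_template()] (or region x L matrix).
#' @param onsets 1-based onset frames.
#' @param gain Scalar multiplier, default 1.
#' @return The modified `region_ts`.
#' @export
inject_qpp <- function(ts, template, onsets, gain = 1) {
  tpl <- if (inherits(template, "qpp_template")) template$data else as.matrix(template)
  L <- ncol(tpl)
  if (nrow(tpl) != n_regions(ts)) stop("template regions do not match")
  onsets <- sort(as.integer(onsets))
  if (any(onsets < 1L | onsets > n_frames(ts) - L + 1L))
    stop("onsets out of bounds")
  if (length(onsets) > 1L && any(diff(onsets) < L))
    stop("onsets overlap: separation must be at least the template length")
  x <- ts$data
  for (o in onsets)
    x[o:(o + L - 1L), ] <- x[o:(o + L - 1L), ] + gain * t(tpl)
  as_region_ts(x, ts)
}

#' Simulate a sleep-stage-like state trajectory
#'
#' Piecewise-constant Markov walk over the given levels (e.g. wakefulness 0,
#' N1 -1, N2 -2, slow-wave sleep -3): each segment dwells between
#' `dwell_frames` and `2 * dwell_frames` frames, then steps to a
#' neighbouring level (reflecting at the extremes).
#'
#' @param n_frames Trajectory length.
#' @param dwell_frames Minimum dwell per stage (>= 1).
#' @param levels Numeric stage levels in order, default `c(0, -1, -2, -3)`.
#' @param seed RNG seed.
#' @return Numeric per-frame stage sequence.
#' @export
simulate_stage_traj <- function(n_frames, dwell_frames,
                                levels = c(0, -1, -2, -3), seed = 1L) {
  if (!length(levels)) stop("'levels' must be nonempty")
  if (dwell_frames < 1L) stop("'dwell_frames' must be at least 1")
  set.seed(seed)
  nl <- length(levels)
  out <- numeric(0)
  i <- 1L
  while (length(out) < n_frames) {
    run <- sample.int(dwell_frames + 1L, 1L) - 1L + dwell_frames  # dwell..2*dwell
    out <- c(out, rep(levels[i], run))
    if (nl > 1L) {
      step <- if (i == 1L) 1L else {
        if (i == nl) -1L else sample(c(-1L, 1L), 1L)
      }
      i <- i + step
    }
  }
  out[seq_len(n_frames)]
}

#' Simulate ECoG-like channels with gradient-coupled gamma modulation
#'
#' Each channel is a gamma-band (default 50-70 Hz) noise carrier whose slow
#' envelope is `1 + couple * rank(g_i) * mod_traj(t)`, plus a 2 Hz delta
#' oscillation and white noise. A channel's gamma band-limited power thus
#' tracks the modulation trajectory in proportion to its gradient rank.
#'
#' @param n_channels Channels.
#' @param fs Sampling rate in Hz (>= 250).
#' @param duration_s Recording length in seconds.
#' @param gradient Per-channel loadings; default equispaced.
#' @param mod_traj Slow modulation in `[0, 1]`, any length (linearly
#'   resampled to the samples); default a 0-to-1 ramp.
#' @param couple Envelope coupling strength, default 1.
#' @param carrier_band Carrier band in Hz, default `c(50, 70)`.
#' @param delta_amp Amplitude of the 2 Hz oscillation, default 0.5.
#' @param noise_sd White-noise SD, default 0.1.
#' @param seed RNG seed.
#' @return A [channel_rec()].
#' @export
simulate_ecog <- function(n_channels, fs, duration_s,
                          gradient = make_gradient(n_channels),
                          mod_traj = c(0, 1), couple = 1,
                          carrier_band = c(50, 70), delta_amp = 0.5,
                          noise_sd = 0.1, seed = 1L) {
  if (fs < 250) stop("'fs' must be at least 250 Hz for 1-100 Hz analysis")
  set.seed(seed)
  ns <- round(fs * duration_s)
  rk <- norm_rank(gradient)
  mod <- stats::approx(seq(0, 1, length.out = length(mod_traj)), mod_traj,
                       xout = seq(0, 1, length.out = ns))$y
  tt <- (seq_len(ns) - 1L) / fs
  delta <- delta_amp * sin(2 * pi * 2 * tt)
  x <- matrix(0, n_channels, ns)
  for (ch in seq_len(n_channels)) {
    carrier <- filtfilt_matrix(matrix(stats::rnorm(ns), ns, 1L),
                               carrier_band[1], carrier_band[2], fs)[, 1L]
    carrier <- carrier / stats::sd(carrier)
    env <- 1 + couple * rk[ch] * mod
    x[ch, ] <- env * carrier + delta + stats::rnorm(ns, sd = noise_sd)
  }
  channel_rec(x, fs)
}

#' Structured connectome with a latent 1-D coordinate
#'
#' `C_ij = exp(-decay * |p_i - p_j|)` for equispaced latent positions
#' `p in [0, 1]`: symmetric, unit diagonal, and its principal diffusion
#' embedding is monotone in `p` — the oracle fixture for embedding tests.
#'
#' @param n_regions Nodes.
#' @param decay Positive decay rate.
#' @return List: `C` (matrix), `p` (latent positions).
#' @export
make_structured_connectome <- function(n_regions, decay = 3) {
  if (decay <= 0) stop("'decay' must be positive")
  p <- seq(0, 1, length.out = n_regions)
  C <- exp(-decay * abs(outer(p, p, `-`)))
  dimnames(C) <- list(paste0("r", seq_len(n_regions)),
                      paste0("r", seq_len(n_regions)))
  list(C = C, p = p)
}
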