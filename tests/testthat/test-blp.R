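# Multitaper spectrogram, normalization, band-limited power, and the
# gamma/delta event statistics.

test_that("dpss tapers are orthonormal and spectrally concentrated", {
  tap <- dpss_tapers(400, nw = 3, k = 5)
  expect_equal(dim(tap), c(400L, 5L))
  expect_equal(t(tap) %*% tap, diag(5), tolerance = 1e-8)
  # in-band energy concentration of the first taper (|f| <= NW/N)
  spec <- Mod(fft(c(tap[, 1], rep(0, 3600))))^2
  inband <- sum(spec[1:31]) + sum(spec[(4000 - 29):4000])  # +/- 3/400 cycles
  expect_gt(inband / sum(spec), 0.999)
})

test_that("multitaper spectrogram localizes tones and counts frames", {
  fs <- 400
  t <- (0:(fs * 20 - 1)) / fs
  rec <- channel_rec(rbind(sin(2 * pi * 60 * t), rep(0, length(t))), fs)
  sp <- multitaper_spectrogram(rec)
  # frame count = floor((T_s - win_s)/step_s) + 1
  expect_equal(dim(sp$power)[3], floor((20 - 1) / 0.2) + 1)
  expect_equal(dim(sp$power)[2], 100L)
  # 60 Hz tone concentrates within the taper bandwidth (NW = 3 -> +/- 3 Hz)
  pw <- apply(sp$power[1, , ], 1, mean)
  expect_equal(which.max(pw), 60L)
  expect_gt(sum(pw[57:63]) / sum(pw), 0.95)
  # zero signal -> zero power
  expect_equal(max(sp$power[2, , ]), 0, tolerance = 1e-20)
  expect_error(multitaper_spectrogram(channel_rec(matrix(rnorm(3000), 1), 300),
                                      f_max = 200), "resolve")
})

test_that("spectrogram normalization removes temporal means and global gain", {
  set.seed(1)
  rec <- channel_rec(matrix(rnorm(2 * 4000), 2), 400)
  sp <- normalize_spectrogram(multitaper_spectrogram(rec))
  mu <- apply(sp$power, c(1, 2), mean)
  expect_lt(max(abs(mu)), 1e-10)
  # doubling the raw signal (4x power) changes nothing after normalization
  rec2 <- channel_rec(2 * rec$data, 400)
  sp2 <- normalize_spectrogram(multitaper_spectrogram(rec2))
  expect_equal(sp$power, sp2$power, tolerance = 1e-8)
  expect_error(normalize_spectrogram(sp), "already")
})

test_that("band_power averages the right bins", {
  set.seed(2)
  rec <- channel_rec(matrix(rnorm(2000), 1), 400)
  sp <- normalize_spectrogram(multitaper_spectrogram(rec))
  bp <- band_power(sp, "gamma")
  oracle <- apply(sp$power[1, 40:100, , drop = FALSE], 3, mean)
  expect_equal(bp$data[1, ], oracle, tolerance = 1e-12)
  bp_d <- band_power(sp, "delta")
  oracle_d <- apply(sp$power[1, 1:4, , drop = FALSE], 3, mean)
  expect_equal(bp_d$data[1, ], oracle_d, tolerance = 1e-12)
  expect_error(band_power(sp, "theta"), "unknown band")
  raw <- multitaper_spectrogram(rec)
  expect_error(band_power(raw, "gamma"), "normalize")
})

test_that("gamma BLP recovers a slow amplitude-modulation envelope", {
  fs <- 400
  dur <- 300
  t <- (0:(fs * dur - 1)) / fs
  env <- 1 + 0.8 * sin(2 * pi * 0.04 * t)
  set.seed(3)
  carrier <- sin(2 * pi * 60 * t + cumsum(rnorm(length(t), sd = 0.05)))
  rec <- channel_rec(matrix(env * carrier + rnorm(length(t), sd = 0.2), 1), fs)
  sp <- normalize_spectrogram(multitaper_spectrogram(rec))
  blp <- blp_filter(band_power(sp, "gamma"))
  mod <- sin(2 * pi * 0.04 * blp$times)
  expect_gt(cor(blp$data[1, ], mod), 0.9)
  # zero-phase: the filtered BLP peaks align with the modulator (lag 0 beats
  # lags of +/- a quarter period)
  lag <- round(6.25 / blp$step_s)    # quarter of the 25 s period
  n <- length(mod)
  r0 <- cor(blp$data[1, ], mod)
  rlag <- cor(blp$data[1, seq_len(n - lag)], mod[seq_len(n - lag) + lag])
  expect_gt(r0, rlag)
})

test_that("blp_hier_trajectory tracks a planted gradient-coupled modulation", {
  mod <- rep(c(0.1, 0.9), each = 500)   # two 150 s half-recordings
  rec <- simulate_ecog(n_channels = 12, fs = 400, duration_s = 300,
                       mod_traj = mod, couple = 2, noise_sd = 0.05, seed = 4)
  sp <- normalize_spectrogram(multitaper_spectrogram(rec))
  blp <- blp_filter(band_power(sp, "gamma"))
  traj <- blp_hier_trajectory(blp, make_gradient(12), window_s = 150)
  # 300 s at 0.2 s frames: ~1496 frames -> one full 750-frame fragment at
  # low modulation, the second fragment catches the high-modulation half
  expect_gte(length(traj$rho), 1L)
  sdmap_hi <- apply(blp$data[, 800:1400], 1, sd)
  expect_gt(spearman_oracle(sdmap_hi, make_gradient(12)), 0.8)
})

test_that("peak_difference contrasts hierarchy extremes and reads the delta tail", {
  g <- make_gradient(10)
  step <- 0.2
  nf <- 100                                  # 20 s event
  base <- matrix(1, 10, nf)
  # identical traces: zero peak difference
  d0 <- peak_difference(base, base, g, step)
  expect_equal(d0$peak_diff, 0)
  # constant offset c between high and low channels
  up <- base
  up[9:10, ] <- up[9:10, ] + 0.7             # top 20% of 10 channels
  d1 <- peak_difference(up, base, g, step)
  expect_equal(d1$peak_diff, 0.7, tolerance = 1e-12)
  # later_delta averages frames (head_s, head_s + tail_s]
  delta <- matrix(0, 10, nf)
  delta[, 61:80] <- 3                        # exactly the 12-16 s span
  d2 <- peak_difference(base, delta, g, step)
  expect_equal(d2$later_delta, 3)
  expect_error(peak_difference(base[, 1:50], delta[, 1:50], g, step),
               "shorter")
})

test_that("gamma surges preceding delta suppression couple across events", {
  set.seed(5)
  g <- make_gradient(10)
  step <- 0.2
  n_ev <- 30
  stats <- t(sapply(seq_len(n_ev), function(i) {
    surge <- runif(1, 0, 2)                  # planted high-order gamma surge
    gamma <- matrix(rnorm(10 * 100, sd = 0.1), 10, 100)
    gamma[9:10, 20:40] <- gamma[9:10, 20:40] + surge
    delta <- matrix(rnorm(10 * 100, sd = 0.1), 10, 100) - surge  # suppression
    pd <- peak_difference(gamma, delta, g, step)
    c(pd$peak_diff, pd$later_delta)
  }))
  expect_lt(cor(stats[, 1], stats[, 2]), -0.5)
})
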