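# QPP template matching, event detection, template building and summaries.

test_that("sliding_match equals the brute-force per-lag correlation", {
  set.seed(1)
  g <- make_gradient(15)
  tpl <- make_wave_template(g, L = 12, dt = 1)
  x <- matrix(rnorm(80 * 15), 80, 15)
  ts <- region_ts(x, dt = 1)
  cs <- sliding_match(ts, tpl)
  expect_length(cs, 80 - 12 + 1)
  oracle <- sapply(1:(80 - 12 + 1), function(tau) {
    cor(as.numeric(t(x[tau:(tau + 11), ])), as.numeric(tpl$data))
  })
  expect_equal(cs, oracle, tolerance = 1e-10)
  # exact template and its negation at a known lag
  y <- matrix(0, 60, 15)
  y[20:31, ] <- t(tpl$data)
  ym <- sliding_match(region_ts(y + 1e-9 * matrix(rnorm(900), 60), dt = 1), tpl)
  expect_equal(ym[20], 1, tolerance = 1e-6)
  y2 <- y; y2[20:31, ] <- -t(tpl$data)
  ym2 <- sliding_match(region_ts(y2 + 1e-9 * matrix(rnorm(900), 60), dt = 1), tpl)
  expect_equal(ym2[20], -1, tolerance = 1e-6)
  # affine invariance of the match series
  cs2 <- sliding_match(region_ts(3 * x + 7, dt = 1), tpl)
  expect_equal(cs, cs2, tolerance = 1e-10)
})

test_that("detect_events finds thresholded local maxima with suppression", {
  expect_length(detect_events(rep(0, 100))$onsets, 0L)
  v <- rep(0.1, 200); v[100] <- 0.9
  ev <- detect_events(v, threshold = 0.4)
  expect_equal(ev$onsets, 100L)
  expect_equal(ev$r, 0.9)
  # plateau resolves to its leftmost frame
  vp <- rep(0, 50); vp[20:23] <- 0.7
  expect_equal(detect_events(vp)$onsets, 20L)
  # suppression keeps the higher of two close maxima
  v2 <- rep(0, 100); v2[30] <- 0.5; v2[35] <- 0.8
  expect_equal(detect_events(v2, min_sep = 10)$onsets, 35L)
  expect_equal(detect_events(v2, min_sep = 2)$onsets, c(30L, 35L))
  # monotone in threshold: lower threshold detects a superset
  set.seed(2)
  v3 <- as.numeric(stats::filter(rnorm(500), rep(0.2, 5), circular = TRUE))
  e_lo <- detect_events(v3, threshold = 0.2, min_sep = 5)
  e_hi <- detect_events(v3, threshold = 0.6, min_sep = 5)
  expect_true(all(e_hi$onsets %in% e_lo$onsets))
})

test_that("injected events are recovered at matched-filter SNR", {
  set.seed(3)
  g <- make_gradient(200)
  tpl <- make_wave_template(g, L = 30, dt = 0.72)
  onsets <- seq(50, by = 95, length.out = 10)
  ts <- region_ts(matrix(rnorm(2000 * 200, sd = 0.5), 2000, 200), dt = 0.72)
  ts <- inject_qpp(ts, tpl, onsets, gain = 1)     # gain / noise_sd = 2
  ev <- detect_events(sliding_match(ts, tpl), threshold = 0.4, min_sep = 30)
  hits <- sapply(onsets, function(o) any(abs(ev$onsets - o) <= 1))
  expect_gte(sum(hits), 9L)
  # oracle: brute-force correlation scan agrees at the detected onsets
  for (o in ev$onsets[1:3]) {
    seg <- as.numeric(t(ts$data[o:(o + 29), ]))
    expect_gte(cor(seg, as.numeric(tpl$data)), 0.4)
  }
})

test_that("build_template recovers a cycle of periodic data and is a fixed point", {
  g <- make_gradient(80)
  tpl <- make_wave_template(g, L = 30, dt = 0.72)
  ts <- periodic_wave_ts(tpl, 600, dt = 0.72)
  bt <- build_template(ts, L = 30, seed = 4)
  pa <- phase_align(tpl, bt, max_shift = 15)
  expect_gt(abs(pa$r), 0.99)
  # re-running detection from the returned template changes no events
  ev1 <- detect_events(sliding_match(ts, bt), 0.4, min_sep = 30)
  segs <- lapply(ev1$onsets, function(o) t(ts$data[o:(o + 29), ]))
  tpl2 <- Reduce(`+`, segs) / length(segs)
  ev2 <- detect_events(sliding_match(ts, qpp_template(tpl2, 0.72)), 0.4,
                       min_sep = 30)
  expect_identical(ev1$onsets, ev2$onsets)
  # pure noise at a high threshold yields an error or nearly no events
  set.seed(5)
  noise <- region_ts(matrix(rnorm(300 * 20), 300, 20), dt = 1)
  res <- tryCatch(build_template(noise, L = 30, threshold = 0.8, seed = 6),
                  error = function(e) "no-events")
  if (!identical(res, "no-events")) {
    ev <- detect_events(sliding_match(noise, res), 0.8, min_sep = 30)
    expect_lte(length(ev$onsets), 2L)
  } else expect_identical(res, "no-events")
})

test_that("phase_align recovers known shifts with the documented tie-break", {
  g <- make_gradient(30)
  tpl <- make_wave_template(g, L = 20, dt = 1)
  expect_equal(phase_align(tpl, tpl)$shift, 0L)
  # delaying b by 3 frames is undone by shift -3
  rolled <- tpl$data[, ((seq_len(20) - 1 - 3) %% 20) + 1]
  pa <- phase_align(tpl, rolled, max_shift = 6)
  expect_equal(pa$shift, -3L)
  expect_equal(pa$r, 1, tolerance = 1e-12)
  # cross-correlation argmax oracle for sinusoidal templates
  b <- tpl$data[, ((seq_len(20) - 1 + 5) %% 20) + 1]
  oracle <- sapply(-8:8, function(s) {
    idx <- ((seq_len(20) - 1 - s) %% 20) + 1
    cor(as.numeric(tpl$data), as.numeric(b[, idx]))
  })
  expect_equal(phase_align(tpl, b, max_shift = 8)$shift, (-8:8)[which.max(oracle)])
})

test_that("gradient_projection is the plain dot product", {
  g <- make_gradient(10)
  expect_equal(gradient_projection(g, g), sum(g^2))
  perp <- c(rep(1, 5), rep(-1, 5))
  perp <- perp - sum(perp * g) * g / sum(g^2)
  expect_equal(gradient_projection(perp, g), 0, tolerance = 1e-12)
  set.seed(6)
  v <- rnorm(10)
  expect_equal(gradient_projection(v, g), sum(v * g))
})

test_that("event_traces expose the low-to-high propagation lag", {
  g <- make_gradient(50)
  tpl <- make_wave_template(g, L = 30, dt = 1, lag_frac = 0.25)
  base <- region_ts(matrix(0, 200, 50), dt = 1)
  ts <- inject_qpp(base, tpl, onsets = 50)
  tr <- event_traces(ts, 50, g, L = 30, frac = 0.2)
  expect_length(tr, 1L)
  expect_length(tr[[1]]$low, 30L)
  expect_gt(which.max(tr[[1]]$high), which.max(tr[[1]]$low))
  # homogeneous regions: identical traces
  hom <- region_ts(matrix(rep(sin(1:100 / 5), 50), 100, 50), dt = 1)
  tr2 <- event_traces(hom, 10, g, L = 20)
  expect_equal(tr2[[1]]$low, tr2[[1]]$high)
  expect_error(event_traces(ts, 50, g, L = 30, frac = 0.001), "at least 1")
})

test_that("classify_trajectory applies the r >= threshold convention", {
  tr <- sin(2 * pi * (1:30) / 30)
  expect_equal(classify_trajectory(tr, tr), "typical")
  expect_equal(classify_trajectory(-tr, tr), "atypical")
  # boundary: r exactly at the threshold counts as typical
  a <- c(1, 2, 3, 4)
  b <- c(2, 1, 4, 3)            # r = 0.6 with a
  expect_equal(classify_trajectory(b, a, r_thresh = cor(a, b)), "typical")
  expect_warning(cl <- classify_trajectory(rep(1, 30), tr), "constant")
  expect_equal(cl, "atypical")
})

test_that("event_network_fc averages within networks with a valid contrast", {
  set.seed(7)
  n <- 40
  labs <- rep(1:4, each = 10)
  g <- make_gradient(n)
  # group A: networks 1 and 2 anticorrelated; group B: independent
  mk_ev <- function(anti) {
    f <- rnorm(30)
    x <- matrix(rnorm(30 * n, sd = 0.3), 30, n)
    x[, labs == 1] <- x[, labs == 1] + f
    x[, labs == 2] <- x[, labs == 2] + (if (anti) -f else rnorm(30))
    x
  }
  build_run <- function(k, anti) {
    xs <- lapply(seq_len(k), function(i) rbind(mk_ev(anti), matrix(0, 10, n)))
    region_ts(do.call(rbind, xs) + 1e-9, dt = 1)
  }
  tsA <- build_run(6, TRUE); tsB <- build_run(6, FALSE)
  onsets <- seq(1, by = 40, length.out = 6)
  fcA <- event_network_fc(tsA, onsets, labs, L = 30)
  fcB <- event_network_fc(tsB, onsets, labs, L = 30)
  expect_equal(fcA$mean_fc, t(fcA$mean_fc), tolerance = 1e-12)
  expect_equal(diag(fcA$mean_fc), rep(1, 4))
  expect_lt(fcA$mean_fc[1, 2], -0.5)
  ct <- network_fc_contrast(fcA$per_event, fcB$per_event)
  expect_lt(ct$t[1, 2], 0)
  expect_lt(ct$p[1, 2], 0.05)
  # identical events give zero t
  ct0 <- network_fc_contrast(fcA$per_event, fcA$per_event)
  expect_equal(ct0$t[1, 2], 0, tolerance = 1e-10)
  expect_error(event_network_fc(tsA, onsets, rep(1, n), L = 30), NA)
  expect_error(event_network_fc(tsA, onsets,
                                factor(rep(1:3, length.out = n), levels = 1:4),
                                L = 30),
               "empty")
})
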