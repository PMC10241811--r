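# GS topography, state clustering, node strength and the entropy measures.

test_that("global_signal and gs_topography match direct oracles", {
  set.seed(1)
  x <- matrix(rnorm(300), 100, 3)
  expect_equal(global_signal(x), rowMeans(x))
  expect_equal(global_signal(x[, 1, drop = FALSE]), x[, 1])
  # two anti-phase sinusoids cancel
  t <- 1:100
  anti <- cbind(sin(t / 5), -sin(t / 5))
  expect_equal(global_signal(anti), rep(0, 100), tolerance = 1e-12)
  topo <- gs_topography(x)
  gs <- rowMeans(x)
  expect_equal(unname(topo), as.numeric(cor(x, gs)), tolerance = 1e-12)
  # a region equal to +/- the global signal
  y <- cbind(gs, -gs, x)
  topo2 <- gs_topography(y)
  expect_equal(unname(topo2[1:2]), c(1, -1), tolerance = 1e-10)
})

test_that("cluster_states recovers planted topography families", {
  g <- make_gradient(60)
  set.seed(2)
  topo <- rbind(t(sapply(1:40, function(i) g + rnorm(60, sd = 0.3))),
                t(sapply(1:40, function(i) -g + rnorm(60, sd = 0.3))))
  truth <- rep(1:2, each = 40)
  cl <- cluster_states(topo, seed = 3)
  expect_equal(cl$k, 2L)
  expect_gte(label_accuracy(cl$labels, truth), 0.95)
  # silhouette prefers the planted two-family structure
  expect_gt(cl$silhouette["2"], cl$silhouette["3"])
  expect_equal(which.max(cl$silhouette), c("2" = 1L))
  # determinism under a fixed seed
  cl2 <- cluster_states(topo, seed = 3)
  expect_identical(cl$labels, cl2$labels)
  # silhouette oracle on the chosen labels
  sil <- cluster::silhouette(cl$labels, dist(topo))
  expect_equal(unname(cl$silhouette["2"]), mean(sil[, "sil_width"]),
               tolerance = 1e-12)
  expect_error(cluster_states(matrix(1, 30, 5)), "degenerate")
})

test_that("centroid_contrast orders states by gradient similarity", {
  g <- make_gradient(60)
  set.seed(4)
  topo <- rbind(t(sapply(1:30, function(i) 0.8 * g + rnorm(60, sd = 0.3))),
                t(sapply(1:30, function(i) -0.8 * g + rnorm(60, sd = 0.3))))
  cl <- cluster_states(topo, k_select = 2, seed = 5)
  cc <- centroid_contrast(cl, g)
  expect_gt(spearman_oracle(cc$contrast, g), 0.9)
  # state 1 is the higher-similarity state by definition
  expect_equal(cc$state1, which.max(cc$similarity))
  # identical centroids give a zero map
  cl0 <- cl
  cl0$centroids[2, ] <- cl0$centroids[1, ]
  cc0 <- centroid_contrast(cl0, g)
  expect_equal(unname(cc0$contrast), rep(0, 60))
})

test_that("node_strength sums off-diagonal weights", {
  M <- matrix(1, 4, 4)
  expect_equal(node_strength(M), rep(3, 4))
  expect_equal(node_strength(matrix(0, 3, 3)), rep(0, 3))
  set.seed(5)
  S <- matrix(rnorm(36), 6, 6); S <- S + t(S)
  expect_equal(node_strength(S),
               sapply(1:6, function(i) sum(S[i, -i])))
})

test_that("connectivity_entropy equals the brute-force histogram entropy", {
  # all values in one bin
  expect_equal(as.numeric(connectivity_entropy(c(1, 1, 1 + 1e-16, 1))), 0)
  # exactly uniform counts across 10 bins -> 1
  v <- rep(seq(0.05, 0.95, by = 0.1), each = 5)   # 5 values per decile bin
  expect_equal(connectivity_entropy(v, 10), 1, tolerance = 1e-12)
  # random profile vs an independent direct implementation
  set.seed(6)
  x <- runif(199, -1, 1)
  br <- seq(min(x), max(x), length.out = 11)
  cnt <- hist(x, breaks = br, plot = FALSE)$counts
  p <- cnt / sum(cnt); p <- p[p > 0]
  oracle <- -sum(p * log(p)) / log(10)
  expect_equal(connectivity_entropy(x, 10), oracle, tolerance = 1e-12)
  # bounded and affine-invariant
  expect_true(connectivity_entropy(x) >= 0 && connectivity_entropy(x) <= 1)
  expect_equal(connectivity_entropy(5 * x - 2), connectivity_entropy(x),
               tolerance = 1e-12)
})

test_that("sample_entropy equals an exhaustive pair-count oracle", {
  sampen_oracle <- function(x, m = 2, r_factor = 0.5) {
    r <- r_factor * sd(x)
    n <- length(x)
    np <- n - m
    count <- function(len) {
      cnt <- 0L
      for (i in 1:(np - 1)) for (j in (i + 1):np) {
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r)
          cnt <- cnt + 1L
      }
      cnt
    }
    -log(count(m + 1) / count(m))
  }
  expect_equal(as.numeric(sample_entropy(rep(2, 10))), 0)
  # strictly increasing ramp: no template pair is within tolerance, so the
  # ratio is undefined in both the implementation and the oracle
  x6 <- c(1, 2, 3, 4, 5, 6)
  expect_true(is.nan(as.numeric(sample_entropy(x6))))
  expect_true(is.nan(suppressWarnings(sampen_oracle(x6))))
  set.seed(7)
  for (len in c(20, 35, 50)) {
    x <- rnorm(len)
    expect_equal(as.numeric(sample_entropy(x)), sampen_oracle(x),
                 tolerance = 1e-12)
  }
  # monotone decreasing in r_factor (until saturation)
  x <- rnorm(100)
  h <- sapply(c(0.2, 0.5, 1, 2),
              function(rf) as.numeric(sample_entropy(x, r_factor = rf)))
  expect_true(all(diff(h) <= 0))
})

test_that("noise is less regular than a same-variance sinusoid", {
  set.seed(8)
  wins <- replicate(100, {
    noise <- rnorm(500)
    sine <- sqrt(2) * sin(2 * pi * (1:500) / 50 + runif(1, 0, 2 * pi))
    sample_entropy(noise) > sample_entropy(sine)
  })
  expect_gte(mean(wins), 0.95)
})

test_that("state_entropy_summary separates a planted high-diversity state", {
  set.seed(9)
  n <- 40; T <- 400
  # state A windows: regions split into two anticorrelated families with
  # noise (diverse FC values); state B windows: one common driver
  # (homogeneous high FC)
  mk_win <- function(diverse) {
    if (diverse) {
      f <- rnorm(50)
      sapply(1:n, function(i) rnorm(1) * f + rnorm(50))
    } else {
      f <- rnorm(50)
      sapply(1:n, function(i) f + rnorm(50, sd = 0.2))
    }
  }
  labs <- rep(c(1L, 2L), times = 4)
  x <- do.call(rbind, lapply(labs, function(l) mk_win(l == 1L)))
  ts <- region_ts(x, dt = 1)
  cl <- structure(list(labels = labs, k = 2L), class = "state_clustering")
  es <- state_entropy_summary(ts, cl, window_len = 50)
  expect_equal(nrow(es), 8L)
  expect_gt(mean(es$conn_entropy[es$label == 1]),
            mean(es$conn_entropy[es$label == 2]))
  # identical windows give zero between-state difference
  one <- mk_win(TRUE)
  x2 <- do.call(rbind, rep(list(one), 4))
  es2 <- state_entropy_summary(region_ts(x2, dt = 1),
                               structure(list(labels = rep(1:2, 2), k = 2L),
                                         class = "state_clustering"),
                               window_len = 50)
  expect_equal(mean(es2$conn_entropy[es2$label == 1]),
               mean(es2$conn_entropy[es2$label == 2]), tolerance = 1e-12)
})
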