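# Time-resolved global-signal topography, k-means state decomposition,
# node strength, and the two entropy measures (connectivity and sample
# entropy).

#' Global signal of a run
#'
#' Unweighted mean across regions at each frame.
#'
#' @param ts A [region_ts()] or plain frames x regions matrix.
#' @return Numeric vector, one value per frame.
#' @export
global_signal <- function(ts) {
  x <- if (inherits(ts, "region_ts")) ts$data else as.matrix(ts)
  rowMeans(x)
}

#' Global-signal topography of a window
#'
#' Per-region Pearson correlation with the window's global signal: the
#' spatial pattern of which regions "ride" the global fluctuation in that
#' moment.
#'
#' @param ts_window A [region_ts()] or matrix restricted to one window
#'   (>= 3 frames).
#' @return Numeric vector in `[-1, 1]` per region; constant regions are
#'   flagged `NA`.
#' @export
gs_topography <- function(ts_window) {
  x <- if (inherits(ts_window, "region_ts")) ts_window$data else as.matrix(ts_window)
  if (nrow(x) < 3L) stop("window must have at least 3 frames")
  gs <- rowMeans(x)
  r <- suppressWarnings(as.numeric(stats::cor(x, gs)))
  names(r) <- colnames(x)
  r
}

#' Windowed GS topographies for a run
#'
#' @param ts A [region_ts()].
#' @param window_len Frames per window, default 50.
#' @param stride Step between windows, default nonoverlapping.
#' @return window x region matrix of GS topographies.
#' @export
gs_topography_windows <- function(ts, window_len = 50L, stride = window_len) {
  ws <- make_windows(n_frames(ts), window_len, stride)
  t(vapply(seq_along(ws$starts), function(w) {
    gs_topography(ts$data[window_frames(ws, w), , drop = FALSE])
  }, numeric(n_regions(ts))))
}

#' K-means decomposition of GS topographies into brain states
#'
#' Euclidean k-means (multiple restarts) on window topography vectors, with
#' the average silhouette width computed for each candidate k. By default
#' the k with the largest silhouette is selected; `k_select` pins a fixed
#' solution (the two-state solution of the resting-state analysis).
#'
#' @param topographies window x region matrix (e.g.
#'   [gs_topography_windows()]).
#' @param k_range Candidate cluster counts, default `2:10`.
#' @param k_select Optional fixed k overriding the silhouette choice.
#' @param seed RNG seed for the restarts.
#' @param nstart Random restarts per k, default 50.
#' @return Object of class `state_clustering`: `labels` (1..k per window),
#'   `centroids` (k x region), `k`, `silhouette` (named by k), `seed`.
#' @export
cluster_states <- function(topographies, k_range = 2:10, k_select = NULL,
                           seed = 1L, nstart = 50L) {
  X <- as.matrix(topographies)
  k_range <- k_range[k_range * 2L <= nrow(X)]
  if (!length(k_range)) stop("too few windows for any candidate k")
  if (stats::sd(as.numeric(stats::dist(X[seq_len(min(50L, nrow(X))), ]))) == 0)
    stop("degenerate identical topographies")
  dX <- stats::dist(X)
  fits <- list()
  sil <- numeric(length(k_range))
  names(sil) <- as.character(k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)
    fits[[i]] <- stats::kmeans(X, centers = k, nstart = nstart,
                               iter.max = 100L)
    sil[i] <- mean(cluster::silhouette(fits[[i]]$cluster, dX)[, "sil_width"])
  }
  k <- if (is.null(k_select)) k_range[which.max(sil)] else k_select
  if (!k %in% k_range) stop("'k_select' outside the evaluated range")
  fit <- fits[[match(k, k_range)]]
  structure(list(labels = fit$cluster, centroids = fit$centers, k = k,
                 silhouette = sil, seed = seed),
            class = "state_clustering")
}

#' @export
print.state_clustering <- function(x, ...) {
  cat(sprintf("state_clustering: k = %d over %d windows; silhouette max at k = %s\n",
              x$k, length(x$labels),
              names(x$silhouette)[which.max(x$silhouette)]))
  invisible(x)
}

#' Centroid contrast map of a two-state clustering
#'
#' Orders the two states by their hierarchical similarity (Spearman with
#' the gradient): State 1 is the higher-similarity state, and the contrast
#' is `centroid(State 1) - centroid(State 2)`. In the resting-state
#' analysis this difference recapitulates the principal gradient.
#'
#' @param clustering A `state_clustering` with `k = 2`.
#' @param gradient Gradient map or numeric vector on the same regions.
#' @return List: `contrast` (per-region difference), `state1` (original
#'   cluster id of the higher-similarity state), `similarity` (per-state
#'   Spearman with the gradient).
#' @export
centroid_contrast <- function(clustering, gradient) {
  stopifnot(inherits(clustering, "state_clustering"))
  if (clustering$k != 2L) stop("centroid contrast is defined for k = 2")
  g <- map_values(gradient)
  simil <- apply(clustering$centroids, 1L, spearman, y = g)
  s1 <- which.max(simil)
  s2 <- setdiff(1:2, s1)
  list(contrast = clustering$centroids[s1, ] - clustering$centroids[s2, ],
       state1 = s1, similarity = simil)
}

#' Node strength of a weighted network
#'
#' Sum of each node's link weights, excluding the self-connection.
#'
#' @param C Square symmetric weight matrix.
#' @return Numeric vector per node.
#' @export
node_strength <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  rowSums(C) - diag(C)
}

#' Connectivity entropy of a node's FC profile
#'
#' Normalized Shannon entropy `H = -sum p_i log(p_i) / log(n_bins)` of the
#' node's functional-connectivity values discretized into `n_bins`
#' equal-width bins spanning their observed range; `0 log 0 = 0`. Values in
#' `[0, 1]`; invariant to affine rescaling of the profile.
#'
#' @param fc_row Numeric vector of the node's FC values (self-connection
#'   already excluded).
#' @param n_bins Number of bins, default 10.
#' @return Entropy in `[0, 1]`; a constant profile returns 0 (flagged with
#'   attribute `degenerate = TRUE`).
#' @export
connectivity_entropy <- function(fc_row, n_bins = 10L) {
  stopifnot(n_bins >= 2L)
  v <- fc_row[is.finite(fc_row)]
  if (!length(v)) stop("no finite values in the FC profile")
  rng <- range(v)
  if (rng[1] == rng[2]) return(structure(0, degenerate = TRUE))
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n_bins)
}

#' Sample entropy of a time series
#'
#' Richman-Moorman sample entropy: with tolerance `r = r_factor * SD(x)`,
#' `B` counts pairs of length-`m` templates within Chebyshev distance `r`
#' (self-matches excluded, overlapping templates allowed, templates taken
#' at positions `1..N-m` so every one extends to length `m+1`), `A` the
#' same for length `m+1`, and `H = -log(A/B)`.
#'
#' @param x Numeric time series (length >= m + 2).
#' @param m Template length, default 2.
#' @param r_factor Tolerance as a multiple of the series SD, default 0.5.
#' @return Nonnegative entropy; a constant series gives 0. `A = 0` gives
#'   `Inf` (flagged with attribute `degenerate = TRUE`); `B = 0` gives `NaN`
#'   likewise.
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(m >= 1L, r_factor > 0)
  if (n < m + 2L) stop("series too short for sample entropy")
  r <- r_factor * stats::sd(x)
  np <- n - m                       # template start positions for both lengths
  # Chebyshev distances accumulated coordinate-by-coordinate
  cheb <- function(len) {
    D <- matrix(0, np, np)
    for (off in 0:(len - 1L)) {
      seg <- x[seq_len(np) + off]
      D <- pmax(D, abs(outer(seg, seg, `-`)))
    }
    D
  }
  Bmat <- cheb(m) <= r
  Amat <- cheb(m + 1L) <= r
  B <- (sum(Bmat) - np) / 2         # exclude self-matches, count pairs once
  A <- (sum(Amat) - np) / 2
  if (B == 0) return(structure(NaN, degenerate = TRUE))
  if (A == 0) return(structure(Inf, degenerate = TRUE))
  -log(A / B)
}

#' Per-window entropy summaries aligned with a state clustering
#'
#' For each window: the mean connectivity entropy over regions (from the
#' window's Pearson FC matrix) and the mean sample entropy of the region
#' time courses, tabulated with the window's state label so between-state
#' differences and index correlations can be reported.
#'
#' @param ts A [region_ts()].
#' @param clustering A `state_clustering` whose labels align with the
#'   windows of `window_len`/`stride`.
#' @param window_len,stride Windowing as used for the clustering.
#' @param n_bins Bins for connectivity entropy.
#' @param m,r_factor Sample-entropy parameters.
#' @return data.frame with one row per window: `window`, `label`,
#'   `conn_entropy`, `samp_entropy`.
#' @export
state_entropy_summary <- function(ts, clustering, window_len = 50L,
                                  stride = window_len, n_bins = 10L,
                                  m = 2L, r_factor = 0.5) {
  ws <- make_windows(n_frames(ts), window_len, stride)
  if (length(ws$starts) != length(clustering$labels))
    stop("clustering labels do not align with the window scheme")
  rows <- lapply(seq_along(ws$starts), function(w) {
    seg <- ts$data[window_frames(ws, w), , drop = FALSE]
    C <- suppressWarnings(stats::cor(seg))
    ce <- mean(vapply(seq_len(ncol(C)), function(i)
      as.numeric(connectivity_entropy(C[i, -i], n_bins)), numeric(1)),
      na.rm = TRUE)
    se <- vapply(seq_len(ncol(seg)), function(i)
      as.numeric(sample_entropy(seg[, i], m, r_factor)), numeric(1))
    data.frame(window = w, label = clustering$labels[w], conn_entropy = ce,
               samp_entropy = mean(se[is.finite(se)]))
  })
  do.call(rbind, rows)
}
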