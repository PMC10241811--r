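# Shared fixtures and independent oracles for the suite.

# Best label-match accuracy over all k! label permutations (exact for the
# small k used in tests).
label_accuracy <- function(labels, truth) {
  k <- max(labels, truth)
  perms <- perms_of(seq_len(k))
  best <- 0
  for (p in perms) best <- max(best, mean(p[labels] == truth))
  best
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

# Brute-force Spearman: Pearson on average ranks.
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))

# Normalized rank in [0, 1].
norm_rank_test <- function(g) (rank(g) - 1) / (length(g) - 1)

# Continuously periodic wave run: frame t carries column (t mod L) of the
# template, plus tiny jitter so correlations are defined.
periodic_wave_ts <- function(template, n_frames, dt, jitter_sd = 1e-6,
                             seed = 5L) {
  tpl <- template$data
  L <- ncol(tpl)
  x <- t(tpl)[(seq_len(n_frames) - 1L) %% L + 1L, ]
  set.seed(seed)
  region_ts(x + jitter_sd * matrix(stats::rnorm(length(x)), nrow(x), ncol(x)),
            dt = dt)
}

# Per-window mean of a per-frame signal under a window scheme.
window_means <- function(v, ws) {
  vapply(seq_along(ws$starts), function(w) mean(v[window_frames_test(ws, w)]),
         numeric(1))
}
window_frames_test <- function(ws, w) ws$starts[w]:(ws$starts[w] + ws$window_len - 1L)
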