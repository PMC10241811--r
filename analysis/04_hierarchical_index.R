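#!/usr/bin/env Rscript
# Stage 4 -- hierarchical index and its dynamics.
#
# The scalar signature: Spearman correlation between each window's
# z-normalized SD map and the principal gradient. On the simulated
# vigilance ramp the 24-window trajectory should rise; the paired-t and
# interval-correlation maps should recapitulate the gradient.

suppressMessages(library(hierdyn))
ts <- read_region_ts("results/rest_run.tsv")
grad <- read_map("results/gradient.tsv")

traj <- hier_trajectory(ts, grad, window_len = 50, filter = FALSE)
utils::write.table(data.frame(window = seq_along(traj$rho) - 1L,
                              rho = traj$rho),
                   "results/hier_trajectory.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
tt <- trend_test(traj)
message(sprintf("%d-window trajectory: rho in [%.3f, %.3f]; trend r = %.3f, p = %.2g",
                length(traj$rho), min(traj$rho), max(traj$rho), tt$r, tt$p))

# windowed amplitude maps for the contrast constructions
ws <- make_windows(nrow(ts$data), 50)
amp <- t(vapply(seq_along(ws$starts), function(w) {
  seg <- ts$data[ws$starts[w]:(ws$starts[w] + 49), ]
  v <- apply(seg, 2, sd)
  (v - mean(v)) / sd(v)
}, numeric(ncol(ts$data))))

# vigilance-drift construction: all 276 window pairs against interval
ic <- interval_corr_map(amp)
write_map(stats::setNames(ic$stat, ts$region_ids),
          "results/interval_corr_map.tsv")
message(sprintf("interval map vs gradient: rho = %.3f over %d pairs",
                hier_index(ic$stat, grad), ic$n))

# two-condition contrast: first 6 vs last 6 windows as paired pseudo-subjects
pt <- paired_t_map(amp[19:24, ], amp[1:6, ])
message(sprintf("late-vs-early paired-t map vs gradient: rho = %.3f",
                hier_index(pt$stat, grad)))
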