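#!/usr/bin/env Rscript
# Stage 1 -- synthetic cohort.
#
# Generates the study's stand-in data: an HCP-like resting-state run whose
# per-region fluctuation amplitude is coupled to a slow vigilance ramp
# along a planted gradient, a sleep-stage-like trajectory, and an
# ECoG-like recording. Everything downstream reads these artifacts.

suppressMessages(library(hierdyn))
dir.create("results", showWarnings = FALSE)
set.seed(1)

spec <- synth_spec(n_regions = 200, n_frames = 1200, dt = 0.72,
                   beta = 1, sigma0 = 1, seed = 1)
sim <- simulate_rest(spec)
write_region_ts(sim$ts, "results/rest_run.tsv", meta = list(seed = 1))
write_map(stats::setNames(sim$truth$gradient, sim$ts$region_ids),
          "results/planted_gradient.tsv")
message(sprintf("simulated %d x %d run (%.0f s); state ramps 0 -> 1",
                nrow(sim$ts$data), ncol(sim$ts$data),
                nrow(sim$ts$data) * spec$dt))

stages <- simulate_stage_traj(1200, dwell_frames = 120, seed = 2)
utils::write.table(data.frame(frame = seq_along(stages) - 1L, stage = stages),
                   "results/stage_traj.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("stage trajectory visits levels: %s",
                paste(sort(unique(stages), decreasing = TRUE), collapse = ", ")))
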