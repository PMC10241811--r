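# hierdyn

Hierarchical dynamics of cortical fluctuation amplitude.

## The problem

Global states of consciousness — wakefulness, drowsiness, sleep, sedation —
reorganize *where* on the cortex spontaneous slow activity fluctuates most.
In vivid wakefulness, low-frequency (0.01–0.08 Hz) signal variability
concentrates in transmodal association cortex; as vigilance fades it shifts
toward unimodal sensory cortex. Because the unimodal→transmodal axis is
captured by the principal diffusion-map gradient of the functional
connectome, this spatial shift can be compressed into a single scalar:

> **hierarchical index** = Spearman ρ between the z-normalized per-region
> fluctuation-amplitude map and the principal connectome gradient
> *g* — ρ(rank SD*ᵢ*, rank *gᵢ*).

`hierdyn` implements this statistic and the analysis pipeline around it for
researchers in neuroimaging and systems neuroscience:

- **Amplitude maps** — zero-phase Butterworth bandpass (0.01–0.08 Hz),
  per-region SD, ALFF (`Σₖ √((aₖ² + bₖ²)/N)` over the low band), fALFF,
  z-normalization, nonoverlapping window schemes (1200 frames → 24 windows
  of 50).
- **Connectome gradients** — Pearson FC, row sparsification (0.9), cosine
  affinity, diffusion-map embedding (α = 0.5).
- **Index dynamics** — windowed trajectories, Pearson trend tests,
  paired-*t* and state/interval Spearman contrast maps (276 window pairs
  per 24-window run).
- **Spin tests** — Haar-uniform rotations on the sphere with
  nearest-neighbour reassignment (vertex) and parcel re-averaging,
  preserving spatial autocorrelation in map-vs-map significance tests.
- **Brain states** — global-signal topography per window, Euclidean k-means
  with silhouette-based model selection, centroid contrasts, node strength,
  normalized connectivity entropy (10 equal-width bins) and Richman–Moorman
  sample entropy (m = 2, r = 0.5·SD, Chebyshev distance).
- **Quasiperiodic patterns (QPP)** — sliding spatiotemporal template match,
  event detection at local maxima ≥ 0.4, recursive template building,
  phase alignment, low/high-hierarchy event traces, typical/atypical
  bifurcation at r = 0.5, within-event network FC.
- **Electrophysiology** — multitaper spectrogram (1 s window, 0.2 s step,
  5 DPSS tapers), dB + temporal-mean normalization, band-limited power
  (delta 1–4, alpha–beta 5–30, gamma 40–100 Hz), 0.01–0.08 Hz BLP
  filtering, gamma peak-difference and delta-tail event statistics.
- **Synthetic generator** — every input above with planted ground truth
  (gradient-coupled amplitude schedules, injectable wave events,
  stage trajectories, ECoG-like channels), so the whole pipeline is
  testable without restricted recordings.

## Worked example

Simulate an HCP-like run (200 regions, 1200 frames at 0.72 s) whose
amplitude allocation drifts up the planted gradient with a slow state ramp,
then recover the drift:

```r
library(hierdyn)

spec <- synth_spec(n_regions = 200, n_frames = 1200, dt = 0.72,
                   beta = 1, sigma0 = 1, seed = 1)
sim <- simulate_rest(spec)
sim$ts
#> region_ts: 1200 frames x 200 regions, dt = 0.72 s (864.0 s total)

traj <- hier_trajectory(sim$ts, sim$truth$gradient, window_len = 50,
                        filter = FALSE)   # generator output is band-limited
traj
#> hier_traj: 24 windows of 50 frames; rho range [-0.040, 0.552]
round(traj$rho[1:6], 3)
#> [1] -0.029 -0.040  0.145  0.114  0.123  0.230

trend_test(traj)[c("r", "p")]
#> $r: 0.921   $p: 1.8e-10
```

The 24 per-window values are hierarchical indices: near 0 while the planted
state is low (amplitude spatially unstructured), rising past 0.5 as
fluctuations concentrate in high-gradient regions; the trend test confirms
the drift (r = 0.921, p = 1.8e-10). The embedding side, on a connectome
with a known 1-D latent coordinate:

```r
sc <- make_structured_connectome(50, decay = 3)
emb <- diffusion_embedding(cosine_affinity(sparsify_rows(sc$C, 0.9)))
emb
#> gradient_map: 50 regions, 2 components; eigenvalues 0.989, 0.956
abs(cor(rank(emb$loadings[, 1]), rank(sc$p)))
#> [1] 1
```

The principal component orders all 50 nodes exactly along the latent
coordinate.

## Analysis workflow

`analysis/01_simulate.R` … `analysis/08_blp.R` are numbered drivers that
run the full story on synthetic data — simulation, amplitude maps,
gradient embedding, index dynamics, spin tests, state clustering with
entropies, QPP detection, and the ECoG band-limited-power path — each
writing small tables under `results/` and narrating what it found:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

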