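---
title: "Methods: hierarchical dynamics of cortical fluctuation amplitude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical dynamics of cortical fluctuation amplitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hierdyn)
```

This vignette is the package's own account of its models, conventions and
design choices. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` compute.

## The model

The object of study is the spatial allocation of slow cortical signal
variability and how it moves along the cortical processing hierarchy with
global state. Three ingredients define the pipeline:

1. **A per-region amplitude map.** The signal is restricted to the
   0.01–0.08 Hz band and summarized per region either by the sample SD
   over time or by ALFF, the summed Fourier amplitude
   $\sum_{k: f_k \in [0.01, 0.08]} \sqrt{(a_k^2 + b_k^2)/N}$ under the
   real-DFT convention fixed below. By Parseval's theorem the two are
   analogous: on band-limited signals that differ by amplitude scaling
   they are proportional and rank regions identically. With heterogeneous
   spectra the agreement is near- but not exactly perfect, because ALFF
   sums per-bin amplitudes rather than the RMS; the tests assert exact
   rank identity only on amplitude-scaled common-spectrum fixtures and
   near-identity (ρ > 0.999) otherwise.
2. **A hierarchy reference.** The principal diffusion-map component of the
   functional connectome, or any externally supplied per-region map
   (a group-template gradient). Computed and supplied references are
   treated identically.
3. **The hierarchical index.** Spearman correlation (average-rank ties)
   between the z-normalized amplitude map and the reference. Because it is
   a rank statistic it is invariant to monotone transforms of either map;
   z-normalization matters only for the map artifacts, not the index.

Windowed over a run (50-frame nonoverlapping windows by default; a 1200
frame run yields 24), the index becomes a trajectory whose drift is
assessed by a Pearson trend test against window order, with the two-sided
$t = r\sqrt{(n-2)/(1-r^2)}$ p-value.

## Conventions that change numbers

These are fixed once, and the tests pin them:

- **Filter.** Butterworth bandpass of polynomial order 4 (`signal::butter`
  with n = 2), applied forward–backward (`signal::filtfilt`) for zero
  phase. Exact double-filter idempotence is impossible for any Butterworth
  (the squared response attenuates band edges); the invariant actually
  guaranteed, and tested, is second-pass gain within 5% at mid-band.
  Forward–backward transients extend roughly one period of the low edge
  (~100 s at 0.01 Hz) into each end of a record, which is why already
  band-limited input should be windowed without refiltering
  (`hier_trajectory(..., filter = FALSE)`).
- **Fourier convention.** Demean, then real DFT with
  $a_k = (2/N)\sum x\cos(2\pi f_k t)$, $b_k = (2/N)\sum x\sin(2\pi f_k t)$
  for $0 < f_k < $ Nyquist; DC and Nyquist excluded. A unit-amplitude
  in-band sinusoid then contributes $1/\sqrt{N}$ to ALFF.
- **SD and z-normalization** use the sample (N−1) denominator.
- **Windows** are consecutive, in-bounds, remainder frames dropped at the
  run end; the R API is 1-based while on-disk artifacts (window starts,
  event onsets) are 0-based half-open, converted by the io layer.
- **Embedding.** Row sparsification keeps the top `ceiling((1-s)(n-1))`
  entries per row then symmetrizes by `(S + t(S))/2`; cosine affinities
  are clipped at 0 so the random-walk kernel stays nonnegative; the
  density-normalized kernel uses α = 0.5; components are eigenvectors of
  the row-stochastic transition matrix scaled by their eigenvalues
  (diffusion time 0), trivial constant component excluded. Eigenvector
  sign is arbitrary and resolved against a reference (`align_sign`).
- **Spin tests.** Only the first map is rotated; nearest-neighbour
  reassignment by greatest dot product with lowest-index tie-break;
  two-sided p by absolute value with the add-one convention, so p is
  never 0. Test geometry is a Fibonacci lattice, so no surface files are
  needed. Rotation index maps depend only on the geometry and can be
  precomputed (`spin_rotation_maps`) and shared across tests on the same
  sphere — the rotations are independent of any map, so validity per test
  is unaffected.
- **Entropies.** Connectivity entropy bins a node's FC profile into 10
  equal-width bins spanning its observed range (this range convention
  changes H and is therefore fixed explicitly), normalized by log(10),
  with 0·log 0 = 0; it is invariant to affine rescaling of the profile.
  Sample entropy follows the Richman–Moorman convention: overlapping
  templates, self-matches excluded, template starts 1..N−m for both
  lengths, Chebyshev distance ≤ r with r = 0.5·SD; `-log(A/B)` with
  degenerate cases (A or B zero) flagged rather than silently propagated.
  A strictly monotone ramp such as 1..6 has no matching template pair at
  these parameters, so its entropy is undefined — the tests assert this.
- **QPP.** Flattening is region-major (irrelevant to Pearson r, fixed for
  reproducible artifacts); no wrap-around matching; events are local
  maxima ≥ 0.4 with plateaus resolved to their leftmost frame and maxima
  closer than the template length suppressed in favor of the higher match;
  template building restarts from 20 random segments, converges when the
  event set repeats, and returns the candidate with the highest summed
  event correlation. The typical/atypical split uses r ≥ 0.5, boundary
  inclusive. `phase_align` treats "rolled by +s" as delayed by s frames;
  ties prefer the smaller |shift|, then the negative one.
- **Spectrogram.** DPSS tapers from the symmetric tridiagonal
  formulation with NW = 3 and 5 tapers (the time–bandwidth at which
  exactly 5 tapers are well concentrated); 1 s windows and 0.2 s steps;
  per-window demeaning; power aggregated into 1 Hz bins over 1–100 Hz. A
  pure tone is therefore spread over ±3 Hz by design — concentration is
  asserted within the taper bandwidth, not at a single bin. dB conversion
  floors power at 1e−12 of the maximum, which makes the
  normalized spectrogram exactly invariant to a global gain; per-channel,
  per-frequency temporal means are removed. Band averages are taken on
  the normalized dB spectrogram.

## The synthetic generator

No generative model is claimed for the brain; the generator is a fixture
that plants exactly the structure the analyzers are supposed to recover:

$$x_i(t) = [\sigma_0 + \beta\,\mathrm{rank}(g_i)\,s(t)]\,\eta_i(t)
         + w_i(s(t))\,G(t) + \varepsilon_i(t)$$

with band-limited unit-variance noises $\eta_i$ and shared component $G$
produced by the *same* zero-phase filter the analyzers use (so generator
and analyzer agree about the band), normalized gradient ranks in [0, 1]
(the index is a rank correlation, so coupling in rank space makes ground
truth interpretable), and global-component weights interpolating
`gs_weight_low → gs_weight_high` with rank × state. Defaults mirror the
study's data shape: 200 regions, 1200 frames at dt = 0.72 s, σ₀ = 1,
β = 1, white-noise SD 0.1, a 0→1 state ramp, and all RNG through one seed.
ECoG channels are a 50–70 Hz noise carrier whose slow envelope is
1 + couple · rank · mod(t), plus a 2 Hz oscillation and white noise, at
fs ≥ 250 Hz. Wave events are one sinusoid cycle whose phase lags linearly
with gradient rank (a quarter cycle across the hierarchy by default) over
30 frames — analytically checkable, and matching the idea of activity
propagating up the gradient. Stage trajectories are piecewise-constant
neighbour walks over the levels 0/−1/−2/−3 with dwell between one and two
`dwell_frames`.

What the generator does **not** emulate: hemodynamics, anatomical
geometry, physiological confounds (cardiac/respiratory), head motion,
inter-subject variability. Passing tests therefore show that the
*computations* recover planted structure at realistic sizes and
signal-to-noise; they do not validate the neuroscientific claims on real
recordings.

## Problem sizes and numerical choices

The suite and acceptance script run at sizes chosen to make the
statistical assertions sharp while staying desk-scale: planted-state
recovery at 200 regions × 2000 frames (r > 0.9 against the window-mean
state); trend-test size at 1000 replicates of a 50-region, 600-frame null
(rejection in [0.03, 0.07]); spin-test size at 500 smoothed-noise map
pairs on a 1000-vertex sphere with 500 rotations each (one shared
precomputed rotation set); QPP recovery with 20 events injected into
200 × 2000 noise at gain/noise = 2 (precision and recall ≥ 0.9, onsets
within one frame); embedding checked against a direct eigendecomposition
on a 50-node structured connectome to 1e−8; entropies against brute-force
oracles to 1e−12; BLP envelope recovery on a 300 s, 400 Hz recording with
a 0.04 Hz amplitude modulation (r > 0.9).

Degenerate inputs are flagged, not fatal mid-pipeline: constant maps give
`NA` indices with a warning, constant FC profiles give zero connectivity
entropy with a `degenerate` attribute, zero-variance regions propagate
`NA` through `fc_matrix`, and disconnected affinity graphs are refused
with the component sizes named.

## Open choices made here

- k-means runs on raw topography vectors (50 seeded restarts), not on the
  window×window similarity matrix; the similarity matrix is a diagnostic,
  not the clustering space.
- The interval-correlation map pools all window-pair amplitude differences
  with equal weight against the pair interval.
- Among template-building candidates from different random starts, the
  one with the highest summed super-threshold correlation wins.
- The gamma "peak difference" is the difference of per-trace maxima within
  the initial 12 s (`mode = "diff_of_max"`), with `max_of_diff` available,
  since the wording admits both readings; the subsequent 4 s of delta
  power are averaged across all channels.
- A 50 Hz notch for line noise is available upstream of the spectrogram in
  principle but is off by default, since the synthetic inputs contain no
  mains component.

## Known limitations

- The embedding targets parcel-scale (≤ a few thousand nodes) dense
  matrices; no sparse eigensolvers, so grayordinate-scale (91k) embedding
  is out of reach by design.
- Spin tests assume an isotropic spherical projection; no medial-wall
  masking is implemented beyond the nearest-donor rule stated in the io
  conventions.
- `build_template` is a local search; on data without recurring structure
  it correctly errors rather than returning a spurious template, but with
  low thresholds it can converge to different fixed points from different
  seeds — the summed-correlation selection rule is a heuristic.
- Sample entropy is O(N²) in the series length; windows of ≤ a few
  hundred frames are the intended regime.
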