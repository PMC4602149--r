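---
title: "Functional typing of retinal ganglion cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional typing of retinal ganglion cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgctyper)
```

## What this package computes

Retinal ganglion cells (RGCs) are the retina's output neurons; a piece of
retina contains a few dozen functional types that differ in response
polarity (ON, OFF, ON-OFF), kinetics (brisk/sluggish, transient/sustained),
receptive-field size, and motion preferences (direction and speed
selectivity). `rgctyper` implements a complete functional-typing workflow
for RGC spike trains recorded on a high-density microelectrode array
(17.5 µm pitch, 126 simultaneously recorded electrodes):

1. **Stimulus protocols** (`stim_marching_square()`, `stim_narrow_bars()`,
   `stim_width_test()`, `stim_speed_test()`): timed event tables for a
   flashing-square receptive-field mapping grid and three moving-bar
   tunings.
2. **A synthetic retina** (`sample_population()`, `drive_cell()`,
   `spikes_from_rate()`, `render_traces()`): model cells with known ground
   truth, driven by the same protocols, emitting inhomogeneous-Poisson
   spike trains and, optionally, 20 kHz extracellular voltage traces.
3. **Spike sorting** (`sort_spikes()` and its stages): 300 Hz–8 kHz
   band-pass, 3.5 σ robust threshold detection, PCA + Gaussian-mixture
   demixing on seven-electrode groups, spike-triggered-average (STA)
   templates, normalized least-squares template matching, and duplicate
   merging with a 1% refractory-violation budget.
4. **Seven response parameters** (`extract_parameters()`): ON-OFF bias
   index, latency, transience, receptive-field diameter, DS index,
   preferred-speed and preferred-width indices, plus responsiveness flags.
5. **Cell typing** (`cluster_cells()`): k-means swept over k = 4…25 with
   the mean silhouette selecting k, validated by pairwise Fisher
   separation, receptive-field tiling and direction-preference polar
   diagnostics.

Because no public recordings accompany the workflow, every stage is
validated end to end on synthetic populations whose generating parameters
are known exactly.

## The response indices

For spike counts `ON` and `OFF` in the bright and dark phases of a square
flash, the bias index is

$$BI = \frac{ON - OFF}{ON + OFF} \in [-1, 1],$$

+1 for a pure ON cell, −1 for pure OFF, 0 for balanced ON-OFF. **Latency**
is the time from stimulus onset to the peak of the PSTH after smoothing
with a centred 25 ms boxcar over 5 ms bins (ties resolve to the earliest
bin). **Transience** peak-normalizes the 1.5 s PSTH, integrates it and
divides by 1.5, so a response sustained over the whole window scores 1.
The **receptive-field diameter** comes from the 9 × 9 map of mean spike
counts per square location: the map is upsampled 9× per axis (bilinear),
thresholded at 33% of its maximum, the supra-threshold pixel fraction is
scaled to the mapped area $A$, and $d = \sqrt{4A/\pi}$. The **DS index**
is the vector average over eight directions,
$D = |\sum_i r_i\,\hat u(\theta_i)| / \sum_i r_i$, and the **preferred
speed/width indices** are response-weighted means of the tested condition
values normalized by the maximum tested value.

Two measurement conventions matter and are applied uniformly:

* **Baseline correction.** Every response measure subtracts the
  background rate estimated from the inter-stimulus background intervals
  (known exactly in noiseless mode). Without it the boundary values above
  are unattainable for any spontaneously active cell — a uniform baseline
  drags `BI` toward 0 and dilutes the DS index.
* **Settle windows.** Moving-bar rate and peak windows run from bar entry
  to the end of the post-traversal background interval. Bar protocols use
  a 1.0 s inter-event interval (squares use 0.5 s) so that a sluggish
  cell's trailing-edge (OFF) response is fully counted even when the bar
  exits the field just before the response begins; with a shorter window
  the truncation is direction-dependent and masquerades as direction
  selectivity.

Cells that fail to respond to any of the four protocols are discarded
(`responsiveness_filter()`). The decision is an exact Poisson test of the
window counts against the background expectation, Bonferroni-corrected
across windows and combined with a pooled whole-protocol test at
α = 0.001. A plain "peak rate > baseline + 3 SD" rule was rejected: the
maximum of ~10⁵ smoothed bins virtually always exceeds it, so a
baseline-only cell would never be discarded.

## The generative model

Each synthetic cell's firing rate is

$$\lambda(t) = b + r_{peak} \cdot G_{spatial} \cdot K(t - t_{drive})
  \cdot S(v) \cdot W(w) \cdot D(\theta),$$

with one kernel term per driving stimulus transition: ON cells fire at
positive-contrast transitions (square onset, bright-bar leading edge,
dark-bar trailing edge), OFF cells at the opposite ones, ON-OFF cells at
both with a 1.1:1 ON-dominant gain so the larger-peak polarity rule is
deterministic.

* $G_{spatial}$ — overlap of the stimulus footprint with an isotropic
  Gaussian receptive field. The Gaussian SD is **calibrated against the
  diameter estimator itself**: the 100 µm mapping square convolves the
  response map with its footprint and the bilinear upsampling widens
  narrow peaks, so the SD producing a measured 33%-contour diameter equal
  to the nominal one is found numerically (phase-averaged over grid
  offsets) and inverted through a monotone spline. A closed-form
  $\sigma = d / (2\sqrt{2\ln 3})$ is exact only for an unsmoothed
  Gaussian and under-sizes small fields.
* $K$ — a peak-normalized temporal kernel
  $(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$ with a fixed 20 ms rise. The decay
  $\tau_d$ is **calibrated by root-finding** so that the transience index
  measured on a noiseless flashing-square PSTH equals the archetype's
  target, including, for ON-OFF cells, the partial OFF lobe that enters
  the 1.5 s window. An alpha kernel was tried first and rejected: its
  measured transience plateaus near 0.65 for sluggish latencies, so
  sustained targets are unreachable.
* $S, W$ — log-Gaussian speed and width tunings (bandwidths 0.7 and 1.2
  log-units). The broader width tuning keeps the 1000 µm
  direction-selectivity bar from being over-penalized relative to the
  robust bar responses real recordings show.
* $D$ — a von Mises-shaped direction gain $e^{\kappa(\cos\Delta - 1)}$
  for DS cells. κ = 1.5 yields a noiseless DS index of ≈ 0.60 over eight
  directions, essentially independent of where the preferred direction
  falls relative to the direction grid.

Spikes are inhomogeneous Poisson: the baseline is sampled homogeneously
and each kernel component is thinned against its own peak rate; the
superposition realizes λ(t) exactly. A 2 ms absolute refractory period is
applied by deletion.

### Default archetypes

`rgc_archetypes()` ships seven rows — OFF brisk transient, OFF sluggish
transient, ON-OFF brisk transient, ON-OFF sluggish sustained, ON-OFF DS,
ON brisk transient, ON DS — with latency means 0.12 s (brisk) / 0.30 s
(sluggish), transience targets 0.15 (transient) / 0.25 (sustained),
RF diameter 270 ± 60 µm, peak rate 60 Hz over a 0.2 Hz baseline, and
per-archetype preferred speeds (300–900 µm/s) that spread the speed
index. These are artifacts of this package for recovery and
property-based testing, not measured values. The sustained target is
deliberately moderate: with 1 s ON and OFF phases, a response whose decay
approaches the phase length leaks across the polarity windows, and above
a measured transience of ≈ 0.3 the leak alone pushes a balanced ON-OFF
cell's bias index past ±0.1. Reported transience durations for real
sustained cells (∼0.45 on this index at most) are consistent with staying
below that regime.

```{r archetypes}
rgc_archetypes()[, 1:8]
```

## What the synthetic data does and does not emulate

The generator reproduces the *measured-parameter structure* of RGC
responses: polarity gating, Gaussian receptive fields at the recorded
scale, kernel-shaped PSTHs with controlled latency/transience, von Mises
direction tuning, log-Gaussian speed/width tuning, Poisson spiking with
refractoriness, and (for the sorting stages) biphasic extracellular
waveforms with exponential spatial decay over a 17.5 µm-pitch grid with
2.4 µV RMS noise. It does **not** model photoreceptor/bipolar circuitry,
adaptation, serial correlations, correlated noise across cells,
electrode drift, or overlapping-spike waveform superposition beyond
linear addition. Passing tests therefore demonstrate that the estimators
and the clustering recover a known generative structure at realistic
scales and rates — not that they would be unbiased on any real retina.

## Numerical and algorithmic choices

* **PSTHs**: 5 ms bins; smoothing = centred 25 ms boxcar with partial
  windows at the edges; latency is quantized to the bin grid.
* **Diameter estimator reliability**: with a 100 µm mapping grid the
  33%-contour estimator's phase scatter grows quickly below ≈ 240 µm
  nominal diameter; recovery tests therefore assess each archetype at its
  mean diameter, with positions (and DS preferred directions) random.
* **Spike sorting**: detection threshold 3.5 × robust SD
  (median |x| / 0.6745), 1 ms dead time, plus afterpotential
  suppression — a trough reaching at most 35% of a deeper trough's
  amplitude within the preceding 2 ms on the same electrode is the
  band-pass filter's undershoot of that spike, not a new event.
  Electrode groups = centre + six nearest; mixture components chosen by
  BIC in 1…5 with a bounded EM iteration budget (the library default is
  effectively unbounded and can cycle on ill-conditioned groups);
  clustering runs on an evenly thinned subsample above 500 events with
  the fit classifying the rest. Templates are STAs realigned on the
  strongest electrode's negative peak (detection-sample jitter on weak
  electrodes otherwise smears the average); the template footprint keeps
  electrodes above 25% of the peak-to-peak maximum — a permissive floor
  would dilute the matching score of small cells with noise-only
  channels. Duplicate candidate templates (r > 0.90, peak-aligned) keep
  the sharpest representative: partially misaligned clusters produce
  amplitude-diluted variants of the same unit. Matching accepts
  1 − RSS/TSS ≥ 0.6 maximized over ±0.25 ms lags; when several
  templates claim the same event within 1 ms, the one explaining the
  most residual energy (TSS − RSS) wins — the score alone is scale-free,
  so a small artifact template can score as well as the true large one.
  Templates below 7 robust SDs peak-to-peak are discarded (noise-built
  STAs reach ≈ 4.5 σ); duplicates merge at Pearson r > 0.90 subject to
  the merged train keeping ≤ 1% of intervals under 2 ms. At a 3.5 σ
  threshold the false-detection rate on noise alone is ∼10
  events/s/electrode — the Rice level-crossing rate for the
  300 Hz–8 kHz band — which is why the template stages, not detection,
  provide the selectivity.
* **Clustering**: the five canonical parameters (bias, latency,
  transience, DS, speed); latency min–max scaled, intrinsic-range columns
  passed through. k-means uses sequential single-start calls so a longer
  restart budget strictly extends a shorter one under the same seed;
  silhouette ties resolve to the smallest k; singleton clusters score 0.
  Restart budgets matter: with only ~25 restarts the sweep can miss the
  global optimum at the true k and hand the selection to a worse k.
* **Fisher separation**: group SDs are sample moments of the projections
  onto the inter-mean axis (deterministic and bin-free, rather than a
  histogram Gaussian fit); separation = distance between means divided by
  the average SD; a zero-SD pair reports a 10⁶ sentinel.
* **Polar diagnostics**: von Mises kernel density (20° bandwidth), modes
  = circular local maxima above half the peak; a density whose minimum
  stays above that threshold is flagged inconclusive.

## Problem sizes used in the shipped tests

Unit tests run on single cells or populations of ≤ 25 cells/archetype and
on 10–20 s trace blocks. The full-scale checks use the study conditions
the pipeline is designed for: cluster-number recovery on 280 cells
(40 per archetype, 20 seeded replicates, 200 restarts per k), and spike
sorting on a 126-electrode, 60 s block with 12 embedded cells at the
default 50–300 µV amplitudes over 2.4 µV noise.

## Known limitations

* Diameter estimates below ≈ 2.4 grid spacings are imprecise by
  construction of the mapping stimulus.
* Latency resolution is one PSTH bin (5 ms).
* In spike (non-noiseless) mode the DS index of weakly responding cells
  is noisy — single-trial bar windows contain only a handful of driven
  spikes at realistic rates.
* The sorter resolves overlapping spikes only by best-score-first
  exclusion; simultaneous spikes of nearby cells can shadow each other.
* Bars travel a fixed-length path equal to the larger field dimension,
  so for diagonal directions the extreme field corners are not swept;
  receptive fields sit well inside the field and are unaffected.
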