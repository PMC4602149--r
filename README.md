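# rgctyper

Functional classification of retinal ganglion cells (RGCs) from
multi-electrode spike trains.

A piece of retina contains a few dozen functional RGC types — ON, OFF and
ON-OFF cells; brisk and sluggish, transient and sustained kinetics;
direction- and speed-selective subtypes — and high-density microelectrode
arrays (HD-MEAs, 17.5 µm pitch, 126 electrodes recorded simultaneously)
make it possible to type dozens of cells per preparation in a single
session. `rgctyper` implements that workflow end to end for
electrophysiologists and methods developers:

* **Stimulus protocols** as timed event tables: a flashing-square
  receptive-field mapping grid (81 locations × 5 repetitions), narrow
  moving bars in 8 directions × 3 lateral offsets, and width and speed
  tuning tests (80 and 96 presentations).
* **A synthetic retina** with known ground truth: model cells with
  polarity gating, Gaussian receptive fields, calibrated latency and
  transience kernels, von Mises direction tuning and log-Gaussian
  speed/width tuning, spiking as an inhomogeneous Poisson process — plus
  an extracellular trace renderer (20 kHz, 2.4 µV RMS noise) for the
  sorting stages.
* **Spike sorting**: 300 Hz–8 kHz zero-phase band-pass, 3.5 σ robust
  threshold detection, PCA + Gaussian-mixture demixing on
  seven-electrode groups, spike-triggered-average templates, normalized
  least-squares template matching, and duplicate merging under a 1%
  refractory-violation budget.
* **Seven response parameters** per cell, with the field's standard
  definitions:
  - bias index `BI = (ON − OFF)/(ON + OFF)` ∈ [−1, 1]
  - latency: time to the peak of the 25 ms-smoothed PSTH
  - transience: peak-normalized PSTH integral over 1.5 s, divided by 1.5
  - receptive-field diameter `d = √(4A/π)` from the 33%-of-maximum
    contour of the 9×-upsampled response map
  - direction-selectivity index `D = |Σ rᵢ û(θᵢ)| / Σ rᵢ`
  - preferred speed and width indices (response-weighted mean condition,
    normalized by the maximum tested value)
* **Cell typing**: k-means swept over k = 4…25 with the mean silhouette
  `Sᵢ = (bᵢ − aᵢ)/max(aᵢ, bᵢ)` selecting k, validated by pairwise
  Fisher separation (distance between cluster means over the mean
  projection SD), receptive-field tiling and direction-preference polar
  diagnostics.

Everything runs on synthetic data with known generating parameters, so
estimator correctness and cluster recovery are tested quantitatively; the
same functions accept any spike table (`cell_id`, `protocol`, `time_s`)
plus stimulus event logs.

## Worked example

Simulate the default seven-archetype population, extract the parameters
from noiseless expected responses, and cluster:

```r
library(rgctyper)
protocols  <- stimulus_protocols(seed = 1)
pop        <- sample_population(n_per_archetype = 10, seed = 1)
params     <- expected_parameters(pop, protocols)
responsive <- responsiveness_filter(params)
model      <- cluster_cells(responsive, k_range = 4:12,
                            restarts = 100, seed = 1)
model
#> <rgc_clusters> k = 7 (mean silhouette 0.904) over 70 cells, 100 restarts

dplyr::select(group_characteristics(responsive, model$labels),
              cluster, n, bias_index, latency_s, transience, ds_index,
              suggested_label)
#> # A tibble: 7 × 7
#>   cluster     n bias_index latency_s transience    ds_index suggested_label
#> 1       1    10     0.989      0.126      0.150 0.00000486  ON brisk transient
#> 2       2    10    -1.000      0.126      0.150 0.000664    OFF brisk transient
#> 3       3    10     0.933      0.210      0.200 0.600       ON DS sluggish sust…
#> 4       4    10    -1.000      0.303      0.150 0.00178     OFF sluggish transi…
#> 5       5    10     0.0476     0.119      0.150 0.000000545 ON-OFF brisk transi…
#> 6       6    10     0.0390     0.307      0.249 0.000757    ON-OFF sluggish sus…
#> 7       7    10     0.0474     0.140      0.200 0.604       ON-OFF DS brisk sus…

sep <- separation_matrix(model$data, model$labels)
min(sep[upper.tri(sep)])
#> [1] 16.92
```

The silhouette sweep selects k = 7 — one cluster per generating
archetype — and the group means read back the generating parameters: pure
ON/OFF clusters at bias ±1, balanced ON-OFF clusters near 0, the two DS
clusters at a DS index of 0.60, brisk (0.12 s) versus sluggish (0.30 s)
latencies, and transient (0.15) versus sustained (0.25) transience. The
smallest pairwise separation coefficient, 16.9 standard deviations, says
every cluster pair is cleanly separable. `autoplot(model)` draws the
silhouette-versus-k profile; `tidy()`, `glance()` and `augment()` give
broom-style summaries.

`run_pipeline(pipeline_config(...))` wraps the same chain (including
Poisson spike simulation instead of noiseless expectations) with a seeded
manifest and CSV/TSV/JSON artifacts; `sort_spikes()` and
`select_configuration()` cover the trace-level stages on rendered
voltage blocks.

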