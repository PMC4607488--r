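---
title: "Dynamic phase-synchronization micro-states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic phase-synchronization micro-states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynsync)
```

## The problem

Resting-state fMRI coupling between large-scale intrinsic connectivity
networks (ICNs) is not stationary: over a scan, the pattern of inter-network
synchrony wanders through a small repertoire of recurring configurations
("micro-states"). `dynsync` implements a complete pipeline for
characterizing that repertoire from ICN time courses and for contrasting it
between two scan conditions — conventionally eyes-open (EO) versus
eyes-closed (EC) resting state:

1. instantaneous phase and amplitude of each ICN time course via the
   analytic signal;
2. sliding-window mean phase coherence (dPS) between every ICN pair and
   windowed mean amplitude (dAMP) of every ICN;
3. motion censoring by framewise displacement (FD) and DVARS;
4. Ward hierarchical clustering of the windowed synchrony patterns into
   micro-states, with the number of states chosen by repeated
   Gaussian-mixture fits;
5. state-wise EO/EC statistics: Welch t-tests with Benjamini–Hochberg FDR
   for the dPS/dAMP features, and Fisher r-to-z contrasts for
   amplitude–synchrony coupling;
6. per-window graph metrics (node strength, thresholded global efficiency)
   and a window-length robustness harness.

A synthetic-data generator with planted ground truth makes every stage
testable without imaging data.

## Core quantities

For a time course $s(t)$, the analytic signal $s(t) + i\,\hat s(t)$ (with
$\hat s$ the Hilbert transform, computed here by the frequency-domain
multiplier on the full-length series) yields the instantaneous phase
$\phi(t)$ and amplitude $A(t)$. A window with parameter $m$ starting at
sample $i$ covers samples $i..i+m$ inclusive — $m+1$ samples. For two ICNs
with phases $\phi_1,\phi_2$ and $\hat\phi = \phi_1 - \phi_2$,

$$\mathrm{dPS}_i \;=\; \sqrt{\Big[\tfrac{1}{m+1}\!\!\sum_{t=i}^{i+m}\!\cos\hat\phi(t)\Big]^2
 + \Big[\tfrac{1}{m+1}\!\!\sum_{t=i}^{i+m}\!\sin\hat\phi(t)\Big]^2},
 \qquad
 \mathrm{dAMP}_i \;=\; \tfrac{1}{m+1}\!\!\sum_{t=i}^{i+m} A(t).$$

dPS is the resultant length of the windowed phase differences: 1 for
perfect locking, and for independent (iid uniform) phases it concentrates
near the finite-sample baseline $\sqrt{\pi}/(2\sqrt{m+1})$ — about 0.185
for the default $m = 22$, not 0. The normalization by $m+1$ (the number of
summed samples) keeps dPS in $[0,1]$. With the default $m = 22$, step 1 and
TR = 2 s, a window spans 44 s and a 235-sample session yields 213 windows.

Node strength of an ICN in a window is the mean dPS of that ICN to the
other $K-1$ ICNs; node amplitude is its dAMP.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window_m` | 22 | samples | window span is `m + 1` samples (44 s at TR 2 s) |
| `step` | 1 | samples | window advance |
| `band` | 0.01–0.08 | Hz | temporal pass band (zero-phase Butterworth) |
| `fd_thresh` | 0.5 | mm | FD censoring threshold |
| `tau` | 0.5 | – | synchrony threshold for graph binarization |
| `alpha` | 0.001 | – | significance level on FDR-adjusted q-values |
| `draw_size`, `n_sims` | 200, 1000 | – | Gaussian-mixture cluster-number detection |
| `window_sweep` | 13..40 by 3 | samples | robustness harness |

The band-pass is implemented forward–backward (zero phase) because any
filter phase lag would bias the downstream instantaneous-phase estimates.
Phases are stored wrapped and every dPS computation uses cosines and sines
of differences, so phase unwrapping never enters.

## Micro-state discovery

Retained windows of all sessions are concatenated into an $N \times 45$
matrix of vectorized upper-triangle dPS values (row-major pair order;
amplitudes travel alongside as aligned metadata but do not enter the
clustering). Agglomerative clustering uses Euclidean distance with Ward's
variance-minimizing criterion (`hclust` method `ward.D2`); the tree is cut
at `k` clusters. `k` can be fixed or detected: repeatedly draw 200
instances, fit Gaussian mixtures with 1–9 components over spherical,
diagonal and full covariance families, select the component count by BIC,
and take the mode of the per-draw optima (the median is reported
alongside; the two coincide in every configuration we exercise, and the
mode matches the histogram-peak reading of the repeated-draw procedure).

State summaries are within-state means: a $10 \times 10$ centroid synchrony
matrix with unit diagonal, a 10-vector amplitude profile, and per-condition
occupancy percentages. Centroids can be sparsified at `tau = 0.5` for
display. Models fitted under different window lengths are compared by
optimally pairing states (exact assignment maximizing summed centroid
correlations) — the robustness harness reports the matched-state
correlation per window length in 13..40 samples against the 22-sample
reference.

## Condition statistics and their assumptions

Within each state, EC and EO instances are compared per feature with
Welch's t-test; BH-FDR is applied within each state separately for the
45-pair synchrony family and the 10-ICN amplitude family (the joint-versus
per-family choice is configurable; per-family is the default). The
amplitude–synchrony analyses correlate a reference ICN's dAMP with node
strength (or with each pair's dPS) within state and condition, and contrast
conditions with the Fisher r-to-z statistic
$Z = (z_1 - z_2)\big/\sqrt{1/(n_1-3) + 1/(n_2-3)}$, two-sided normal p.

These formulas treat windows as independent observations. With step-1
windows that assumption is mechanically violated — consecutive windows
share $m/(m+1)$ of their samples, and window statistics co-move — which
makes instance-level tests anticonservative regardless of the data source.
The package documents rather than corrects this (no subject-level random
effects are fitted), and its own validation experiments therefore test the
statistical machinery on disjoint windows (step $\ge m+1$), where the
synthetic generator delivers exactly or approximately independent
instances. Interpret step-1 significance maps accordingly.

## The synthetic cohort generator

`synthetic_spec()` / `generate_cohort()` emulate the data structure the
analysis assumes: per subject, one EO and one EC session of 10 band-limited
ICN time courses (240 volumes, TR 2 s), plus 6-parameter motion traces.
The planted structure:

- **Micro-states** are partitions of the 10 ICNs into synchrony groups
  (defaults: global synchrony; fully dys-synchronized; two bipartitions
  that differ from each other in most pairs). The state sequence is a
  uniform random walk without immediate repeats over fixed dwell blocks
  (default 60 samples), so dwell always exceeds the window span and
  window-majority labels are unambiguous.
- **Phases.** Each group gets a block-wise constant frequency plus a slow
  shared drift (0.15 rad/sample) and a fresh uniform offset per block;
  ICN-level phase noise is wrapped-normal with concentration
  $\kappa$ (default 20), the single knob mapping monotonically to
  within-group dPS ($\approx e^{-1/\kappa}$). Group frequencies are drawn
  *stratified* across the 0.01–0.08 Hz band — one jittered sub-band per
  group, assigned at random — because two independent narrowband
  oscillators that happen to draw nearly equal frequencies are genuinely
  indistinguishable from a phase-locked pair over a 44-s window; the
  stratification guarantees the planted asynchrony is identifiable at the
  window scale while every frequency stays inside the band.
- **Amplitudes** follow a per-state profile times a per-condition factor
  (default: EC multiplies SMN and AN by 1.5). Observation noise is white
  with sd equal to the planted envelope over `noise_snr` (default 10), so
  condition effects live in the envelope, not in the noise floor, and
  windowed amplitude estimates track planted envelopes within about 5%
  away from state switches.
- **Motion** is smooth sub-threshold sinusoidal drift plus step
  displacements of 0.7–1.2 mm at Poisson-planted spike samples, which FD
  flags exactly at the spikes.

What the generator does *not* emulate: hemodynamic response convolution,
voxel-level physics, spatially correlated noise, subject-level variability
in state structure or coupling strength, and scanner drifts. Passing tests
on this generator therefore demonstrate that the machinery recovers the
structure it assumes, not that real EO/EC effects of any particular size
are detectable in a given dataset.

## Numerical and design choices

- Window span is inclusive, `i..i+m`, matching the summation limits of the
  windowed statistics; only this convention reproduces 213 windows from 235
  samples at `m = 22`.
- The Hilbert transform is computed once on the full series, then windowed;
  no edge trimming is applied by default (tests assert properties away from
  the first/last samples).
- Quartiles for the DVARS boxplot rule use the linear-interpolation
  convention (type 7); DVARS is normalized by its median (robust to the
  spikes being detected) and computed per session.
- FD converts rotations to arc length at a 50 mm head radius; marks are
  dilated ±1 sample; a window survives only if none of its samples is
  marked. Censoring runs per session before concatenation.
- Ward clustering uses the squared-Euclidean merge cost (`ward.D2`);
  agglomeration ties are broken by lowest pair index (relevant only for
  degenerate duplicated instances). Global efficiency uses the binarized
  (`tau = 0.5`) graph with unit edge lengths, disconnected pairs
  contributing 0; a weighted variant is a one-line change but the
  thresholded form is the default.
- Degenerate inputs are explicit: constant series are rejected by
  `analytic_signal()`, zero-variance features by `detect_cluster_number()`,
  constant reference amplitudes yield flagged-untested correlation cells,
  fully censored sessions contribute zero rows with a warning, and an
  all-censored cohort aborts the pipeline.
- One global seed fans out deterministically to per-stage seeds; library
  code saves and restores the caller's RNG state.

## Problem sizes used in the validation suite

The packaged experiments run at deliberately modest sizes chosen as the
package's own validation conditions: the default recovery cohort is 10
subjects × 2 conditions × 240 volumes with 4 planted states and
$\kappa = 20$; clustering recovery is asserted at adjusted Rand index
≥ 0.8 on step-1 windows; planted 1.5× amplitude effects must be flagged at
q < 0.001 with correct direction on disjoint windows while zero-effect
features stay silent. Fisher r-to-z calibration uses 500 contrasts from
null cohorts sampled one window per dwell block (empirical type-I ≈ 0.05),
and cluster-number detection is exercised with 200 repeated draws on three
10σ-separated Gaussians (modal k = 3 in ≥ 90% of draws; the full
procedure defaults to 1000 draws).

## Known limitations

- Instance-level tests inherit the window-overlap autocorrelation described
  above; subject-level inference (e.g. mixed models on per-subject state
  summaries) is out of scope.
- dPS is undirected and single-band; directional or multi-band phase
  metrics are not provided.
- Only stage 1 of dual regression is implemented (time-course extraction);
  subject-specific spatial maps are not.
- The cluster-number histogram depends on the covariance families offered
  to the mixture fits; with 45-dimensional features and 200-instance draws,
  full-covariance models are often unestimable and selection is effectively
  among the simpler families, as in the repeated-draw procedure this
  reimplements.
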