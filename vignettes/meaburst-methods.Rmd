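---
title: "Detecting theta-range superburst dynamics and propagation motifs on MEAs"
author: "meaburst authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting theta-range superburst dynamics and propagation motifs on MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

## The problem

Mature, dense hippocampal cultures on planar multielectrode arrays (MEAs)
can settle into a striking activity regime: *long superbursts* of 10-30 s
containing hundreds of short (30-100 ms) network bursts repeating at
theta-range interburst frequencies (~11 Hz), with per-electrode spiking
rates of roughly 100-300 Hz inside each burst. Each small burst is a
travelling wave across the array, and the waves cluster into a small number
of recurring *motifs* distinguished by propagation direction. Successive
superbursts switch between two motif-defined types in an apparently random
binary sequence.

`meaburst` implements the full analysis chain that extracts this structure
from raw voltage or spike tables, paired with a synthetic generator that
plants every quantity the chain estimates, so that each stage can be
validated by parameter recovery rather than by eyeballing.

## The pipeline, stage by stage

**Spike detection.** Each channel is bandpass filtered (4th-order
Butterworth, 300-8000 Hz, applied forward-backward so filtering is
zero-phase and does not shift first-spike latencies). The noise scale is
the spike-robust estimate `sigma = median(|x|)/0.6745`, and events are
threshold crossings of `|x|` at `T = NS * sigma` with `NS = 8`. We detect
on the magnitude (both polarities) and report the signed extremum within
1 ms of the crossing; a 1 ms per-channel refractory period prevents double
counting, and a 20-200 uV amplitude gate discards artefacts. Sigma is
computed once per channel over the whole recording; a sliding variant was
considered and rejected because superbursts occupy a small duty cycle, so
the global median is dominated by inter-burst noise anyway.

**Network bursts.** The total spiking rate TSR(t) counts spikes from all
electrodes in 5 ms bins. Maximal runs with `TSR > 0.2 * sd(TSR)` are
network bursts; the start is adjusted to the first spike at or after the
crossing, the end is the first bin back below threshold, and the peak is
the centre of the earliest maximal bin (a fixed tie-break so runs are
reproducible). Interburst peak intervals (IBPIs) are peak-to-peak gaps
between consecutive small bursts *within* a superburst; their reciprocals
are instantaneous frequencies (IFs). IF distributions are non-normal, so
the per-recording summary is the median IF.

**Initiation vs small bursts.** Superbursts open with one large initiation
burst (1000-3000 spikes) followed by small bursts (10-500 spikes). The
two classes are separated by two-means clustering of spikes-per-burst.
Because the data are one-dimensional, the k = 2 K-means optimum is a
contiguous split of the sorted counts and is computed exactly by scanning
all split points (Lloyd iterations with restarts were observed to miss the
global optimum on occasion; the exact scan is both faster and
deterministic). The reported threshold is the midpoint between the cluster
extremes.

**Superbursts.** The TSR is correlated with a wide Gaussian kernel —
effective width read as the full width at half maximum, 50 s by default,
support truncated at ±2 FWHM and normalized to unit sum so correlation
magnitudes are comparable across widths. The correlation is evaluated on a
10 ms grid and thresholded at `0.4 * sd`; supra-threshold runs are
superbursts and bursts whose peak falls inside a run are its members.
Superbursts with at least 21 member small bursts are classed `long`
(the boundary sits just above the 3-20 small bursts typical of regular
superbursts and is configurable). Note the geometry this implies: with a
50 s kernel and a 0.4-sd threshold, detected boundaries extend a few tens
of seconds beyond the dense block itself, so distinct superbursts are only
resolved when their gaps exceed roughly two kernel widths.

**Activation and dynamic patterns.** A burst's activation pattern is the
vector of per-electrode first-spike latencies from burst start (missing
for silent electrodes). Its dynamic pattern is a vector field: for each
electrode we fit a least-squares plane to the latencies over the electrode
and its lattice neighbours within one pitch (up to 8 neighbours; at least
3 non-missing, non-collinear points). The fitted gradient (s/um) points
from early to late activation, i.e. along the propagation direction, and
the burst's *major direction* is the angle of the magnitude-weighted mean
of all defined vectors (an unweighted unit-vector mean is available).
Patterns with fewer than half the electrodes active are rejected rather
than imputed.

**Motif clustering.** Three routes are provided: K-means on
principal-component scores of whole activation patterns, EM
Gaussian-mixture clustering on 2 or 3 components, and K-means on major
directions embedded as `(cos, sin)` unit vectors (which removes the
0°/360° seam; per-motif summaries are circular means via the resultant
vector). For PC features, missing latencies are imputed with the burst's
maximum observed latency — "activated last or never" — which preserves
recruitment order without inventing early spikes; electrodes missing in
more than half the bursts are dropped. Cluster number is selected by the
Davies-Bouldin index `DB = (1/k) sum_i max_j (S_i+S_j)/M_ij` (mean
within-cluster distance to centroid over centroid separation), scanned
over k = 2..30 with the smallest k taken on ties; DB below 1 is treated
as robust clustering. The EM engine is a full-covariance Gaussian mixture;
for very small inputs (superburst typing works on a handful of fraction
vectors) the covariance model is chosen by BIC instead, which proved much
more stable than forcing the unconstrained model on 3-4 points.

**Typing and switching statistics.** Long superbursts are summarized by
their motif-fraction vectors and split into two types by a 2-component
mixture. Each type's dominant motif is its modal motif (ties broken by
earliest occurrence). From the typed sequence we compute: *motif
fidelity*, the fraction of small bursts carrying their superburst type's
dominant motif; the *superburst switch probability* between consecutive
typed superbursts; and the *small-burst motif switch probability* over the
whole recording's time-ordered small-burst sequence, ignoring superburst
boundaries (pairs spanning gaps are included there, but excluded from
within-superburst fidelity).

## What the generator emulates

`generatorConfig()` defaults encode the study conditions: 100-150 small
bursts per long superburst at a mean IBPI of 89.3 ms (median IF 11.2 Hz,
sd 20 ms, truncated so bursts never overlap), small bursts of 30-50 ms and
initiation bursts of 50-100 ms with 1000-3000 spikes, per-electrode
intra-burst rates of 139 Hz, motif fidelity 0.915, equiprobable type
switching (p = 0.5), and two motif directions 29° and 294° — 95° apart,
the across-culture mean separation. Values the source material does not
pin down were fixed once at realistic levels: wave speed 100 um/ms (so a
wave crosses the 1.4 mm array in 14-20 ms, inside a 30-50 ms burst),
Gaussian latency jitter of 2 ms truncated to the burst window, background
rate 0.1 Hz per electrode placed only outside burst windows, and
inter-superburst gaps of 100-200 s, consistent with several long
superbursts per half-hour recording and resolvable under the 50 s kernel.

Small bursts are planar waves: the first-spike latency of each electrode
is its position projected on the motif's unit direction divided by the
wave speed, plus jitter; with zero jitter, regressing latency on the
coordinates returns the planted direction and speed exactly, which makes
direction recovery analytically checkable. After the first spike each
electrode fires at the intra-burst rate; the per-electrode count is drawn
as `1 + Poisson(rate * duration - 1)` so that the natural estimator
(spikes over window duration, first spike included) is unbiased for the
configured rate. Extra spikes are placed with a 1 ms dead time per
electrode, honouring the spike table's refractory contract — without it,
rendered voltage templates would collide. Initiation bursts are
motif-neutral by default (isotropic latencies; a `wave` option exists
because burst origin statistics are not pinned down). Initiation-burst
sizes are homogeneous within a recording: the configured 1000-3000 range
is a population range across cultures, so one recording-level mean is
drawn from it and per-burst counts jitter by an eighth of the range. This
matters: two-means on spikes-per-burst provably mis-splits when initiation
counts within one recording span the full population range (a lone
1000-spike initiation burst is cheaper to absorb into the small cluster
than to keep beside a 3000-spike one), and simulation shows the homogeneous
structure makes the class gap the global optimum essentially always.

What the generator does *not* emulate: temporally clustered motif errors
(its fidelity is an independent Bernoulli per burst, so the expected
small-burst motif switch rate is `2f(1-f)` ≈ 15.6% at f = 0.915, higher
than in recordings where off-motif bursts come in runs), electrode-specific
amplitude and noise profiles, drifting rates within a superburst, and any
biophysics (it is a statistical emulator, not a neuron model). Passing
recovery tests on generator data therefore validates the estimators under
the assumed statistical structure, not the biology of real cultures.

## Numerical choices and degenerate inputs

- All times are seconds from recording start; intervals are half-open
  `[start, end)`; electrode ids are 0-based and keyed to the layout.
- A constant TSR (sd 0) or constant kernel correlation yields "no
  detections" with a warning rather than an error; a zero-noise channel
  (sigma 0) is skipped with a warning because its threshold is undefined.
- Coincident cluster centroids make the DB ratio undefined and raise an
  error; a degenerate mixture component triggers a refit with a
  regularizing prior (logged).
- Angles live in `[0, 360)`; a floating-point guard maps the `%% 360`
  artefact 360 back to 0. Circular differences are in `[0, 180]`.
- Constant latency fields give zero gradient vectors; the major direction
  is then `NA` (flagged) rather than an arbitrary angle.
- The pipeline derives every stochastic stage from one configured seed and
  bundle hashes are MD5 over the serialized stage outputs, so identical
  (input, config) pairs are hash-identical.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
data built at run time: recordings of 2-12 superbursts with 10-150 small
bursts each (up to ~1.4 million spikes for the sequence-statistics
recovery), 10^6-sample noise traces for the noise-scale and
false-positive checks, 100-trial paired simulations for the
two-motif/no-motif DB contrast, and 50 seeded recordings for the
burst-classification split. These sizes keep every closed-form or planted
comparison well inside three standard errors while remaining quick to run
on one CPU.

## Known limitations

- Per-electrode (single-channel) burst detection is out of scope; bursts
  are network-level by definition here.
- Spike sorting is out of scope: activity is treated as per-electrode
  multiunit, as in the source analyses.
- The regular/long boundary (21 small bursts) and the superburst kernel
  interpretation (effective width = FWHM) are declared conventions,
  configurable but not estimated from data.
- Statistical testing of angle differences is deliberately not provided:
  angle means are circular quantities, and a naive t-test on raw degrees
  is seam-dependent. Circular means and differences are reported instead.
- On-disk formats are CSV/YAML/JSON only.
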