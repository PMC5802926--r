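# meaburst

Network-burst, superburst and propagation-motif analysis for
multielectrode-array (MEA) recordings of cultured neuronal networks.

Mature, dense hippocampal cultures on a 59-electrode MEA can generate
*long superbursts*: 10-30 s episodes containing hundreds of short network
bursts recurring at theta-range frequencies (~11 Hz), each burst a
travelling wave whose direction falls into one of a few recurring motifs.
Successive superbursts switch between two motif-defined types like a
random binary sequence. `meaburst` implements the full analysis chain for
this phenomenon, for electrophysiologists working with MEA spike trains:

- **Spike detection** from raw voltage: zero-phase 300-8000 Hz Butterworth
  filtering, robust noise scale `sigma = median(|x|)/0.6745`, threshold
  `T = NS * sigma` (NS = 8), 1 ms refractory, 20-200 uV amplitude gate.
- **Network bursts** from the total spiking rate TSR(t) (spikes from all
  electrodes per 5 ms bin): runs above `0.2 * sd(TSR)`, starts adjusted to
  the first spike; interburst peak intervals (IBPI) and instantaneous
  frequencies IF = 1/IBPI; initiation (1000-3000 spikes) vs small
  (10-500 spikes) bursts split by exact 1-D two-means.
- **Superbursts** by correlating the TSR with a 50 s Gaussian kernel and
  thresholding at `0.4 * sd`; regular vs long classes.
- **Activation patterns** (per-electrode first-spike latencies) and
  **dynamic patterns** (local latency-gradient vector fields whose mean
  gives each burst's major propagation direction).
- **Motif clustering** by K-means or EM Gaussian mixtures on
  principal-component scores or on circle-embedded direction angles, with
  cluster number selected by the Davies-Bouldin index
  `DB = (1/k) sum_i max_j (S_i+S_j)/M_ij` over k = 2..30 (DB < 1 = robust).
- **Sequence statistics**: superburst typing by motif content, motif
  fidelity, superburst type switch probability and small-burst motif
  switch probability.
- A **synthetic MEA generator** that plants all of the above (planar-wave
  bursts, theta-range rhythms, two-type switching) with full ground truth,
  so every stage is validated by parameter recovery.

## Worked example

Simulate a six-superburst recording at the default study conditions and
run the whole pipeline:

```r
library(meaburst)

cfg <- generatorConfig(seed = 42, nSuperbursts = 6)
ds  <- generateDataset(cfg)
ds$spikes
#> SpikeTable: 272623 spikes on 59 electrodes, 836.9 s

bundle <- runPipeline(ds$spikes, pipelineConfig(seed = 42))
bundle
#> AnalysisBundle (config 9122c2f9)
#>   272623 spikes; 831 bursts; 6 superbursts
#>   fidelity 0.925, superburst switch 0.8, burst motif switch 0.136
#>   - spike_detection: skipped (spike-table input)
#>   - burst_detection: 831 bursts
#>   - superburst_detection: 6 superbursts (6 long)

round(bundle$ibpi$median_if_hz, 1)          # bursting rhythm
#> 11.1
act <- bundle$intra_burst_rates
round(mean(act$rate_hz[act$active]), 1)     # intra-burst rate, Hz/electrode
#> 130.5
bundle$motif_model
#> MotifModel: kmeans in angle space, k = 2 ; DB = 0.113
#>   motif circular means:  29.46, 294.30 deg
```

Reading the output: the small bursts recur at a median instantaneous
frequency of 11.1 Hz (theta range); active electrodes fire at ~130 Hz
inside bursts; the burst propagation directions cluster into two motifs
(DB = 0.11, far below the robustness boundary of 1) whose circular means
are 95° apart; 92.5% of small bursts carry their superburst type's own
motif, while consecutive superbursts switch type in 4 of 5 transitions in
this short sequence.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/meaburst-pipeline.R` (`simulate` and `run` subcommands).

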