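---
title: "Analyzing spiking-pattern propagation in modular two-chamber MEA cultures"
author: "modularMEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing spiking-pattern propagation in modular two-chamber MEA cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modularMEA)
```

## The experimental system

Modular cultures are grown in two chambers of a microfluidic chip — a
*Source* and a *Target* module — connected by asymmetric microchannels that
force axons to grow in one direction, so synaptic connections run
predominantly Source → Target. The chip sits on a 60-electrode MEA
(59 active, 1 reference, 20 kHz sampling); 8 of the microchannels carry 3
electrodes each. Two channel geometries ("fish" and "octopus") give weak and
strong inter-module coupling.

The analyses this package implements answer three questions about such
preparations:

1. Do spontaneous network bursts propagate between the modules, in which
   direction, and how often?
2. How strongly does electrical stimulation of the channel axons drive the
   Target module (evoked responses, PSTH)?
3. Does high-frequency (tetanic) conditioning change the evoked responses
   (potentiation / depression)?

Every stage can be exercised on synthetic recordings from the built-in
simulator, which supplies ground truth; that is how the package's test suite
validates the estimators.

## Spike detection

Raw traces are thresholded per electrode at `kSigma` times a median-based
noise estimate, `median(|x|)/0.6745` — the robust Gaussian scale estimator,
insensitive to the spikes themselves. Defaults: `kSigma = 8`, negative
polarity, 1 ms dead time, spike time at the absolute extremum within 1 ms of
the crossing (extremum alignment makes timing independent of spike height).
Detected times are scale-equivariant: scaling a trace leaves them unchanged.
There is no band-pass pre-filter by default; synthetic traces are already
band-limited, and real recordings should be filtered upstream.

## Network-burst detection

A module's population rate (spikes per `rateBin` = 50 ms, chamber electrodes
only by default) is thresholded at `thresholdSpikes = 5` spikes/bin;
candidate runs separated by less than `mergeGap` = 100 ms are merged, then
refined to the first/last spike and filtered by `minActiveElectrodes = 4`
and `minDuration = 20` ms. These constants are reconstructed defaults, all
exposed in `burstParams()`. Bursts touching the recording edges are flagged
and excluded from duration statistics.

Each burst's **peak time** is the center of the 1 ms bin with the maximal
instantaneous module rate. With realistic per-electrode rates the expected
count in a single millisecond bin at the envelope peak is of order one, so
the raw argmax can jitter by tens of milliseconds; the package therefore
smooths the 1 ms rate with a Gaussian kernel (`peakSmoothSigma` = 5 ms,
set 0 for the raw rule) before taking the earliest maximal bin. The
propagation-direction statistic depends on this peak, so the kernel estimate
is the package's main numerical-robustness choice.

## Burst propagation

Bursts of the two modules are paired greedily by peak-time proximity inside
a `window` of 200 ms (bursts last 60–190 ms and inter-burst intervals at
typical burst rates are seconds, so the window separates propagation from
independent bursting). The delay of a pair is
`peak(Target) − peak(Source)`; positive delays are forward events, negative
backward, and zero-delay pairs are discarded as unclassifiable. Forward
propagation probability is the forward-event count divided by the Source
burst count, backward the backward count divided by the Target burst count;
zero denominators give `NA`, never 0.

`propagationSummary()` refines the plain nearest-peak pairing with a second
greedy pass ordered by deviation from the median first-pass delay. The
reason is a failure mode of pure nearest matching: an independent burst that
lands by chance closer to a Target peak than the true partner (which sits
one propagation delay away) steals the pairing and shows up as propagation
in the wrong direction. Centering the priority on the culture's
characteristic latency resolves these ties, while a genuine cluster of
delays of either sign is untouched. The procedure negates symmetrically
when the modules are relabeled, so forward/backward antisymmetry is exact;
tests verify this on random instances.

Chip geometries are compared with the O/F relative difference,
`relativeDifference(octopusValue, fishValue)`, a plain ratio.

## Evoked responses and PSTH

Responses to low-frequency test stimulation (60 or 300 biphasic pulses,
1–5 s inter-stimulus intervals) are quantified with the post-stimulus time
histogram: per electrode, spike latencies in the analysis window are counted
into half-open 2 ms bins and normalized by the number of stimuli. The window
starts 10 ms after the stimulus to exclude the artifact and ends at 200 ms
for fish chips and 110 ms for octopus chips (95 and 50 bins). The raw
integer counts are retained alongside the normalized matrix, so conservation
(`sum(raw)` = number of in-window spikes) is exact. An electrode's **mean
PSTH** is the sum of its bins — evoked spikes per stimulus — and a module's
mean PSTH averages its electrodes. Overlapping analysis windows are refused
with the offending stimulus pair named.

## Plasticity classification

A plasticity experiment is the sequence test1 → test2 → tetanus (20 trains
of 10 pulses, 50 ms within trains, 5 s between) → test3. Per electrode, the
spontaneous drift PRE = meanPSTH(test2) − meanPSTH(test1) is compared to the
tetanus-induced change POST = meanPSTH(test3) − meanPSTH(test2) with a
two-sided Mann–Whitney rank-sum test (exact null distribution when the
pooled sample is ≤ 16 without ties, normal approximation with tie and
continuity corrections otherwise; α = 0.05). Significant experiments are
labelled potentiation or depression by the sign of the median shift; the
averaged magnitude (mean |POST| over the module's electrodes) is reported
only for significant outcomes. Differencing is done per electrode first and
averaged afterwards; module membership defaults to chamber plus the
channel-end electrodes of that side (`includeChannels`), and electrodes
silent in all three tests are excluded and logged.

## The simulator

`simConfig()` describes a statistical — not biophysical — model of the
preparation, sufficient to exercise every estimator:

- **Bursts.** Source bursts arise as a Poisson process (default 20/min)
  thinned by a 300 ms post-burst refractory gap: a module cannot start a new
  network burst while one is running, and without the gap overlapping
  "bursts" would make ground-truth attribution ill-defined. Envelope widths
  are Normal(141, 65) ms truncated at 20 ms — the mature-culture regime —
  with a piecewise envelope (linear rise over the first 20% of the width,
  exponential decay after; the peak is therefore well defined). Each
  chamber electrode fires as an inhomogeneous Poisson process under the
  envelope with a 100 spikes/s peak rate; background activity is
  0.5 spikes/s per electrode everywhere.
- **Propagation.** A Source burst spawns a Target burst with probability
  `pForward` (default 0.25) at a truncated-normal peak-to-peak delay of
  50 ± 10 ms. Autonomous Target bursting and backward propagation exist
  (`targetAutonomousRate`, `pBackward`) but default to 0: in the
  unidirectional cultures the defaults emulate, Target activity follows the
  Source.
- **Evoked responses.** Each stimulus makes every Target electrode emit
  Poisson(`weight × baseCount`) spikes (baseCount 5) at truncated-normal
  latencies (30 ± 15 ms) inside the chip's analysis window; Source
  electrodes emit a retrograde response of `retroFraction = 0.8` of the base
  count, independent of `weight` — the probe measures the Source→Target
  efficacy, so a tetanus (multiplying `weight` by `tetanusEffect`) moves
  Target responses but not Source ones, and Source POST differences stay
  small, as the asymmetry tests check.
- **Raw traces.** Gaussian noise (5 µV SD) plus a biphasic ~1 ms template
  (50 µV negative peak, SNR 10 against the default noise) at each spike
  time; overlaps sum linearly.

All draws come from a single seeded generator; identical seed and
configuration give byte-identical outputs, and experiment-level helpers
derive sub-seeds by fixed offsets.

What the simulator does **not** reproduce: electrode-specific amplitudes and
waveform diversity, spike sorting ambiguity, bursts with internal structure
(reverberations), stimulus artifacts (the 10 ms blanking is mirrored by
latency truncation instead), non-stationarity across a session, and
correlated noise. Estimator performance on these synthetic recordings
therefore bounds what the code does on clean data; it does not certify
performance on real recordings.

## Worked example

```{r example}
cfg <- simConfig(seed = 1, duration = 120)
sim <- simulateSpontaneous(cfg)
res <- runSpontaneousPipeline(sim$spikes)
res$summary
res$report$source$duration_mean_ms

ex <- simulatePlasticityExperiment(simConfig(seed = 7, tetanusEffect = 1.5))
runPlasticityPipeline(ex$test1, ex$test2, ex$test3)$result
```

## Numerical and design choices

- Times are seconds in files (fixed 6-decimal formatting, tab-delimited, so
  files are byte-stable), milliseconds in analysis-facing parameters;
  conversion is centralized.
- The 35 non-channel electrodes split 18 Source / 17 Target by convention;
  analyses group by region label, never by electrode-id arithmetic, so the
  particular split is immaterial.
- Peak ties break toward the earlier 1 ms bin; greedy pairing ties break by
  earlier source, then target, peak — everything is deterministic.
- Truncated-normal draws use rejection sampling, guaranteeing positive
  delays and latencies.
- Degenerate inputs are legal where the science allows (zero rates give
  empty tables; empty burst lists give `NA` probabilities) and errors where
  it does not (overlapping PSTH windows, spikes beyond the recording,
  sampling below 2 kHz).
- Raw traces travel in the package's native serialized container with
  metadata and layout attached; spike tables and stimulus logs are plain
  tab-delimited text with a commented metadata block.

Test problem sizes (600 s spontaneous runs, 20-seed batches, 50-experiment
plasticity batches) were chosen so the statistical assertions have clear
margins while the whole suite stays fast on a single CPU.

## Known limitations

- The burst criterion is a reconstruction with exposed defaults, not a
  published constant set; on real data the thresholds need tuning to firing
  levels.
- Propagation probabilities are slightly attenuated at low coupling because
  short bursts can fall below the detection minima; the consistency tests
  quantify the effect.
- The rank-sum exact path is limited to pooled samples of 16 without ties;
  beyond that the corrected normal approximation is used (the tests bound
  its error at n = 20/20 by 0.02).
- Plasticity classification treats electrodes as exchangeable samples;
  spatial correlation within a module is not modeled.
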