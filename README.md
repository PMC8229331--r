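# modularMEA

Network-activity analysis for **modular two-chamber MEA cultures**:
dissociated neurons grown in a *Source* and a *Target* chamber of a
microfluidic chip whose asymmetric microchannels force axons — and therefore
synaptic connections — to run in one direction. Recordings come from a
60-electrode array (59 active, 20 kHz) with three electrodes inside each of
eight instrumented microchannels. The package is for electrophysiologists
who need to quantify, from such recordings:

- spontaneous **network bursts** per module and their durations,
- **burst propagation** between modules — direction and probability,
- **evoked responses** to test stimulation of the channel axons (PSTH),
- **tetanus-induced plasticity** (potentiation / depression) of those
  responses.

A seeded statistical simulator of the two-module preparation is included and
generates ground truth for every stage, so the whole pipeline is testable
without laboratory data.

## Methods in brief

**Spike detection.** Per electrode, threshold at `k·σ̂` with
`σ̂ = median(|x|)/0.6745` (robust Gaussian scale); default `k = 8`, negative
crossings, spike time at the extremum within 1 ms, 1 ms dead time.

**Bursts.** Module population rate in 50 ms bins, threshold 5 spikes/bin,
runs merged across gaps < 100 ms, ≥ 4 active electrodes, ≥ 20 ms duration.
Each burst's peak is the maximal instantaneous (1 ms-binned, kernel-smoothed)
module rate.

**Propagation.** Bursts of the two modules are paired by peak proximity
(window 200 ms, delay-coherent greedy matching); the delay
`Δ = peak(Target) − peak(Source)` classifies direction (`Δ > 0` forward).
Then

    p_forward  = #(Source→Target events) / #(Source bursts)
    p_backward = #(Target→Source events) / #(Target bursts)

and chip geometries are compared by the O/F ratio of a statistic measured on
octopus-type vs fish-type chips.

**Evoked responses.** Post-stimulus time histogram on 2 ms bins in a
10–200 ms (fish) or 10–110 ms (octopus) latency window, normalized by the
number of stimuli; an electrode's *mean PSTH* is its per-stimulus evoked
spike count.

**Plasticity.** Around a tetanus (20 trains × 10 pulses, 50 ms/5 s), the
per-electrode PRE difference `meanPSTH(test2) − meanPSTH(test1)` is compared
to POST `meanPSTH(test3) − meanPSTH(test2)` with a two-sided Mann–Whitney
rank-sum test (α = 0.05); significant increases are potentiation, decreases
depression.

## Worked example

```r
library(modularMEA)

cfg <- simConfig(seed = 1, duration = 120)     # two-module culture, 2 min
sim <- simulateSpontaneous(cfg)
sim$spikes
#> SpikeTable: 7110 spikes on 59 electrodes, 120.0 s @ 20000 Hz (fish chip)

res <- runSpontaneousPipeline(sim$spikes)
res$summary
#> PropagationSummary: 33 source / 7 target bursts; 7 forward, 0 backward;
#>   p_forward = 0.212, p_backward = 0.000
```

33 Source bursts were detected, 7 of which propagated to the Target module
(forward probability 0.21 — the generator's true value is 0.25), none
backward; the report also carries the burst-duration summary
(`128.9 ± 59.1 ms` here, against a generated envelope of `141 ± 65 ms`).

```r
ex <- simulatePlasticityExperiment(simConfig(seed = 7, tetanusEffect = 1.5))
runPlasticityPipeline(ex$test1, ex$test2, ex$test3)$result
#> PlasticityResult: potentiation (U = 118, p = 0.0001656, alpha = 0.05)
#>   averaged |POST difference| = 1.693 spikes/stimulus
```

The simulated tetanus multiplied the Source→Target efficacy by 1.5; the
rank-sum comparison of pre- vs post-tetanus PSTH differences across the
Target electrodes flags the change as potentiation.

See `vignettes/modular-mea-analysis.Rmd` for the full model description,
parameter meanings, and design rationale.

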