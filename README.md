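# lamidelay

Spike-to-spike delay analysis of laminar population activity in dual-probe
cortical recordings.

## What it is for

Laminar probes record extracellular signals at each of the six cortical
layers; with one probe per hemisphere in primary somatosensory cortex (S1)
there are twelve layer × hemisphere channels.  `lamidelay` asks how
population spiking propagates across those channels:

* Does activity climb **upward**, from infragranular layers (L5/L6) toward
  the surface (L1), in stimulus-evoked and in spontaneous activity?
* Is the interhemispheric relay **deep-first** — after a spike in one S1,
  do the deep layers of the other S1 respond before the superficial ones?
* Is the upward climb a **step-wise progression over layers** or a
  continuous wave through tissue?

The core statistic: for every population spike at time *t*, the delay Δt
to the *next* spike in each of the other channels, within the same epoch
and a 30 ms horizon.  Cell-wise means form 6 × 6 delay matrices D(s, t)
(spike layer s → target layer t) per reference (spike hemisphere vs. the
other hemisphere).  Upward propagation appears as D(s, t) growing as t
moves surfaceward of s; the relay appears as smaller delays onto deep
target layers of the other hemisphere.  Firing-rate confounds are
controlled by shuffling the twelve channel labels across all spikes
(times fixed), contrasts are tested with an animal-level percentile
bootstrap, upward velocity is the reciprocal slope of delay against
cortical depth, and step-wise versus continuous propagation is compared
through a BIC-approximated Bayes factor,
B₁₂ = exp(−(BIC₁ − BIC₂)/2), between fits on equally spaced layer depths
and on the unequally spaced actual recording depths.

Because no public recordings accompany this analysis, the package includes
a synthetic generator of two-hemisphere, six-layer spike data with known
ground truth (cascade lags, relay delays, true velocity) used by all tests
and demos.

## Worked example

```r
library(lamidelay)

cfg <- run_config(
  scenario_evoked      = scenario_config("evoked",      n_animals = 6, n_epochs = 200),
  scenario_spontaneous = scenario_config("spontaneous", n_animals = 6, n_epochs = 200),
  seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
Laminar delay analysis report (6 animals, seed 1)
  evoked      upward 4.50 ms, downward 3.91 ms; other S1 deep 8.80, superficial 12.52 ms
              delay ratio same 1.17 / other 0.86  (shuffled 1.08 / 1.00)
  spontaneous upward 4.36 ms, downward 3.91 ms; other S1 deep 4.30, superficial 7.15 ms
              delay ratio same 1.17 / other 1.09
  mean velocities (m/s):
    evoked       other_S1  0.237
    spontaneous  other_S1  0.342
    evoked       same_S1   1.382
    spontaneous  same_S1   1.142
```

Reading this: within the spike hemisphere, delays toward the surface
(upward, 4.50 ms) exceed delays toward depth (3.91 ms) — activity climbs
upward.  In the other hemisphere the deep layers respond first (8.80 ms
vs. 12.52 ms onto superficial targets): the relay targets infragranular
layers.  The delay ratio (mean delay after deep-layer spikes over mean
delay after superficial-layer spikes) is 1.17, above its label-shuffled
rate control (1.08), so the pattern is not a firing-rate artifact.  The
bootstrap contrast makes the upward–downward difference explicit:

```r
report$bootstrap$evoked_up_vs_down
#> Bootstrap contrast (n = 6 animals, 5000 resamples)
#>   M = 0.588, 95% CI [0.497, 0.674]  (excludes 0)
```

Per-animal matrices are plain 6 × 6 grids:

```r
report$per_animal[[1]]$matrices$evoked
#> Next-spike delay matrices (animal 1, evoked, horizon 30 ms, 6800 spikes)
#> Spike S1 (references collapsed; rows spike layer, cols target layer):
#>            target_layer
#> spike_layer   L1   L2   L3   L4   L5   L6
#>          L1   NA 7.51 6.95 3.43 2.85 3.08
#>          ...
```

Lower-level entry points mirror the analysis stages: `detect_spikes()`
(adaptive thresholding of bandpassed multi-unit activity),
`epoch_events()`, `next_spike_delays()`, `summarize_delays()`,
`shuffle_labels()`, `bootstrap_diff()`, `fit_velocity()`,
`bayes_factor()`.  The vignette
(`vignettes/laminar-delay-analysis.Rmd`) documents the model, the
generator, and every numerical choice.

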