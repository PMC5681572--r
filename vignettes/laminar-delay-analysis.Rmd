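---
title: "Quantifying laminar propagation with next-spike delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying laminar propagation with next-spike delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamidelay)
```

## The problem

In a laminar recording, one depth probe samples extracellular voltage at
each of the six cortical layers; with probes in the primary somatosensory
cortex (S1) of both hemispheres there are twelve layer-by-hemisphere
channels.  Population spikes — negative threshold crossings of the
bandpassed multi-unit band — mark moments of locally synchronized firing.
The scientific question this package addresses is *directional*: does
population activity climb from the deep (infragranular) layers toward the
surface, does it do so step-wise over layers or continuously through
tissue, and how is it relayed between the two hemispheres?

The core statistic is deliberately simple.  For every population spike at
time *t* on one channel, we record the delay Δt to the *next* spike on each
of the eleven other channels, provided it falls within the same epoch and
within a 30 ms horizon.  Cell-wise averages of these delays form a 6 × 6
delay matrix per reference (spike hemisphere vs. the other hemisphere).
Upward propagation appears as delays that grow as the target layer moves
toward the surface; an interhemispheric relay that targets deep layers
appears as shorter delays onto L4–L6 of the other hemisphere.

## Analysis pipeline

1. **Detection** (`detect_spikes()`): zero-phase Butterworth bandpass
   (500–3000 Hz default; a narrower 750–2000 Hz multi-unit preset is also
   named in `band_presets()`), then a per-channel data-driven threshold of
   5 noise standard deviations on the negative amplitude.  The noise scale
   defaults to `median(|x|)/0.6745`, the adaptive-threshold convention for
   spike detection, which is consistent for the SD of Gaussian noise but
   robust to the spikes themselves; the literal sample SD is available as
   `noise_estimator = "plain_sd"`.  Events within 0–5 ms after a stimulus
   are discarded (mechanical stimulator artifacts), and a 1 ms dead time
   prevents one transient from being counted at several samples.  The dead
   time is our choice: multi-sample crossings of a single transient are a
   sampling artifact, not repeated population events.
2. **Epoching** (`epoch_events()`): evoked epochs keep 5–60 ms after each
   stimulus; spontaneous epochs are 7 s windows starting 2 s after
   stimulation.  Windows are half-open, `[start, end)`, so boundary spikes
   are counted exactly once.
3. **Delay matrices** (`next_spike_delays()`): strictly positive delays
   (simultaneous spikes are ties from finite sampling, not succession),
   never across epoch boundaries, diagonal undefined within the spike
   hemisphere.  Cells with no contributing pair stay undefined and are
   excluded from summaries rather than imputed.  Averaging is
   hierarchical: spike pair → within-animal cell mean → across-animal
   mean.  Contra- and ipsi-referenced matrices are pooled cell-wise with
   count weighting (`collapse_references()`), which is equivalent to
   pooling the underlying spike pairs.
4. **Summaries** (`summarize_delays()`): mean upward vs. downward delays
   (cells above vs. below the spike layer), interhemispheric means onto
   deep (L4–L6) vs. superficial (L1–L3) targets, and the delay ratio —
   mean delay after deep-layer spikes over mean delay after
   superficial-layer spikes, which exceeds 1 when upward lags dominate.
5. **Rate control** (`shuffle_labels()`): the twelve channel labels are
   permuted across all spikes of an animal (1000 permutations), keeping
   every spike time and every per-channel total fixed.  Any delay
   structure surviving in the shuffled data reflects firing rates alone;
   the observed ratio is compared against the shuffled ratio distribution.
6. **Inference** (`bootstrap_diff()`): animal-level percentile bootstrap
   (5000 resamples) of paired differences; a contrast is called when the
   95% interval excludes zero.  Paired resampling keeps each animal's two
   condition values together because all contrasts are within-animal.
7. **Velocity** (`fit_velocity()`): ordinary least squares of mean delay
   (ms) on cortical depth (mm) over the target layers; within the spike
   hemisphere only targets *above* the spike layer are used, so only spike
   layers L4–L6 provide the three or more points a two-parameter fit
   needs, and the spike layer's own zero-delay point is never included.  A
   slope in ms/mm is not a velocity; we report the reciprocal of its
   magnitude (mm/ms ≡ m/s).  Depths default to the equally spaced
   per-layer model depths (−0.10 … −1.50 mm, 0.28 mm spacing).  This is a
   deliberate choice where two depth conventions exist (see below): since
   propagation is layer-wise, the layer spacing is the natural axis, and
   it makes noiseless layer-step cascades recover their ground-truth
   velocity exactly.  Any depth vector can be supplied instead.
8. **Model comparison** (`bayes_factor()`): the same delay row is fitted
   against the equally spaced layer depths (step-wise model M1) and
   against the unequally spaced actual recording depths
   (−0.10, −0.25, −0.50, −0.75, −1.10, −1.50 mm; continuous model M2).
   With equal priors the Bayes factor is approximated from the Bayesian
   Information Criterion as B12 = exp(−(BIC1 − BIC2)/2), using
   BIC = n·ln(RSS/n) + k·ln(n) with k = 2 for both models, so all
   constant terms cancel in the difference and the residual variance is
   the only discriminator.  Per-animal Bayes factors are averaged
   arithmetically (`bayes_factor_summary()`) to limit the influence of
   outlying animals.  B12 > 3 is conventionally positive evidence for the
   layer model, < 1/3 positive evidence for the depth model.

`run_pipeline()` drives all stages and returns one `laminar_report`;
`write_report()` serializes it deterministically, so a config plus seed
reproduces every output file byte for byte.

## The synthetic generator

No public recordings accompany this analysis, so the package ships a
generator (`scenario_config()`, `generate_events()`) whose defaults encode
the study conditions: 6 animals, 200 epochs per regime, 100 ms evoked
epochs and 7 s spontaneous epochs, all at event level.  Each epoch holds:

* **Background**: independent Poisson spikes per channel with a laminar
  rate profile (sparse L1, dense L5); defaults 2–14 Hz evoked and
  0.5–5 Hz spontaneous.
* **Cascade events**: in the evoked regime a stimulus-locked volley at
  7 ms co-activates L4–L6 of the contralateral hemisphere and climbs
  upward at `cascade_lag` ms per layer step (default 0.4 ms, i.e. a true
  upward velocity of 0.28/0.4 = 0.7 m/s); spontaneous up-states start at
  Poisson-random onsets (1.5 Hz), sweep upward from L6 at 1.1 ms per step
  (0.25 m/s) and occur in a random hemisphere.  Under
  `cascade_mode = "depth_linear"` the per-step lag is instead proportional
  to the distance between the actual recording depths, which is what the
  Bayes-factor comparison should *reject* the layer model against.
* **Interhemispheric relay**: each event is relayed to L6 of the other
  hemisphere after `relay_delay` ms (9 ms evoked, 8 ms spontaneous) and
  climbs upward there by `relay_superficial_increment` per layer (1.6 ms
  evoked, 0.8 ms spontaneous), so deep layers of the other hemisphere
  always lead.
* **Participation and afterdischarge**: each layer joins an event with a
  probability that falls from L5 upward (0.95 at L5 down to 0.45 at L1),
  and a participating layer fires a brief Poisson afterdischarge that
  trails its own first (sweep) spike.  Afterdischarge windows are long in
  infragranular layers (8–12 ms evoked, 15–25 ms spontaneous) and short
  superficially (2–4 ms).  This reproduces two robust features of laminar
  data — abundant deep and sparse superficial activity around each event,
  and short *downward* delays (after a superficial spike the deep layers
  are still discharging) — while the first spike per layer carries the
  upward lag.  Without it, downward delays would be governed by the sparse
  background and upward delays could not exceed them.
* **Jitter**: Gaussian timing noise (0.3 ms SD) on all structured spikes.

Every epoch draws from its own seeded RNG stream (derived from the
scenario seed by animal and epoch counters), so generation is exactly
reproducible and per-epoch parallelizable.  The generator also returns its
ground truth (event onsets, structural lags, true velocity), and
`generate_continuous()` renders events into Gaussian noise as biphasic,
dominantly negative transients for exercising the detection stage — at
short epoch counts, since a full spontaneous scenario would be gigabytes
of signal.

### What the generator does and does not emulate

It reproduces the *directional statistics* the analysis targets: upward
delay gradients, deep-first interhemispheric relay, laminar rate profiles,
delay ratios above 1, and their disappearance under label shuffling or in
the rate-only null (`generate_rate_only_null()`).  It does not model
biophysics: no membrane or synaptic dynamics, no LFP, no oscillatory
volley recurrence, no anesthesia-state dynamics.  Two consequences are
worth knowing.  First, the mixture of sweep spikes and afterdischarge
spikes flattens delay-versus-depth rows relative to the pure sweep, so
velocities fitted on the paper-like scenario sit above the generator's
nominal sweep velocity within the spike hemisphere, and per-row Bayes
factors on such mixture rows need not favor the layer model even though
the sweep itself is layer-stepped.  The Bayes-factor machinery is
therefore validated separately on `generate_delay_rows()`, which produces
rows exactly linear in one spacing or the other plus noise.  Second,
passing tests on synthetic data demonstrates correctness of the
*computations*, not fidelity of any particular biological magnitude.

## Numerical choices and edge cases

* Filtering is forward–backward (`signal::filtfilt`), so detection
  timestamps carry no group delay; a 4th-order Butterworth is stable at
  the 3000 Hz corner with a 6250 Hz sampling rate.
* An all-constant channel has no noise scale; detection flags it with a
  warning and returns no events for that channel.
* Ties in spike times never count as "next" (strict inequality), and a
  perfect linear fit is reported as BIC −∞ with a `perfect_fit` flag
  rather than an error.
* Velocities are undefined (flagged, not fabricated) when the fitted
  slope is numerically zero.
* The percentile bootstrap is the minimal nonparametric reading for six
  animals; with n = 6 its 95% intervals genuinely undercover (~85–88% in
  our Monte-Carlo checks), a known small-sample property the user should
  keep in mind when interpreting borderline contrasts.
* Where sources disagree on the detection band (500–3000 Hz vs.
  750–2000 Hz) the wider band is the default and the narrower one a named
  preset; the recording-depth list used by the depth model differs from
  the histological electrode depths (300 vs. 250 µm at L2, 800 vs. 750 µm
  at L4), so the geometry is fully overridable via `layer_geometry()`.

## Problem sizes

The shipped defaults — 6 animals × 200 epochs × 2 regimes, 1000 shuffles,
5000 bootstrap resamples — run end to end in under a minute on one core;
the test suite exercises reduced versions of every stage plus the full
scenario.  The functions, `run_pipeline()`, and this vignette are the
interface; the package deliberately ships no shell wrapper, since its
users drive analyses from R.
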