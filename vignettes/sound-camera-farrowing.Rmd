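---
title: "Monitoring farrowing sows with an acoustic camera: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring farrowing sows with an acoustic camera: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farrowcam)
```

## The problem

Around farrowing, sows show characteristic acoustic and behavioural
patterns: intense nest-building (playing with a jute sack, rooting the
floor near the head end of the crate) in the hours before birth, near-total
inactivity once farrowing starts, and movement of newborn piglets in the
area behind the sow while births are in progress. An acoustic camera — an
overhead array of 64 microphones running delay-and-sum beamforming — shows
each detected sound as a coloured "spot" at its estimated position in the
pen. If spots can be trusted, their spatial pattern over time is a
farrowing monitor: head-zone spots stopping marks onset, fresh rear-zone
spots mean births are still in progress, and their joint absence marks the
end.

`farrowcam` implements that whole chain as testable code: a synthetic-scene
generator (no field recordings are publicly available), the beamformer, the
spot-versus-reference validation protocol with its confusion counts and
metrics, and the onset/progress monitor.

## The validation protocol

Spots are compared against two observer-style reference streams: audible
sounds (point events with a label such as `sow_in_crate`, `trough`,
`metal_fence`, `neighbour_sow`) and behaviour states (`lying`,
`sitting_standing`, `jute_rooting`). The rules, all implemented in
`match_events()`:

* a spot within ±1 s of an audible sound, at a zone the correspondence
  table accepts for that label, is a **correct positive** (CP);
* a paired spot at the wrong location is counted as a **false negative**
  or a **correct positive** according to the *location policy* — both
  columns are reported, as in the original field validation;
* unpaired spots are **false positives** (FP), unmatched references
  **false negatives** (FN);
* every maximal stretch of at least 2 s with neither a spot nor reference
  activity contributes `floor(length / 2 s)` **correct negatives** (CN).
  How long silences accumulate is not fixed by the protocol, so the
  alternative one-per-stretch rule is available via `cn_mode`.
* behaviours are states, not points, so a behaviour validates a spot by
  interval containment (with the ±1 s tolerance at the edges) plus zone
  correspondence; in `sound_or_behaviour` mode a spot is correct when
  either stream validates it.

Pairing is one-to-one. A pure greedy nearest-in-time pairing is not
maximum-cardinality (spots {0, 1} s and references {1.0, 1.1} s with a 1 s
tolerance defeat it), so `match_events()` seeds greedily by smallest time
distance and completes the pairing with augmenting paths; the tests verify
equality with a brute-force enumeration oracle on hundreds of random
instances.

Metrics follow the standard definitions: accuracy (CP+CN)/total, error
(FP+FN)/total, sensitivity CP/(CP+FN), specificity CN/(CN+FP), precision
CP/(CP+FP), and the correct-positive share CP/total. One printed formula in
the source material reads as CN/(FN+CP) for specificity, which does not
reproduce the published table values (it gives 47.5 where 12.8 is printed);
CN/(CN+FP) reproduces them in both policy columns and is the standard
definition, so it is used here. Rounding (half-up, one decimal) happens
only at presentation.

```{r metrics}
fc <- field_counts()
metrics_report(fc)
```

## The synthetic-data generator

The generator emulates the study conditions: a 2.80 × 1.75 m farrowing pen
with a 2.1 × 1.0 m crate, observed from 2 m above by a 64-microphone
array. Its defaults are the field values wherever those are stated, and
field-plausible choices elsewhere:

* **Timeline** — 4 h of pre-farrowing observation, onset, a litter of 12
  piglets (the study mean was about 12.5) at gamma-distributed intervals
  (mean 15 min), and 4 h post farrowing. `profile = "demo"` shrinks this
  to a half-hour scene with 3 births for audio-level runs.
* **Behaviour** — a renewal process: bouts are drawn with probabilities
  proportional to (phase budget / mean bout length) and gamma bout
  durations (shape 4; means 60/25/30 s for lying, sitting/standing,
  rooting), so time shares converge to the per-phase budgets: 71.7/3.3/25 %
  before farrowing, 93.5/6.2/0.3 % during, 100/0/0 % after. The 0.3 %
  residual rooting during farrowing is kept, and after farrowing the sow
  only lies.
* **Sound events** — Poisson streams tied to behaviour: rooting sounds
  (10/min) only during rooting bouts in the head zone; trough and fence
  sounds while sitting/standing; sow vocalisations at the head
  throughout; one inaudible birth event per piglet and piglet-movement
  sounds (3/min for 10 min after each birth) behind the sow; neighbour-sow
  sounds outside the pen. Source levels are log-normal (median 0.05,
  sdlog 0.6 in linear units at 1 m).
* **Audio** — band-limited noise bursts (the field system characterises
  sources only by frequency band) with raised-cosine ramps, free-field
  direct-path propagation at c = 343 m/s, spherical 1/r attenuation, no
  reverberation, fractional delays by linear interpolation, white
  background noise. `snr_db = 30` sets the in-band SNR at 1 m of a
  median-level event; fs = 192 kHz respects the 39–49 kHz analysis band.
* **Audibility** — the field analysis band is ultrasonic while the
  reference sounds are audible to humans; the link between the two is not
  described, so audibility is an independent per-event flag (events below
  `audibility_threshold`, and all piglet events, are inaudible).

What the generator does *not* emulate — reverberation, occlusion by the
sow's body, correlated interference, real vocalisation spectra, observer
labelling errors — bounds what passing tests show: they validate the
pipeline's logic and its behaviour under the stated statistical structure,
not performance on farm recordings.

## The beamformer

`das_beamform()` is the textbook operation: per focus point, channels are
shifted by the exact propagation delay (nearest sample at 192 kHz), summed,
divided by the channel count, and the maximum absolute amplitude of the
aligned sum is the map value. The map grid covers the pen at 0.05 m
spacing; the array is an 8 × 8 grid at 0.04 m pitch.

Streaming long scenes needs two departures from the textbook, both
implemented as the package's own design:

* **Frequency-domain evaluation** (`das_power_map()`): steering by exact
  phase `exp(2πi f d)` over the FFT bins inside the analysis band, with the
  map value the in-band RMS of the averaged beam spectrum. Peak positions
  agree with the time-domain map, band selection replaces the explicit
  band-pass filter, and a frame costs ~30× less, which is what makes a
  half-hour 64-channel scene tractable. A full 30-min scene at 192 kHz ×
  64 channels (~90 GB as floats) is never materialised: `beamform_scene()`
  synthesises audio lazily, gating frames on the in-band energy of a
  reference channel before beamforming only the active ones.
* **Peak refinement**: an 8 × 8 half-wavelength-violating array has strong
  grating lobes (~0.43 m from the main lobe, up to ~90 % of its height),
  and the 0.05 m grid under-samples the ~7 cm beam, so an off-grid main
  lobe can sample *below* an on-grid sidelobe. Each frame therefore
  re-evaluates up to 24 separated coarse peaks on a 0.0125 m sub-grid and
  reports the best refined position. Spot positions are consequently not
  quantised to the coarse grid.

Detection implements the camera's documented behaviour: "no clear source,
no spot" becomes *map maximum < per-frame median × 10^(6 dB/20) ⇒ no
spot* (the medium is the per-frame noise floor, robust to nonstationary
background); the spatial filter localises on a grid extended 0.5 m beyond
the region of interest and discards frames whose global peak falls outside
it — restricting the map to the region instead would mistake edge
sidelobes of outside sources for in-pen spots. One spot per frame (the
global maximum) is reported; the recording-chain lag (+1.5 s timestamp
correction in the field) is simulated and corrected symmetrically.

The camera's frame rate, detection threshold and map resolution are not
public; frame length 50 ms, 6 dB floor margin and 0.05 m spacing are
config-exposed defaults.

## The onset monitor

`detect_onset()` encodes the behavioural findings as a detector with
config-exposed thresholds (none are given numerically in the source
material):

1. head-zone spot rate in a 600 s sliding window must first exceed
   2.5/min (nest building present), then fall below 0.6/min (ceased) and
   *stay* below the high threshold — nest building does not resume;
2. the cessation is confirmed by a rear-zone spot cluster (≥ 5 spots
   within 120 s) within one window of the crossing — newborn piglets
   behind the sow;
3. the onset estimate is the change point of a two-rate Poisson fit to the
   head-zone spot times around the crossing, i.e. the cessation moment
   itself rather than the (later) detection time.

`monitor_progress()` chains rear-zone clusters: gaps of ≥ 30 min raise a
"stalled" alert, and the end of farrowing is the last cluster plus the
timeout. The low-rate threshold default derives from the 0.3 % residual
rooting budget; the cluster minimum (5) keeps isolated clutter spots
(simulated at 1/min over the pen) from faking progress.

## Numerical choices and degenerate inputs

* Seeds: every stochastic stage derives its own stream from the single
  configured seed and restores the session RNG afterwards; equal seeds give
  byte-identical artefacts end to end.
* A litter of zero collapses the farrowing phase (onset = end, no births);
  zero-length phases produce empty scripts; empty event lists produce
  empty (all-noise or all-zero) audio and empty logs.
* Matching tie-breaks: edges are processed by (time distance, spot time,
  reference time); CN counting uses closed observation windows supplied by
  the caller (defaulting to the span of the streams).
* Undefined metrics (zero denominators) are `NA`, never 0; accuracy +
  error ≡ 100 by construction.
* Spot clouds (≥ 5 spots within 1 s and 0.3 m — the cloud is described
  only qualitatively in the field reports) are collapsed to their first
  spot before matching, following the slowed-replay observation that
  clouds start with one spot in the right place.

## Problem sizes used in the shipped checks

The automated checks run a 30-minute demo scene through the full audio
chain (about 30,000 frames scanned, several hundred beamformed), twenty
11-hour study scenes at log level for onset recovery, a 40-hour behaviour
simulation for budget convergence, 500 random matcher instances against
the brute-force oracle, and 1000 random count vectors for the metric
identities. These sizes were chosen so the whole suite runs on a laptop in
well under half an hour while keeping every stochastic tolerance
comfortably non-trivial.

## Known limitations

* The free-field scene model is optimistic: no reverberation or occlusion
  means localisation accuracy here is an upper bound on field accuracy.
* The square array's grating lobes are physical; the refinement step picks
  the true main lobe only while it remains the global maximum, which very
  low SNR can break.
* Onset detection assumes rooting sounds dominate the head zone before
  farrowing; a pen layout that places loud persistent sources in the head
  zone would need re-tuned rate thresholds.
* The end-of-farrowing estimate inherits the progress timeout (30 min) as
  an irreducible latency.
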