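---
title: "Methods: pressure-pulse gait analysis with gaitpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pressure-pulse gait analysis with gaitpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpress)
```

## The measurement model

Six piezoresistive sensors sit under the shoe linings, three per foot:
channels 1 and 2 under the forefoot (medial/lateral), channel 3 under the
heel. Each sensor forms the lower arm of a voltage divider with a fixed
reference resistor, so its output voltage

$$V_{out} = V_{s}\,\frac{R_{ref}}{R_{ref} + R_{sensor}}$$

rises as load compresses the sensing film and its resistance falls. The
method is deliberately calibration-free: all downstream quantities are
relative (pulse amplitudes above the idle baseline, pulse timings), so the
absolute resistance–force curve never needs to be known.

A gait cycle — one full left+right stride — partitions, per leg, into a
stance phase (foot loaded) and a swing phase. In normal adult gait stance
occupies about 60% of the cycle, of which about 20% is double support
(both feet loaded); swing takes the remaining 40%. These printed fractions
are the defaults of `gait_phase_model()` and the package's primary
quantitative benchmark: a noise-free simulated normal gait must round-trip
through pulse detection back to 60/20/40 within one sample period.

### A consistency constraint on the phase fractions

With both feet alternating in continuous ground contact, the time both
feet are loaded per cycle is an identity, not a free choice:

$$T_{ds} = S_L + S_R - T,$$

where $S_L, S_R$ are the stance durations and $T$ the cycle. The default
triple (60/20/40) satisfies it exactly, which is why `gaitpress` treats a
requested double support below $2\,\mathrm{stance} - 1$ as an error. When
a *larger* double support is requested (possible only with uneven
alternation), the timeline shifts the right foot off the symmetric
half-cycle so that a single double-support episode of exactly the
requested duration occurs each cycle. Symmetric alternation — two equal
episodes per cycle — is used whenever the requested value equals the
symmetric one.

## The synthetic-data generator

`simulate_recording()` composes:

1. **Timeline** (`build_gait_timeline`): left stances at multiples of the
   cycle; right foot offset half a cycle (or as derived above); per-leg
   stance multipliers inject duration asymmetry.
2. **Load waveforms** (`channel_load_waveform`): each channel is active in
   a sub-window of the stance (heel first in normal gait, sensor 2 first
   in the abnormal modes), rising to its per-mode peak load with a
   raised-cosine edge, holding a plateau, and falling back with a
   raised-cosine. Front sensors rise more slowly than the heel, giving
   them the longest stepping abruptness.
3. **Electrics**: hyperbolic resistance–load law
   $R(load) = R_0/(1 + k\,load/R_0)$ — a documented stand-in, strictly
   decreasing and positive — followed by the divider formula, Gaussian
   noise, optional linear drift, and clamping to $[0, V_s]$.

Tunable parameters, defaults, and why:

| parameter | default | rationale |
|---|---|---|
| sampling rate | 100 Hz | resolves the ~0.15 s timing contrasts of interest with ≥15 samples; the acquisition hardware class samples far faster |
| supply voltage | 3.3 V | typical for the wireless microcontroller boards used in wearable acquisition |
| reference resistor | 200 Ω | the readout circuit's documented value |
| unloaded resistance | 2 kΩ | puts the idle output at 0.3 V, ≈3 noise SDs above the ADC floor so baseline noise does not clip at 0 |
| load sensitivity | 4 kΩ per load unit | one load unit divides the resistance by 3; load units are arbitrary (no force calibration) |
| rise / fall time | 0.15 s | yields extracted abruptness ≈0.10–0.16 s, the magnitude seen on real recordings |
| noise SD | 0 (tests use 0.05–0.1 V) | additive Gaussian; drift defaults to 0 and is available as volts/second |

Per-mode peak-load tables are calibrated so the divider voltages show the
field-typical contrasts — within-foot amplitude spreads up to ≈1.9 V,
between-leg mean contrasts up to ≈0.7 V, and a ≈0.3 s left–right rhythm
shift for the straight-leg gait (injected by moving the right-foot onset
to 0.65 of the cycle). The divider saturates at high loads, so load-space
contrasts compress in voltage space; the tables are defaults that encode
each mode's documented dominant-sensor signature (e.g. left heel + right
forefoot for the turnaround, right forefoot sensor 1 for shuffling), not
ground truth about any subject.

**What a green test establishes — and what it does not.** The generator
emulates the acquisition chain and the qualitative signatures of the seven
gait modes. It does not emulate inter-subject variability, sensor aging or
hysteresis of the sensing film, wireless packet loss, or footwear effects.
Classifier accuracy on synthetic data therefore demonstrates internal
consistency (the extraction and rules recover what the generator encoded),
not clinical performance.

## Pulse detection and extraction

Detection is per channel. The dynamic range is the 95th percentile minus
the baseline (5th percentile — the divider idles above zero). A pulse is a
run above the low threshold (10% of range) containing a sample above the
high threshold (20%): hysteresis. Three numerical choices matter:

* **Noise guards.** Thresholds never drop below 4–5 robust noise SDs
  (MAD of the quiet portion of the trace), so weak channels in noisy
  recordings do not dissolve into spurious runs. On clean signals the
  guards are inactive.
* **Gap merging.** Runs closer than `min_width` (0.1 s) merge only if the
  gap itself stays loaded (above the refinement floor); a mid-pulse noise
  dip merges, a spurious spike across a baseline gap does not.
* **Boundary refinement.** The hysteresis crossing necessarily lags the
  true loading onset (the low threshold sits 10% up the edge), which would
  bias stance durations by several samples. The onset is therefore walked
  back to the last sample at or below baseline + 1% of range, the offset
  forward symmetrically. On clean signals every recovered boundary is
  within one sample of the simulator's ground truth; durations, combining
  two boundaries, are within two.

Full loading is the first sample reaching 90% of the pulse's peak
amplitude; abruptness is full-load minus onset. Unevenness pairs each
pulse on left channel *k* with the nearest subsequent onset on right
channel *k* (and symmetrically), because the shift is drawn between
successive opposite-foot pulses; pairing across a missing pulse produces
an outlier near one full cycle, which the noise guards make rare.

Per-foot stance is reported both per channel and as the aggregate envelope
(union of the foot's pulse intervals). The phase-fraction recovery uses
the envelope; double support is the total left∧right envelope overlap per
cycle, measured over a whole number of cycles anchored midway between the
feet's first onsets so no overlap episode straddles the window edge.

## Statistics

`series_report()` implements the small-sample chain: arithmetic mean,
experimental standard deviation with $n-1$, standard mean deviation
$\sigma/\sqrt{n}$, and random error $S_c \cdot S_{md}$ with $S_c$ the
two-sided Student quantile at $n-1$ degrees of freedom and probability
level $\alpha$ (0.95 by default; the level is the *confidence* mass, i.e.
two-sided tail 0.05). `stats::qt` is the Student table. The Monte-Carlo
coverage of the resulting $\bar{m}_v \pm \Delta$ interval is 0.95 within
±0.02 at $n \in \{3, 5, 10\}$ over 2000 replications — exact in theory
for Gaussian repeats, verified empirically in the test suite. With a
single measurement the mean is reported and the error is `NA`.

## Gait-mode rules and anomaly flags

`compute_signature()` reduces a parameter table to: dominant sensor per
foot (amplitude argmax; ties to the lower channel index), left/right
amplitude ratio, mean stance asymmetry, per-pair unevenness imbalance
$|\overline{L_k{-}R_k} - \overline{R_k{-}L_k}|$, mean abruptness per
channel, and the step-period coefficient of variation (from envelope
onsets, robust to a single missed pulse).

`classify_mode()` scores each rulebook row: 2 points per matching
dominant sensor, 1 for the amplitude-ratio direction (balanced within
±10%), 2 for the imbalance state (shifted above 0.20 s — midway between
the rhythmic ≈0 and the pathological ≈0.3 s). Ties break by the fixed
rulebook order. The imbalance weight (2) intentionally exceeds the ratio
weight (1): the turnaround and straight-leg gaits share dominant sensors,
and the rhythm shift is the more reliable discriminator under noise. The
rulebook is data (a CSV), so the signatures can be edited without touching
code.

`flag_anomalies()` compares a signature with a normal baseline of the same
subject: `rhythm` when the step-period CV grows by more than 0.10;
`load_asymmetry` when the amplitude ratio moves more than 25% relative to
the baseline ratio; `phase_asymmetry` when the largest imbalance grows by
more than 0.25 s. Each score is deviation/threshold, so flags fire exactly
above score 1 and scores are monotone in the injected asymmetry. Without a
baseline, population defaults (ratio 1, imbalance 0, CV 0) are used with a
warning. The first recording labelled normal serves as the baseline in the
pipeline; there is no online learning.

## Pipeline and reproducibility

`run_pipeline()` drives simulate → extract → summarise → detect from one
flat `key: value` config (a deliberate minimal format — no YAML library is
required; writing and re-reading a config is byte-stable). A seed is
mandatory whenever simulation is configured; per-recording seeds are
derived deterministically from it. Identical config + seed reproduce every
data artifact (recordings, parameter tables, stats, detection JSON) byte
for byte. The manifest records the package version, the MD5 of the
serialised config, per-stage outputs, and the wall-clock timestamp — the
one field that legitimately differs between reruns, which is why the
manifest sits outside the byte-identity contract.

With several repeats, the statistics stage first averages each parameter
within a recording and then treats the repeats as the measurement series
(the three-repeat protocol); with a single recording the per-step values
form the series.

## Known limitations

* The resistance–load law is a monotone stand-in, not a characterised
  material model; only relative amplitudes are meaningful.
* The classifier is rule-based over seven encoded modes; an unseen gait is
  mapped to the nearest signature rather than rejected.
* Spatial parameters (stride length, speed) are out of scope — pressure
  sensors cannot measure them.
* Phase recovery assumes at least two stances per foot and a roughly
  stationary cadence within a recording.
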