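---
title: "From friction sounds to electrotactile stimulation: the texturestim pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From friction sounds to electrotactile stimulation: the texturestim pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texturestim)
```

## The problem

A hand prosthesis that restores motor function but no touch leaves its user
without texture perception. One minimal way to give some of it back is
sensory substitution through the auditory-like channel of friction sound: a
small microphone stroked across a surface picks up vibrations whose
spectral content depends on the surface micro-structure, and that content
is re-encoded as the pulse frequency of transcutaneous electrical nerve
stimulation (TENS) over the median nerve. The user feels a stimulation
whose *rate* varies with the texture being stroked — frequency is the only
information-carrying parameter, keeping amplitude, pulse shape and electrode
location free for other feedback channels.

`texturestim` is a desk-scale simulator of that whole loop. It lets you run
the signal chain on recorded or synthetic friction sounds, model the timing
of the pulse stimulator, and measure — with a simulated observer instead of
a human participant — how discriminable a set of texture signatures is
through this channel.

## The signal chain and its parameters

**Spectral stage** (`feature_trace()`). The audio signal is sampled at
6 kHz with 16-bit resolution (friction content for common textures lies
below 3 kHz). A 2048-sample FFT window slides in steps of 128 samples, a
nominal update interval of 128/6000 s ≈ 21.3 ms (~50 Hz). Before any
feature is computed, every bin below 20 Hz (including DC) and the bin
nearest the 50 Hz mains frequency are zeroed. The bin resolution at these
defaults is 6000/2048 ≈ 2.93 Hz. Two conventions are worth making explicit:

* Features weight bins by *magnitude*, not power, because the stimulation
  gate compares a summed magnitude against a millivolt threshold. A
  `weighting = "power"` switch exists for sensitivity analysis.
* The median frequency is the smallest bin-center frequency at which the
  cumulative retained magnitude reaches at least half the total (a "≥"
  convention; on an all-zero frame the feature is undefined and is treated
  as gate-off rather than NaN, so downstream logic is total).

No analysis window (i.e. a rectangular window) is the default, matching a
real-time embedded implementation; Hann is available. The counts→millivolt
scale is a calibration the hardware description leaves open; the default
maps a full-scale sample to a 3.3 V ADC reference (3300/32768 mV per
count) and is an explicit parameter everywhere it matters.

**Transduction** (`transfer_function()`, `gate()`). The median frequency
`medianf` maps linearly to stimulation frequency:

    stim = (medianf - lowerB) / scaling + 5   [Hz]

with `lowerB = 50` and `scaling = 10`. The +5 Hz offset doubles as the
output floor: very low pulse rates would stall the control loop, because
the stimulator only accepts a new command after delivering the pulse
promised by the previous one. Outputs are clamped to [5, 80] Hz (the
behaviour below the linear range is a floor clamp — a documented choice,
since a deployed system must do *something* there) and rounded to the
stimulator's integer-hertz grid. Stimulation is enabled only while the
total retained spectral magnitude strictly exceeds 300 mV, so silence and
background noise between strokes do not stimulate. Pulse amplitude is a
participant-specific comfort level on a 0.1–10 mA grid in 0.1 mA steps;
it is a plain input parameter, not a simulated psychometric calibration.

**Stimulator timing** (`schedule()`, `worst_case_latency()`). The
stimulator model is a discrete-event simulation with two constraints: a
20.6 ms serial (UART) command delay, and update-after-pulse — a command
visible during an ongoing pulse interval waits (latest command wins) until
that interval completes. The worst case is one full interval at the 5 Hz
floor plus the link delay: 20.6 + 200 = 220.6 ms, comfortably inside the
50–300 ms human reaction window to sensory stimuli. Three behaviours were
open and are fixed as follows: a newly activated train fires its first
pulse immediately at adoption (no dead first interval); deactivation lets
the already scheduled pulse complete (no truncation); commands arriving
while locked overwrite each other rather than queue. Event times are exact
(`adoption + k/f` within each command segment), never accumulated sums, so
pulse counts are deterministic. Pulses are biphasic, charge-balanced and
cathodic-first (−A then +A, 250 μs per phase), and the rendered current
trace of any train integrates to zero.

## The synthetic texture generator

`synth_stroke()` generates seeded friction-sound surrogates for four
canonical signatures, the defaults of `default_profiles()`:

| texture  | signature                       | default trajectory    |
|----------|---------------------------------|-----------------------|
| felt     | stable high median frequency    | 200 Hz constant       |
| sponge   | stable low median frequency     | 50 Hz constant        |
| silicone | ramps up during the stroke      | 100 → 350 Hz linear   |
| mesh     | fluctuating                     | random walk 50–250 Hz |

The felt/sponge assignment follows the reading under which felt is the
*higher*-frequency texture; the source material is internally inconsistent
on this point (its methods text swaps the two), so the assignment is a
configurable argument rather than a hard-coded fact.

The synthesis is an oscillator bank: 24 cosines with random phases and
fixed random frequency offsets inside the profile bandwidth (40 Hz by
default; 30 Hz for the 50 Hz texture, whose ±20 Hz band would otherwise
straddle both the 20 Hz cut and the 50 Hz notch), all sweeping
phase-continuously with the instantaneous center trajectory, plus
per-128-sample-block Gaussian center jitter and 50 ms raised-cosine edge
fades. A filtered-noise synthesis would serve equally — the pipeline's
median-frequency feature is insensitive to phase detail — but the
oscillator bank keeps the trajectory exact and avoids per-block filter
edge artifacts. The default RMS amplitude (3000 counts) puts the total
retained magnitude roughly an order of magnitude above the 300 mV gate, so
strokes gate on throughout and silence never does.

One subtlety deserves its own paragraph. A profile's `center_trajectory`
is defined as the **target measured median**, i.e. what the pipeline
should read, not merely where the band is placed. With a rectangular
analysis window the magnitude spectrum of a narrowband cluster has
1/distance leakage tails; the upper tail runs to Nyquist while the lower
tail is truncated at the 20 Hz cut, so the raw measured median sits a few
hertz *above* the band center (about +6.7 Hz for a 50 Hz band — almost the
whole ±15% fidelity budget at that frequency). The generator therefore
pre-compensates: it models the expected excluded-bin spectrum of the tone
cluster with Dirichlet kernels (tones combined in quadrature, as
random-phase components add), computes the model's half-mass median as a
function of band center, and inverts that curve (cached per geometry).
With this calibration the mid-stroke measured medians land within ±15% of
the target in well over 90% of seeded strokes for all deterministic
profiles.

Default stroke duration is 2 s with ±20% seeded jitter (manual stroking is
variable); paced evaluation sessions place one stroke every 10 s
(`stroke_schedule()`, `synth_session()`). What the generator does *not*
emulate: contact mechanics (stick–slip, pressure and velocity coupling),
background noise, and the occasional missing ramp of a sticky surface.
Passing tests therefore show that the *pipeline and its transduction
preserve and convey the four signature classes*, not that real recordings
of these materials would be classified equally well.

## The simulated experiment

`run_protocol()` replays the three-phase discrimination protocol on
synthetic strokes: a training phase (4 textures × 20 labelled strokes), a
with-feedback phase (responses followed by the true label) and a
without-feedback phase, each presenting every texture 20 times in seeded
random order with up to two extra repetitions on request. "Participants"
are seeded observer instances (`run_discrimination_study()`); human
results are psychophysical outcomes that software cannot reproduce, so the
harness measures the *informativeness of the stimulation channel* instead,
with inter-participant variance mapped onto seed variance.

The default `template_observer()` perceives only what the participant
perceived — the stimulation-frequency trace — and summarises each stroke
by three statistics (`trace_signature()`): median active frequency, trend
slope over normalised stroke time, and interquartile spread. These are the
minimal statistics separating flat-high / flat-low / ramp / fluctuating
signatures. Classification is nearest-template under per-feature scaling;
a repeat is requested when the distance margin `(d2 - d1)/(d1 + d2)` falls
below 0.2 (how humans decided to request repeats is unknowable, so this
rule is an explicit stand-in). During the with-feedback phase the true
texture's template is nudged toward the observed signature with weight
0.1; templates are frozen during the final phase.

At these defaults the simulated cohort's median without-feedback accuracy
is in the low 90s percent — above the 85% human benchmark, as expected
for an observer that never tires and strokes that never miss their
signature. Two controls bracket it: an oracle observer scores 100% with an
identity confusion matrix, and a uniform-random observer sits in the
binomial 25% chance band. Shrinking `default_profiles(separation = s)`
collapses all trajectories toward a common 150 Hz flat profile; accuracy
degrades monotonically, and the test suite probes s = 1, 0.12 and 0
because a sweep showed the observer still near ceiling at s = 0.2,
mid-range near s = 0.12, and chance-level at identity.

## Numerical choices and degenerate inputs

* WAV I/O is fixed to RIFF PCM mono 16-bit little-endian; anything else is
  rejected with the offending property named, never converted.
* Streams shorter than one FFT window produce an empty feature trace, not
  an error, so silent stubs flow through.
* The gate uses strict `>` at exactly 300 mV; the gate sum is taken *after*
  the 20/50 Hz exclusions, so mains hum cannot trigger stimulation, and
  "summing from 1" is read as bin index 1 (DC excluded).
* The 50 Hz removal zeroes the single nearest bin (≈49.8 Hz), with a
  configurable extra half-width for spread mains noise.
* Scheduling with a negative horizon, amplitudes off the 0.1 mA grid,
  non-finite medians into the transfer function, and overlapping session
  events all raise immediate parameter errors.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data generated at call time: strokes of 0.5–2 s at 6 kHz (78 analysis
windows per 2 s stroke), cohorts of 10 seeded participants × 80
without-feedback trials for the headline accuracy, 3 seeds × 40 trials per
separation level for the degradation check, 1000 random frames for the
feature oracles and 100 random command traces for the scheduler
invariants. A full run of the suite plus the acceptance script takes on
the order of two minutes on a single core.

## Known limitations

* The counts→mV calibration is a stated assumption; a different front end
  would shift the gate's effective sensitivity.
* The observer is deliberately simple; it neither fatigues nor learns
  across phases except through the explicit template update, so its
  accuracy is an upper-bound-flavoured proxy, not a prediction of human
  performance.
* The generator's leakage calibration assumes the default analysis
  geometry (2048/6 kHz, 20 Hz cut, 50 Hz notch); profiles played through a
  different geometry will realise slightly shifted medians.
* Statistical modelling of accuracy (mixed-effects models, post-hoc
  tests) is out of scope; the package reports descriptive summaries only.
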