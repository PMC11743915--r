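---
title: "Emulating a trigger box and its timing bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a trigger box and its timing bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Event-related analyses of neurophysiological recordings stand or fall with
event timing: an EEG deflection a few tens of milliseconds wide cannot be
averaged meaningfully if the markers that define time zero wobble by a
comparable amount.  Laboratories therefore interpose a *trigger box* — a
small device that watches a physical signal (the actual sound coming out of
the soundcard, the actual luminance change on the screen, the actual button
contact) and emits a TTL pulse into the acquisition system the moment an
event happens.  The pulse, not the stimulus software's timestamp, marks the
event.

`triggerbench` is a discrete-time software emulation of such a device — a
microcontroller trigger box whose firmware scans up to eight analog inputs
strictly sequentially — together with the measurement bench used to
characterize it: seeded stimulus generators, a virtual two-channel
digitizer, an onset-detection and epoch-realignment pipeline, and
latency/jitter/pulse-duration statistics.  Everything a physical bench
measures with cables and a digitizer card is reproduced here as a
deterministic, seeded simulation, so the device's timing laws can be stated
and tested exactly.

# The trigger state machine

Each trigger channel compares every ADC sample against a raw-count
threshold (strict `sample > threshold`; the firmware's threshold is a
unitless 10-bit count, 0–1023).  The per-tick rules, evaluated only at
sample instants:

* **Onset.** Idle + supra-threshold sample → output goes high, provided the
  *refractory period* since the previous onset has elapsed (suppression is
  silent: a refractory crossing neither fires nor extends anything).
* **Hold.** While in a pulse, each supra-threshold sample refreshes the
  last-crossing time.
* **Termination.** The output returns low at the first tick at which *both*
  the *minimum pulse duration* (since pulse start) and the *pulse
  increment* (since the last crossing) have elapsed.  Termination is
  evaluated before onset logic, so a still-supra sample at a termination
  tick extends only via the hold rule and never re-triggers within the same
  tick.

Because the rules fire only on ticks, realized durations are quantized to
the sample period $T_s$: a sustained input with minimum duration $D$ and
zero increment yields exactly $T_s \lceil D / T_s \rceil$ — at 6.25 kHz
($T_s = 160$ µs) a 10 ms setting produces 10.080 ms pulses, every time.
With $D = 0$ the smallest representable pulse is one sample period.

Switch channels (button presses, nurse-call cords) use a different rule:
one event per closure whose closed state persists at least the de-bounce
time (default 20 ms, a typical mechanical bounce scale), stamped at the
first closure of the stable run, gated by a refractory period.  The switch
spec does not constrain the output width, so the emitted pulse width is a
plain parameter (default 10 ms).

The per-sample semantics live twice in the package, deliberately: an
exported, readable R step function (`trigger_step()`) and a compiled scan
(`run_trigger()`) used by the device model.  The test suite holds a third,
independently written naive implementation and requires edge-for-edge
agreement of all three on randomized inputs.

## `dc` mode

The firmware distinguishes "oscillatory" from "DC" inputs only by signal
character; the emulator uses the same supra-threshold onset logic for both
and adds a polarity option (rising/falling through threshold) for
light-sensor use, where an event may be a *drop* in level.  No baseline
tracking is attempted — none is described for the device.

# The device model

The whole-device emulation adds what surrounds the state machine:

* **Front-ends.** A `half_wave` input feeds the signal straight to the
  unipolar 0–3.3 V ADC, so negative excursions are simply not captured
  (the half-wave-rectifier effect).  A `dc_biased` input first shifts the
  signal by $V_{CC}/2 = 1.65$ V so negative excursions become measurable.
  Quantization is 10-bit by default:
  $\mathrm{counts} = \min(\lfloor v / 3.3 \cdot 1024 \rfloor, 1023)$.
* **Sequential scan.** Tick $n$ occurs at $n T_s$; channel $i$ samples the
  *live* analog source at $n T_s + \sum_{j<i} c_j$ where $c_j$ is channel
  $j$'s processing cost.  There is no sample-and-hold, so two channels
  reading the same source can see different voltages.  A channel's output
  edge lands when its processing completes: its own sample time plus its
  own cost.  Two consequences follow exactly: with a common step crossing
  threshold just before a tick, channels 1 and 8 of an 8-channel device
  with $c = 16.7$ µs fire $7c = 116.9$ µs apart; with the crossing placed
  between their sampling instants, channel 8 detects one whole sample
  earlier and the difference becomes $7c - T_s = -43.1$ µs.  These are the
  only two values the offset can take, at any crossing phase — a property
  the suite tests.
* **Feasibility.** Per-channel costs default to 16.5 µs per trigger and
  0.5 µs per switch — the assignment consistent with the device's measured
  16–17 µs per-trigger processing time and with all three observed rate
  ceilings (6.25 kHz with eight triggers, 10 kHz with six triggers plus a
  switch, 50 kHz with one trigger).  A rate is feasible while the summed
  per-tick cost stays strictly below the sample period, i.e. while idle
  loops remain; `idle_fraction()` reports the headroom
  $1 - (\sum_j c_j + \mathrm{overhead}) / T_s$, floored at zero.
* **Rate menu.** The selectable rates divide the 50 kHz base rate by the
  prescaler chain $\{1, 2, 4, 5, 8, 10, 16, 20\}$ (50 down to 2.5 kHz).
  A naive divisor menu $\{1..8\}$ would contain 50/7 kHz, whose 140 µs
  period exceeds any 8-trigger cost in the 16–17 µs range — it would make
  7.14 kHz the 8-channel ceiling, contradicting the observed 6.25 kHz.
  The chain above is the menu consistent with every rate the device
  exhibits; it remains configurable.

# The measurement bench

`bench_latency()` reproduces the latency/jitter characterization
end-to-end:

1. The stimulus is an abrupt-onset **cosine-phase 100 Hz tone** — the
   first sample sits at $+A$, the most abrupt onset a playback chain can
   deliver — tapering to silence by 100 ms.  The taper is flat for 50 ms
   and then decays as a raised cosine (the taper's exact shape is not
   prescribed anywhere; this choice is smooth and band-limited).
2. 187 presentations are placed with i.i.d. uniform onset-to-onset
   intervals on [0.25, 1] s.  Onsets snap to the 44.1 kHz playback grid,
   which is incommensurate with the device tick, so onset phases are
   effectively uniform over the sample period.
3. The rendered trace is treated as the analog world: the device and the
   **100 kHz virtual digitizer** both read it through linear
   interpolation (an idealized reconstruction; real soundcards add their
   own filtering, which the emulation does not model).
4. Sound onsets are estimated from the digitized stimulus by
   **sample-to-sample change detection** (first $|\Delta v|$ above
   threshold, default 0.1 V, with a 100 ms dead time — longer than any
   stimulus envelope feature, shorter than the 250 ms interval floor) and
   then **group-corrected**: Woody-style iterative realignment of each
   1 ms-pre/5 ms-post epoch to the correlation-maximizing lag (± 2 ms)
   against the mean epoch, ties broken toward the smaller shift, full mean
   rather than leave-one-out, at most 10 sweeps.  This stops the estimates
   from riding on peri-threshold voltage noise.
5. TTL onsets come from `edge_times()`, which interpolates threshold
   crossings linearly between digitizer samples; latencies are the paired
   input-to-output differences (each input pairs with the nearest
   following output).

Because detection happens at the first tick after the threshold crossing,
the latency of an onset at uniform-random phase is uniform over one sample
period, and its standard deviation converges to $T_s/\sqrt{12}$: 46.2 µs
at 6.25 kHz, 5.8 µs at 50 kHz.  The bench's estimates carry small
additional variance from the 10 µs digitizer resolution at both ends.  At
$n = 187$ the sample standard deviation of a uniform variable has standard
error $\approx \sigma\sqrt{0.8/(4n)} \approx 1.5$ µs, which is the
Monte-Carlo tolerance the acceptance tests use (3 SE ≈ ±4.6 µs).

The bench's trigger settings: threshold 50 counts (≈ 0.16 V, well below
the 1 V tone), 10 ms fixed pulses, and a 200 ms refractory period — chosen
between the 100 ms stimulus envelope (so within-stimulus re-crossings
cannot re-trigger) and the 250 ms interval floor (so no stimulus is
swallowed).

`bench_pulse_duration()` is the pulse-length bench: 200 **independently
generated** 25 ms noise bursts (independence matters — with one burst
repeated, the last supra-threshold sample falls at the same waveform
position every trial and the duration statistics collapse).  In
fixed-duration mode every exact pulse is 10.080 ms and every digitized
measurement lands on the digitizer's 10 µs grid inside
{10.080, 10.090} ms.  With a 10 ms increment the pulse outlasts the burst:
duration ≈ burst span + quantized increment minus the random onset/offset
gaps.  One modelling honesty note: the burst noise is zero-mean and the
ADC unipolar, so the supra-threshold fraction of burst samples is below
one half for *any* positive threshold; at noise-to-threshold ratios of
32–64 it approaches 0.49 from below, and there the mean duration sits
stably near 34.6 ms with S.D. ≈ 0.32 ms.  The bench runs this on a single
trigger channel — duration statistics do not depend on how many other
channels are being scanned.

# ERP jitter smearing

The last module demonstrates *why* any of this matters.  A
distractor-minus-standard auditory difference wave is modelled as a sum of
Gaussian components on a 300 Hz grid — an MMN-like −3 µV peak at 175 ms
(40 ms width) and a P3a-like +5 µV peak at 300 ms (60 ms width); the
amplitudes and widths are illustrative defaults, not measurements.
Single trials are the template shifted by
$\mathrm{offset} + \mathcal{N}(0, \mathrm{jitter})$ plus 10 µV white
noise.  With a software-timestamped presentation chain whose audio latency
averaged 227 ms with 30.7 ms jitter, the software-locked average is both
*delayed* by 227 ms and *smeared*: its expectation is the template
convolved with the latency density, which for Gaussian components widens
each width $w$ to $\sqrt{w^2 + \sigma^2}$ and attenuates its peak by
$w/\sqrt{w^2+\sigma^2}$ (≈ 0.79 for the MMN, ≈ 0.89 for the P3a at
$\sigma = 30.7$ ms).  `smear_oracle()` computes that expectation by
quadrature, independently of the Monte-Carlo route, and the suite requires
the two to agree in sup-norm within 3 standard errors at $n = 5000$ —
run with the trial noise off, because the convolution claim concerns the
jitter mechanism, and with i.i.d. per-sample noise a 3-SE sup-norm bound
over ~240 grid points would fail by chance alone about 40% of the time.

`erp_demo()` contrasts hardware-locked (trigger-box) and software-locked
averages of the same trials at $n = 410$.  Peaks are measured after a
5-sample moving average (16.7 ms boxcar — standard practice before peak
picking; it attenuates a 40 ms component by under 1% while cutting
peak-picking noise roughly $\sqrt{5}$-fold).  The demo's latency-shift
tolerance (±30 ms ≈ 2 SE) reflects peak localization on a flattened
~50 ms-wide peak under residual noise of $10/\sqrt{410}$ µV, not the
uncertainty of the mean shift itself (which is only
$30.7/\sqrt{410} \approx 1.5$ ms).

# Units, conventions, numerical choices

* Absolute times (traces, schedules, pulse edges) are **seconds**;
  firmware durations (minimum pulse, increment, refractory, de-bounce,
  channel costs) are **µs**, matching the device's parameter menus;
  latency reports are **µs**; the ERP module works in **ms** and **µV**.
* Tick-time comparisons carry a 1 ps guard (`1e-6` µs) so that durations
  that are exact multiples of the sample period do not fall to
  floating-point rounding.
* Every stochastic generator takes an explicit seed and applies it
  locally (the caller's RNG state is untouched); identical configuration
  and seed reproduce traces bit-identically and report files
  byte-identically.
* Edge times inside the emulator are exact (continuous); quantization
  happens only where it does physically, in the virtual digitizer.
* Degenerate inputs: empty traces yield empty pulse trains; an
  all-sub-threshold trace never fires; fewer than two onsets are returned
  unchanged by group correction; a flat waveform reports peak amplitude 0
  at the window start.

# Problem sizes

The shipped tests run the benches at their full stated sizes — 187 tone
presentations, 200 bursts, 410 oddball events, 5000 Monte-Carlo epochs —
which completes in well under a minute in total; the oddball generator is
exercised at a reduced rendering rate (8 kHz) since its tests concern
schedule structure, not audio fidelity.

# What the simulation does and does not show

The generators emulate an idealized hardware bench: ideal step/tone/noise
sources, ideal linear-interpolation reconstruction, a noiseless digitizer,
and a device whose per-channel costs are exactly constant.  Real benches
add soundcard response, amplifier noise, digitizer jitter, and
firmware-cost variation (on physical hardware the 116.9 µs channel offset
itself fluctuates by a few µs; the emulator's is exact).  Passing tests therefore
validate the *timing laws* — quantization, sequential-scan offsets,
refractory algebra, uniform-phase jitter, convolution smearing — not the
analog idiosyncrasies of any particular laboratory setup.  Likewise the
ERP module demonstrates the statistical effect of latency jitter on
averages; it does not model a head, electrodes, or real EEG noise spectra.
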