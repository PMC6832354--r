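---
title: "Detecting odour-evoked EAG responses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting odour-evoked EAG responses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eagdetect)
```

## The signal and the problem

An electroantennogram (EAG) records the summed receptor potential of an
insect antenna. Odour contact produces a transient *negative* deflection
of roughly −1.8 to 0.5 mV whose spectral content sits below 10 Hz. On a
mobile sensing platform the recording additionally contains:

* **baseline drift** — slow wandering of the DC level (drying antenna,
  electrode polarisation) whose band overlaps the response band;
* **power-line hum** — a residual 50–70 Hz tone that survives analogue
  notch filtering;
* **motor noise** — broadband noise from motors/propellers, plus
  mechanical vibration transmitted to the antenna mount, which is
  concentrated at low frequencies.

Because the drift and the response share the sub-10 Hz band, the two
conventional remedies both fail: an absolute voltage threshold is crossed
or dodged as the baseline wanders, and a high-pass filter deep enough to
remove the drift also attenuates the response. (The package ships
`highpass_reference()`, a causal 2nd-order Butterworth, precisely to make
this failure mode reproducible; the filter family is a conventional
choice, applied forward-only as a real-time system would run it.)

## The detection pipeline

### Conditional EMA filter

The first stage is a direction-dependent exponential moving average with
smoothing factor $\alpha \in (0,1)$ and $y[0] = x[0]$:

$$
y[n] = \begin{cases}
\alpha\, x[n] + (1-\alpha)\, y[n-1], & x[n]-x[n-1] < 0\\[2pt]
(1-\alpha)\, x[n] + \alpha\, y[n-1], & \text{otherwise.}
\end{cases}
$$

With $\alpha > 0.5$, falling samples are tracked with weight $\alpha$
(fast) and rising samples with weight $1-\alpha$ (slow): negative
transients pass nearly intact while baseline recovery and upward noise
excursions are smoothed away. Two details are fixed deliberately:

* **Tie-break.** The falling branch requires a *strictly* negative
  difference; a zero difference takes the rising branch. On constant
  input both branches are fixed points, so the choice is observable only
  through which coefficient smooths a plateau; the strict inequality is
  implemented exactly as specified by the recurrence above.
* **Initialisation.** $y[0] = x[0]$, so the filter is exact on the first
  sample and a constant signal is reproduced exactly.
* The branch is decided on the *input* difference, never on the filter
  state, so the coefficient sequence is a function of the input alone.

Non-finite samples are rejected with an error — never propagated — and
$\alpha$ outside $(0,1)$ is a parameter error.

### D-Counter

The second stage slides a window of $w = \mathrm{round}(s_{win} \cdot
f_s)$ samples across the (filtered) trace at stride 1. Within a window,
the first sample is the *reference*; the count is the number of samples
strictly below the reference, and the deepest drop (initialised at 0) is
tracked. Unless the deepest drop reaches the relative threshold $th < 0$,
the count is reset to 0. Counts therefore lie in $[0, w-1]$, and a count
is attributed to the window's reference index; causally it becomes
available one window later, so the detection latency equals $s_{win}$.

Properties worth stating (each is a test in the suite):

* **Translation invariance.** Only within-window differences enter, so a
  constant baseline offset — the drift, on the window timescale — cannot
  change any count. This is the core advantage over the fixed threshold.
* **Threshold monotonicity.** Deepening $th$ can only zero more windows:
  counts are non-increasing in $|th|$.
* **Time asymmetry.** The counter looks for *drops*; reversing the trace
  changes the output. The fixed threshold, an elementwise comparator,
  commutes with time reversal.
* $th \ge 0$ is rejected at validation: the deepest drop starts at 0, so
  a non-negative threshold would fire the reset on every window and make
  the detector inert.

### Fixed threshold (baseline method)

`fixed_threshold()` emits 1 wherever the voltage is strictly below an
absolute level `th_abs` (e.g. −0.5 mV). It is included as the comparison
baseline and inherits full sensitivity to drift.

### From counts to events

The counter trace is turned into discrete detections by
`extract_events()`: maximal runs with counts $\ge c_{min}$ become events,
and events separated by less than a merge gap are fused. Defaults:
$c_{min} = \lceil w/2 \rceil$ (at least half the window dropping below
the reference, robust to single-sample noise) and a 0.3 s merge gap
(shorter than the minimum 1 s inter-puff interval of the protocols, long
enough to absorb ringing of a single response). Both are configurable;
neither is prescribed by the counter itself, so they are reported in
every run manifest.

`match_events()` scores events against the ground-truth puff train by
greedy one-to-one matching in time order. A stimulus claims the earliest
unclaimed event whose *interval* overlaps `[onset, onset + tol_s]` with
`tol_s = 0.5` s (odour transport plus detector latency). Overlap rather
than onset-containment is used deliberately: the refractory merge can
fuse a short noise blip onto the front of a true detection, shifting the
merged event's onset slightly before the valve trigger while the interval
still covers the response; onset-only matching would score such a
clearly-detected response as a miss.

## Decimation and spectral estimation

Recordings are acquired at high rates (10 kHz class) but the pipeline
runs at 100 Hz: the response band ends below 10 Hz, and a lower rate
means less computation and lower latency on an embedded controller.
`decimate_trace()` applies an anti-aliasing FIR low-pass (Hamming-window
design, cut-off at 0.8× the target Nyquist, applied forward and backward
for zero phase) before selecting every q-th sample, staging large factors
through steps of at most 10. Without this, 50–70 Hz hum would alias
straight into the response band at 100 Hz. A `method = "subsample"`
switch provides naive picking for fidelity experiments with acquisition
chains that resample naively; the aliasing difference between the two is
itself a regression test.

`psd_welch()` estimates one-sided power spectral densities by Welch's
method: 1 s Hann-windowed segments (1 Hz resolution), 50% overlap,
per-segment demeaning, density scaling. The estimator is checked against
single-tone localisation and Parseval consistency (spectral integral ≈
variance within 5%). One practical caveat the test suite encodes: with
per-segment demeaning, power below one segment-reciprocal is removed, so
sub-hertz components (drift) must be characterised with longer segments.

## Evaluation metric

Detection quality is the **maximum lagged cross-correlation**: the
Pearson correlation between detector output and the binary valve-trigger
waveform, maximised over integer lags within ±2 s. The lag absorbs the
(unknown, roughly constant) response and detector latency; Pearson
normalisation makes the metric invariant to affine rescaling, so binary
triggers and integer counts are comparable. Detector outputs enter
*as-is* (binary for the fixed threshold, counts for the D-Counter);
binarising the counter first is possible but was not adopted, since
normalisation already removes the scale and the count magnitude carries
depth information. Constant inputs are a defined error (zero variance),
not a NaN.

`compare_variants()` runs {raw, EMA} × {fixed, D-Counter} on one trace
and tabulates the coefficients; `run_benchmark()` repeats this over
seeds, puff frequencies and window sizes.

## The synthetic generator

No public EAG recordings exist for this setting, so the package ships a
seeded generator (`sim_config()` / `generate_eag()`) that emulates the
four recording conditions: motors off/on × odour absent/present. Drift
and hum are present in all conditions (they originate in the electrode
and the mains); broadband and vibration noise only with motors on;
responses only with odour on. Components draw from independent
substreams of the master seed, so the full trace is exactly the
superposition of its isolated components and toggling one never
reshuffles another.

Defaults, with the reasoning behind each value:

| component | default | rationale |
|---|---|---|
| puff protocol | 10 puffs, 200 ms, at 0.25/0.5/1 Hz | the stimulation protocol of the experiments being emulated |
| response kernel | biexponential, rise 0.05 s, decay 0.3 s | not specified by the source experiments; chosen so a single response lasts a few hundred ms and >90% of a pulse train's power sits below 10 Hz (both verified in tests) |
| per-puff amplitude | uniform in [−1.5, −0.7] mV | inside the observed −1.8…0.5 mV single-response range, with pulse-to-pulse variability emulating the weak responses seen in real trains |
| response latency | 0.25 s after valve onset | odour transport from valve to antenna through delivery tubing at 1 L/min (order 0.3 m at under 1 m/s) plus receptor latency; also consistent with a causal detector whose event can only trail the trigger |
| drift | random walk, 0.2 mV/√s, reflected at ±0.5 mV; optional slow sinusoid | drift overlaps the response band by construction; the bound keeps the background clear of response amplitudes |
| hum | 0.1 mV at 60 Hz, random phase | residual mains interference after analogue notch filtering |
| broadband | white, SD 0.25 mV | motor/electronics noise; calibrated (Monte Carlo over 20 seeds) so that with odour off, well under 1% of samples fall below −1.0 mV |
| vibration | band-limited < 25 Hz, SD 0.15 mV | propeller/frame vibration is mechanically low-frequency; unlike the white component it survives decimation and contaminates the response band, which is what makes the *unfiltered* D-Counter noisy on motors-on data |

Generation runs at 1000 Hz — hum must exist at its true frequency, which
requires a rate above twice 50–70 Hz — and the analysis pipeline
decimates to 100 Hz, mirroring the acquisition chain of the real
experiments. `sim_config_drifting()` is a preset for the classic
absolute-threshold failure case: ±0.5 mV sinusoidal drift with weak
puffs, where a response landing on a positive drift excursion stays above
−0.5 mV absolute but keeps its full relative depth.

**What the generator does not model:** plume transport and intermittency
(puffs arrive exactly on schedule), response adaptation and antenna
fatigue across a train, amplifier saturation, motion artefacts from
flight manoeuvres, and any coupling between motor throttle and noise
level. Passing tests on this generator therefore demonstrate the
pipeline's behaviour under the *stated* noise model, not performance on
any particular recorded dataset — per-animal coefficients from real
recordings cannot be reproduced without the recordings themselves.

## Benchmark problem sizes

The packaged benchmark uses 20 generator seeds × 3 puff frequencies ×
2 window sizes (120 pipeline runs of 12–40 s of signal each), which runs
in well under a minute; the test suite uses the same scale. These sizes
give stable medians and interquartile ranges for the four-variant
comparison while remaining comfortable to re-run interactively.

## Parameter summary

| parameter | meaning | default | notes |
|---|---|---|---|
| `alpha` | EMA smoothing factor | 0.7 | 0.7 and 0.9 are the conventional settings; 0.7 tracks drops faster |
| `s_win` | D-Counter window (s) | 0.1 / 0.2 | equals detection latency; 10–20 samples at 100 Hz |
| `th` | D-Counter relative depth (mV) | −0.5 | −0.5 to −0.3 are typical; must be < 0 |
| `th_abs` | fixed threshold level (mV) | −0.5 | absolute, hence drift-sensitive |
| `c_min` | event count threshold | ⌈w/2⌉ | half-window of drops |
| `merge_gap_s` | refractory merge (s) | 0.3 | below the 1 s minimum inter-puff interval |
| `tol_s` | match tolerance (s) | 0.5 | transport + window latency |
| `lag_max_s` | correlation lag search (s) | 2 | covers all latencies at every puff frequency |

## Known limitations

* The D-Counter's window reference is a single sample; a sharp noise
  spike at the reference position biases a whole window. The conditional
  EMA stage is what makes this tolerable in practice.
* Event extraction (`c_min`, merge gap) is an operationalisation layered
  on top of the counter — the counter itself only produces counts — and
  other downstream rules are possible; all parameters are surfaced and
  logged.
* Decimation assumes integer rate ratios; non-integer resampling is out
  of scope.
* The generator's noise amplitudes are calibrated to qualitative
  descriptions of the recording conditions, not to measured noise
  spectra of any specific airframe.
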