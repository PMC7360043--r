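---
title: "Emulating a rodent constant-current tES stimulator: models, arithmetic and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a rodent constant-current tES stimulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tessim)
```

## What is being emulated

`tessim` is a software twin of an open-hardware constant-current generator
for transcranial electrical stimulation (tES) in rodents. The physical
device drives 10–250 µA through a head-mounted electrode from a 10-bit
PWM-controlled current source (one register count = 0.25 µA, 256 µA full
scale), ramps the current linearly at the start and end of a session to
avoid sensory artifacts, monitors the electrode impedance against a
user-set warning threshold, and can be driven over a serial link for
oscillatory or pulsed variants. The package reproduces that behaviour in
four layers:

1. **Firmware core** — the integer arithmetic and the state machine the
   microcontroller runs, on a discrete 1 ms time base.
2. **Serial protocol** — the single-letter command grammar, hand-check
   discipline, error codes and telemetry frame dialect, over an in-memory
   byte transport.
3. **Analog plant** — a first-order model of the output stage with dead
   time, compliance-voltage saturation and seeded measurement noise.
4. **Characterization** — the measurement protocols used to qualify the
   hardware (step response, 26-level accuracy/precision), re-run against
   the emulator.

The point of the twin is that the device's *quantization guarantees* — the
fade-timing error bound and the display-arithmetic error envelope — are
properties of the integer arithmetic alone, so they can be verified
exhaustively in software, while the analog figures (dead time, settle
times, nanoampere accuracy) depend on the physical output stage and enter
the model only as configurable parameters.

## Fixed-point arithmetic and its error surfaces

**Current conversion.** The set-point register holds `I / 0.25 µA` counts.
All conversions go through exact integer arithmetic; `counts_to_current()`
∘ `current_to_counts()` is the identity on every representable current.

**Fade scheduling.** A fade ramps the register one count per sample period.
For a plateau current $I$ (µA) and configured fade duration $D$ (s) the
firmware stores the period as an integer,

$$\mathrm{SampleRate} = \mathrm{round}\!\left(\frac{250\,D}{I}\right)\ \mathrm{ms},$$

so the executed ramp lasts $4I \cdot \mathrm{SampleRate}$ ms rather than
exactly $D$. `rounding_error_surface()` evaluates the signed error for all
241 × 59 = 14,219 valid settings:

```{r}
surf <- rounding_error_surface()
max(abs(surf$error_s))
surf[which.max(abs(surf$error_s)), ]
```

The maximum is 0.492 s (at 247 µA, 41 s), inside the device's advertised
0.5 s bound. The rounding mode matters here: truncating the division
instead of rounding to nearest would push the error towards a full sample
period per step (about 1 s at 249 µA) and break the bound, which is why
the emulator rounds half-up — the only mode consistent with the bound.

**Display arithmetic.** The displayed load voltage derives from the 10-bit
ADC code as $0.29296875\,D_{val}$ decivolt ($V_{dd} = 5$ V through the
divide-by-six input amplifier: $5 \times 6 \times 10 / 1024$). A
floating-point multiply is unavailable on the microcontroller, so the
firmware computes $\mathrm{round}(2 D_{val} / 7)$ instead.
`display_error_components()` splits the resulting error exactly into a
coefficient-approximation part, linear in the code, and an integer-rounding
part with period 7 in the code:

```{r}
err <- display_error_curve()
range(err$rounding_error_V)          # +/- 3/70 V, peak-to-peak 6/70
err$total_error_V[err$d_val == 1023] # -0.77 V at full scale
max(abs(err$total_error_V))          # 0.78 V, attained at code 1020
```

The worst total error over all codes is 0.783 V at code 1020 — slightly
larger than at the last code 1023 (0.771 V), because the rounding residue
at 1020 adds to the approximation error while at 1023 it partially
cancels.

The divider ratio is taken as 6, which is what reproduces the 0.293
coefficient; a nominal 3.3 ratio would give 0.161 and is inconsistent with
the rest of the arithmetic.

## The state machine

`tes_device()` holds phase (`IDLE → FADE_IN → STIM → FADE_OUT → DONE`,
with `PAUSING/PAUSED/RESUMING` branches), the set-point register, and the
remaining plateau seconds. Clocks: the fade timer at the computed sample
period; the countdown at 1000 ms of *plateau* time (so pausing freezes
it); display refresh at 250 ms, which recomputes voltage, current and
impedance from the synthesised ADC codes and drives the buzzer warning
whenever the impedance exceeds the configured threshold; telemetry at
100 ms, emitting `<prefix><Z>KR` frames with prefix `+` (fade-in), `*`
(stimulating), `#` (paused), `-` (fade-out).

Two behaviours are deliberate design choices rather than documented
firmware facts. First, resuming from a pause replays the full configured
fade-in; only the pause-side fade-out is documented, and the symmetric
ramp is the safer interpretation for an awake, restrained animal. Second,
the battery indicator is a plain threshold on the source voltage
(default 7.2 V) because the hardware's divider values are not part of the
model.

Conservation properties the tests enforce: fade increments sum exactly to
the plateau register value; fade-out mirrors fade-in; total plateau
milliseconds equal `duration_s × 1000` across arbitrary pause/resume
sequences; `remaining_s` never goes negative and decreases only during
`STIM`.

## Serial protocol

Commands are `I<counts>` (write register), `+`/`-` (one count up/down,
clamped at 0 and 1000, never wrapping), `A` (read register), `v`/`i` (raw
10-bit ADC codes). The device echoes the first character of every
successful command (the hand-check); the host must not send the next
command before receiving it. Errors are the literals `ENOTCMD` (unknown
command), `EOOL` (value over the 1000-count/250 µA ceiling) and `EOFBR`
(receive-buffer overflow).

The wire details the hardware documentation leaves open are fixed here as:
carriage-return terminator, an 8-octet receive buffer (the longest valid
frame, `I1000` plus terminator, fits; anything longer overflows), reply
framing as hand-check character + ASCII decimal payload, and a
computer-mode ceiling equal to the standalone maximum. `+`/`-` are honored
in computer-controlled mode only.

## Analog plant

After each set-point change, delayed by the dead time $t_d$, the delivered
current relaxes as

$$I(t) = I_{sp} + (I_{init} - I_{sp})\,e^{-(t - t_d)/\tau},$$

integrated exactly between change points (no discretization error), then
scaled by an optional gain (mis-calibration) factor, plus seeded white
Gaussian measurement noise, and finally clamped to the compliance ceiling
$I \le V_{comp}/R(t)$ (a current source hitting its 30 V rail saturates;
it does not error). Noise is measurement noise on the recorded trace: it
does not feed back into the dynamics and is not clamped at zero, so a
zero set-point with noise has a symmetric, unbiased error distribution.

Defaults: $t_d$ = 14.21 ms (the measured serial-transfer latency) and
$\tau$ = 194.5 ms. The time constant is back-derived from the measured
99 % settle time, $(909 - 14.21)/\ln 100$; the output low-pass filter
alone (4.5 Hz cut-off) would predict $\tau \approx 35$ ms, several times
faster than the measured response, so the measured value is the default
and both are ordinary configuration. Note the two published settle times
(909 ms to 99 %, 1580.58 ms to 99.9 %) are mutually inconsistent under a
single first-order $\tau$ (their delay-corrected ratio should be 1.5);
neither is treated as ground truth for the other, and the package's own
settle-time checks use the closed forms $t_d + \tau\ln 100$ and
$t_d + \tau\ln 1000$ on synthetic traces instead.

Loads are resistors, series-RC pairs (the resistive part is what enters
the voltage and compliance computation at a step), or piecewise-linear
resistance profiles for scenarios like an electrode drifting above the
warning threshold.

## Characterization protocols

`run_step_protocol()` replays the 0 ↔ full-scale switching paradigm:
per rising edge it records the response time (first sample above 0.1 µA
after the command — no interpolation, so the estimate carries up to one
sample of positive bias), the 99 %/99.9 % settle times ("enter and stay in
band", a criterion chosen to be robust to noise re-crossings), and a
Levenberg–Marquardt fit of the first-order-with-dead-time model
(`minpack.lm`). On noiseless synthetic edges the fit recovers $\tau$ and
$t_d$ to better than 1 %; at 1 % noise, better than 5 %.

`run_accuracy_precision_protocol()` replays the 26-level calibration:
set-points 0–250 µA in 10 µA steps, 5 s dwells in randomized order,
50 repetitions, analysing the last 0.5 s of each dwell at 100 Hz.
*Accuracy* is defined as the signed mean of the repetition-mean errors and
*precision* as the SD across repetition means — the published report gives
both figures without formulas, and these definitions reproduce their
orders of magnitude (a 10 nA sample noise gives a per-mean precision of
$10/\sqrt{50} \approx 1.4$ nA). On a noiseless, perfectly calibrated
emulator every tested level is a multiple of 0.25 µA, hence exactly
representable, and the measured accuracy is zero to below a picoampere
(the residual is the tail of the exponential transient inside the 0.5 s
window, about $250\,e^{-4.5/0.1945}$ µA).

## What the synthetic data does and does not show

The generator emulates quantization, timing, protocol framing, first-order
dynamics, compliance saturation and white measurement noise. It does not
emulate electrode electrochemistry, PWM ripple, drifting calibration,
1/f noise or temperature effects — so a passing accuracy/precision test
validates the *pipeline* (definitions, windowing, aggregation), not the
physical device's nanoampere figures, which remain hardware measurements.
The same separation applies to the response time: the emulated value is
the configured dead time plus discretization, by construction.

## Problem sizes and numerics

The test suite runs the full 14,219-cell fade grid and all 1024 display
codes exactly; step-edge checks use 1 kHz traces of 3 s; the acceptance
protocol runs the full 26 × 50 design at 100 Hz (about 650,000 samples,
simulated segment-exactly in a few seconds). Sessions in the state-machine
tests use 10 s plateaus with 2 s fades, which exercise every clock
boundary in 14 s of simulated time. All randomness (noise streams,
randomized level order, property-test draws) is seeded; traces and reports
with equal seeds are bit-identical, and the plant's seeded noise stream
saves and restores the session RNG state so it never perturbs user code.

## Known limitations

- The plant is strictly first-order; overshoot or higher-order dynamics in
  a real output stage would be invisible to `fit_first_order()` beyond a
  worse residual.
- `detect_response_time()` is sample-resolution limited by design
  (matching the original measurement protocol); sub-sample interpolation
  is deliberately not applied.
- The serial transport models framing and ordering, not baud-rate timing,
  so the maximum sustainable command rate of a physical link must be
  validated on hardware.
- Negative currents (alternating or random-noise stimulation) are outside
  the deliverable range of the modelled hardware and are rejected at the
  waveform layer.
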