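# tessim

A software twin of an open-hardware constant-current transcranial
electrical stimulation (tES) generator for rodent research. The physical
device delivers 10–250 µA tDCS (and oscillatory/pulsed variants) through a
head-mounted electrode; `tessim` reproduces its firmware, serial protocol
and analog output stage in software, so that stimulation protocols, host
control code and analysis pipelines can be developed, tested and verified
without hardware — and so that the device's quantization guarantees can be
checked exhaustively rather than by spot measurement.

It is aimed at labs running rodent tES experiments (protocol design,
impedance-warning scenarios, pause/resume logistics), at developers of
host-side control software (the full command grammar runs against an
in-memory device), and at anyone characterizing such a current source
(the measurement protocols ship as reusable pipeline functions).

## What is modelled

**Firmware core.** A 10-bit set-point register at 0.25 µA/count. Fade
ramps advance one count per sample period, with the period stored as an
integer: `SampleRate = round(250·D/I)` ms for fade duration `D` (s) and
current `I` (µA). The executed ramp therefore lasts `4·I·SampleRate` ms,
not exactly `D` — an error that is bounded by 0.5 s over the entire valid
settings grid. The displayed load voltage approximates the exact
`0.29296875·Dval` decivolt per ADC code by the integer form
`round(2·Dval/7)`. A 1 ms discrete clock drives the state machine
(fade-in / plateau with per-second countdown / fade-out, pause and
resume), the 250 ms display refresh with impedance computation and buzzer
warning, and 100 ms telemetry frames (`*25KR` = 25 kΩ while stimulating).

**Serial protocol.** Commands `I<counts>`, `+`, `-`, `A`, `v`, `i`;
hand-check echo of the first character before the next command may be
sent; error literals `EOFBR`, `ENOTCMD`, `EOOL`; device and host ends run
over an in-memory loopback transport.

**Analog plant.** First-order response with dead time,

    I(t) = I_sp + (I_init − I_sp)·exp(−(t − t_d)/τ),

integrated exactly between set-point changes (defaults t_d = 14.21 ms,
τ = 194.5 ms), with gain error, seeded Gaussian measurement noise, and a
30 V compliance clamp (`I ≤ V/R`).

**Characterization.** The step-response protocol (repeated 0 ↔ 250 µA
edges at 1 kHz: response time over 0.1 µA, 99 %/99.9 % settle times,
first-order model fit) and the accuracy/precision protocol (26 levels
0–250 µA × 50 randomized repetitions, last 0.5 s of each 5 s dwell at
100 Hz).

## Worked example

```r
library(tessim)

# worst-case fade-timing error over every valid standalone setting
surf <- rounding_error_surface()
surf[which.max(abs(surf$error_s)), ]
#>      current_uA fade_s error_s
#> 9637        247     41  -0.492

# step response of the default plant, measured like the hardware protocol
p  <- plant_params()     # tau 194.5 ms, dead time 14.21 ms
tr <- simulate_response(data.frame(time_ms = 0, setpoint_uA = 250),
                        p, load_model(), fs_hz = 1000, t_end_ms = 3000)
detect_response_time(tr)     # 15  (dead time + one 1 kHz sample)
settle_times(tr, 250)
#>  settle_99 settle_999
#>        910       1358
fit <- fit_first_order(tr)   # recovers tau = 194.50, t_delay = 14.21

# 26 x 50 accuracy/precision protocol with 10 nA measurement noise
rep <- run_accuracy_precision_protocol(plant_params(noise_sd_nA = 10,
                                                    rng_seed = 7))
head(rep$table, 3)
#>   setpoint_uA accuracy_nA precision_nA n_reps
#> 1           0   0.1859213     1.290617     50
#> 2          10   0.1233321     1.533039     50
#> 3          20  -0.3797877     1.507275     50
```

The fade error peaks at −0.492 s (247 µA, 41 s fade), inside the 0.5 s
bound. The settle times sit within one sample of the closed forms
`t_d + τ·ln(100)` and `t_d + τ·ln(1000)`. With 10 nA sample noise the
per-level precision lands near `10/√50 ≈ 1.4` nA, the SD expected for
means of 50-sample windows, and the accuracy is statistically zero.

A standalone session end to end, with telemetry and a drifting electrode:

```r
drift <- load_model("PIECEWISE_PROFILE",
                    profile = data.frame(time_ms = c(0, 14000),
                                         resistance_kohm = c(20, 160)))
run <- standalone_run(stim_settings(10, 10, 2, 2, 150,
                                    telemetry_enabled = TRUE),
                      load = drift)
subset(run$events, event == "warning")   # buzzer after 150 kOhm is crossed
```

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "tessim.R", package = "tessim")` with subcommands
`stimulate`, `drive`, `characterize`, `analyze` and `fixtures`, plain-text
`key = value` configs, and CSV outputs.

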