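Package: tessim
Title: Software Twin of a Constant-Current Transcranial Electrical
    Stimulator for Rodent Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Firmware-faithful emulation of an open-hardware constant-current
    transcranial electrical stimulation (tES) generator for rodent studies:
    a discrete-time device state machine with fixed-point current, voltage
    and impedance arithmetic, an RS232-style command protocol with
    hand-check discipline and telemetry frames, a configurable first-order
    analog output-stage model with dead time and compliance-voltage
    saturation, host-side waveform drivers for tDCS variants, and a
    characterization pipeline for response-time, step-response and
    accuracy/precision protocols, including the fade-scheduling and
    display-arithmetic quantization error surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
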