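#' Conversion constants of the output stage
#'
#' Collects the fixed-point conversion factors used throughout the firmware
#' emulation. One PWM count corresponds to 0.25 uA of delivered current
#' (10-bit register, 256 uA full scale), so the effective sense resistance is
#' `(vdd_V / 1024) / 0.25e-6` ohms. The displayed voltage uses the exact
#' per-count step `vdd_V * divider_ratio_H * 10 / 1024` decivolt (0.29296875
#' with the 5 V supply and the divide-by-six differential amplifier) and its
#' firmware integer approximation 2/7 decivolt per count.
#'
#' @param vdd_V supply / ADC reference voltage in volts.
#' @param divider_ratio_H attenuation of the differential amplifier in front
#'   of the load-voltage ADC channel.
#' @return A list of class `"tes_constants"` with elements `uA_per_count`,
#'   `r_sense_total_ohm`, `dV_per_count_exact`, `dV_per_count_approx`,
#'   `vdd_V`, `divider_ratio_H`.
#' @examples
#' conversion_constants()$dV_per_count_exact  # 0.29296875
#' @export
conversion_constants <- function(vdd_V = 5, divider_ratio_H = 6) {
  stopifnot(vdd_V > 0, divider_ratio_H > 0)
  out <- list(
    uA_per_count       = 0.25,
    r_sense_total_ohm  = (vdd_V / 1024) / 0.25e-6,
    dV_per_count_exact = vdd_V * divider_ratio_H * 10 / 1024,
    dV_per_count_approx = 2 / 7,
    vdd_V = vdd_V,
    divider_ratio_H = divider_ratio_H
  )
  class(out) <- "tes_constants"
  out
}

# integer round-half-up of num/den for non-negative integer num, positive den;
# exact (no floating point), matches the firmware's integer declaration
.div_round_half_up <- function(num, den) {
  q <- num %/% den
  r <- num %% den
  q + as.integer(2 * r >= den)
}

# round half away from zero for numeric x (positive use here -> half up)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a current in microamperes to PWM register counts
#'
#' One count is 0.25 uA; values are rounded to the nearest count
#' (halves away from zero).
#'
#' @param i_uA current in uA, within `[0, 255.75]`.
#' @return Integer count(s) in `[0, 1023]`.
#' @examples
#' current_to_counts(0.25)  # 1
#' current_to_counts(200)   # 800
#' @export
current_to_counts <- function(i_uA) {
  if (any(!is.finite(i_uA)) || any(i_uA < 0) || any(i_uA > 255.75))
    stop("current must lie in [0, 255.75] uA", call. = FALSE)
  as.integer(.round_half_up(i_uA / 0.25))
}

#' Convert PWM register counts to a current in microamperes
#'
#' @param counts integer count(s) in the 10-bit range `[0, 1023]`.
#' @return Current in uA (`counts * 0.25`).
#' @examples
#' counts_to_current(1)     # 0.25
#' counts_to_current(1000)  # 250
#' @export
counts_to_current <- function(counts) {
  counts <- .check_counts(counts)
  counts * 0.25
}

.check_counts <- function(counts, what = "counts") {
  if (any(!is.finite(counts)) || any(counts != floor(counts)) ||
      any(counts < 0) || any(counts > 1023))
    stop(what, " must be integers in the 10-bit range [0, 1023]", call. = FALSE)
  as.integer(counts)
}

#' Integer fade sample rate
#'
#' The fade-in/fade-out ramp advances one 0.25 uA step per sample, so the
#' firmware derives the sample period as `250 * fade_s / current_uA`
#' milliseconds, stored as an integer (rounded to nearest, halves up).
#' The integer declaration is the source of the fade-duration rounding
#' error bounded by 0.5 s.
#'
#' @param current_uA plateau current in uA (integer, 10-250).
#' @param fade_s fade duration in seconds (integer, 2-60).
#' @return Integer sample period in ms, at least 1.
#' @examples
#' compute_sample_rate(250, 10)  # 10 (exact)
#' compute_sample_rate(200, 10)  # 13 (12.5 rounds up)
#' @export
compute_sample_rate <- function(current_uA, fade_s) {
  if (any(current_uA <= 0)) stop("current must be positive", call. = FALSE)
  stopifnot(all(current_uA == floor(current_uA)), all(fade_s == floor(fade_s)),
            all(fade_s > 0))
  pmax(1L, .div_round_half_up(as.integer(250 * fade_s), as.integer(current_uA)))
}

#' Fade-in step schedule
#'
#' Returns the full ramp of 0.25 uA steps for a fade-in to `current_uA`:
#' `4 * current_uA` steps, one sample period apart, the k-th step raising the
#' set-point register to k counts. The fade-out schedule is the exact time
#' reversal (`direction = "out"`).
#'
#' @param current_uA plateau current in uA.
#' @param fade_s configured fade duration in s.
#' @param direction `"in"` (ramp 1 -> full) or `"out"` (full-1 -> 0).
#' @return A data.frame with columns `time_ms` and `setpoint_counts`.
#' @export
fade_step_schedule <- function(current_uA, fade_s, direction = c("in", "out")) {
  direction <- match.arg(direction)
  sr <- compute_sample_rate(current_uA, fade_s)
  n <- 4L * as.integer(current_uA)
  counts <- if (direction == "in") seq_len(n) else rev(seq_len(n)) - 1L
  data.frame(time_ms = sr * seq_len(n), setpoint_counts = counts)
}

#' Fade duration error induced by the integer sample rate
#'
#' Actual fade duration is `4 * current_uA` steps times the integer sample
#' period; this returns its signed deviation from the configured duration.
#'
#' @inheritParams compute_sample_rate
#' @return Signed error in seconds.
#' @examples
#' fade_duration_error(250, 30)  # 0, sample rate divides exactly
#' fade_duration_error(200, 10)  # +0.4
#' @export
fade_duration_error <- function(current_uA, fade_s) {
  sr <- compute_sample_rate(current_uA, fade_s)
  4 * current_uA * sr / 1000 - fade_s
}

#' Displayed load voltage, exact reference
#'
#' Reference (rational) value of the displayed voltage for an ADC code:
#' `d_val * vdd * H * 10 / 1024` decivolt, i.e. 0.29296875 dV per count with
#' the default 5 V reference and divide-by-six amplifier.
#'
#' @param d_val ADC code(s) in `[0, 1023]`.
#' @param const a [conversion_constants()] list.
#' @return Voltage in decivolt.
#' @export
display_voltage_exact <- function(d_val, const = conversion_constants()) {
  d_val <- .check_counts(d_val, "d_val")
  d_val * const$dV_per_count_exact
}

#' Displayed load voltage as the fixed-point firmware computes it
#'
#' The microcontroller has no floating point, so the per-count step
#' 0.29296875 dV is approximated by 2/7 and the result rounded to an integer
#' decivolt: `round(2 * d_val / 7)`, halves up. Computed here in exact
#' integer arithmetic. Monotone non-decreasing in `d_val`.
#'
#' @param d_val ADC code(s) in `[0, 1023]`.
#' @return Integer decivolt value(s).
#' @examples
#' display_voltage_firmware(7)     # 2  (exact value 2.05 dV)
#' display_voltage_firmware(1023)  # 292 (exact value 299.7 dV)
#' @export
display_voltage_firmware <- function(d_val) {
  d_val <- .check_counts(d_val, "d_val")
  .div_round_half_up(2L * d_val, 7L)
}

#' Decomposition of the displayed-voltage error
#'
#' Splits the firmware display error (firmware minus exact, in volts) into
#' the coefficient-approximation component `(2/7 - 0.29296875) * d_val / 10`
#' and the integer-rounding component `(round(2 d/7) - 2 d/7) / 10`; the two
#' sum to the total identically. The rounding component is bounded by 3/70 V
#' in magnitude; the approximation component grows linearly with the code.
#'
#' @param d_val ADC code(s) in `[0, 1023]`.
#' @param const a [conversion_constants()] list.
#' @return data.frame with columns `d_val`, `approximation_error_V`,
#'   `rounding_error_V`, `total_error_V`.
#' @export
display_error_components <- function(d_val, const = conversion_constants()) {
  d_val <- .check_counts(d_val, "d_val")
  fw <- display_voltage_firmware(d_val)
  approx_dV <- (const$dV_per_count_approx - const$dV_per_count_exact) * d_val
  round_dV <- fw - 2 * d_val / 7
  data.frame(
    d_val = d_val,
    approximation_error_V = approx_dV / 10,
    rounding_error_V = round_dV / 10,
    total_error_V = (fw - d_val * const$dV_per_count_exact) / 10
  )
}

#' Load impedance from raw ADC codes
#'
#' Reconstructs voltage (code times `vdd * H / 1024` volts) and current
#' (code times 0.25 uA) from the two ADC channels and returns their ratio in
#' integer kilo-ohm, as refreshed on the device display. A zero current code
#' makes the impedance undefined; this is reported as `NA` with an
#' `"overrange"` attribute rather than an error, mirroring the device which
#' flags rather than halts.
#'
#' @param adc_v_counts load-voltage channel code(s) in `[0, 1023]`.
#' @param adc_i_counts current channel code(s) in `[0, 1023]`.
#' @param const a [conversion_constants()] list.
#' @return Integer impedance(s) in kOhm; `NA` where the current code is 0.
#' @examples
#' compute_impedance(137, 800)  # 20 (4.01 V / 200 uA)
#' @export
compute_impedance <- function(adc_v_counts, adc_i_counts,
                              const = conversion_constants()) {
  v <- .check_counts(adc_v_counts, "adc_v_counts")
  i <- .check_counts(adc_i_counts, "adc_i_counts")
  volts <- v * const$vdd_V * const$divider_ratio_H / 1024
  amps <- i * 0.25e-6
  z <- ifelse(i == 0L, NA_real_, .round_half_up(volts / amps / 1000))
  out <- as.integer(z)
  attr(out, "overrange") <- i == 0L
  out
}
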