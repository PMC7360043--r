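#' Analog output-stage parameters
#'
#' Parameters of the current source seen from the load: first-order dynamics
#' with time constant `tau_ms` and dead time `t_delay_ms`, a compliance
#' voltage beyond which the commanded current cannot be delivered, an
#' optional gain (calibration) error, and additive Gaussian measurement
#' noise on the recorded current.
#'
#' Defaults describe the characterized hardware: dead time 14.21 ms
#' (RS232 transfer latency) and tau = 194.5 ms, back-derived from the
#' measured 99 % settle time of 909 ms via
#' `tau = (909 - 14.21) / ln(100)`. The anti-ripple low-pass filter alone
#' (4.5 Hz cut-off, `cutoff_hz`, kept as documentation) would give
#' tau of about 35 ms; the measured response is several times slower, so the
#' measured value is the default and both are plain configuration.
#'
#' @param tau_ms first-order time constant, ms (>= 0; 0 is an ideal step).
#' @param t_delay_ms dead time between a set-point change and the onset of
#'   the current response, ms.
#' @param cutoff_hz documentation field: cut-off of the PWM low-pass filter.
#' @param compliance_V maximum voltage the source can develop across the
#'   load; above it the current saturates at `compliance_V / R`.
#' @param gain_error multiplicative calibration error (1 = perfectly
#'   trimmed 0.25 uA/count).
#' @param noise_sd_nA SD of additive Gaussian measurement noise, nA.
#' @param rng_seed seed for the noise stream; traces with equal seeds are
#'   bit-identical.
#' @return List of class `"plant_params"`.
#' @export
plant_params <- function(tau_ms = 194.5, t_delay_ms = 14.21, cutoff_hz = 4.5,
                         compliance_V = 30, gain_error = 1.0,
                         noise_sd_nA = 0, rng_seed = 1L) {
  stopifnot(tau_ms >= 0, t_delay_ms >= 0, compliance_V > 0,
            gain_error > 0, noise_sd_nA >= 0)
  structure(list(tau_ms = tau_ms, t_delay_ms = t_delay_ms,
                 cutoff_hz = cutoff_hz, compliance_V = compliance_V,
                 gain_error = gain_error, noise_sd_nA = noise_sd_nA,
                 rng_seed = rng_seed),
            class = "plant_params")
}

#' Rodent-side load model
#'
#' The load the current source drives: a plain resistor, a series RC
#' (electrode polarization in series with tissue resistance), or a
#' piecewise-linear resistance profile over time (e.g. an electrode drying
#' out and drifting above the warning threshold).
#'
#' @param kind `"RESISTOR"`, `"SERIES_RC"` or `"PIECEWISE_PROFILE"`.
#' @param resistance_kohm single resistance (RESISTOR, SERIES_RC) in kOhm.
#' @param capacitance_uF series capacitance (SERIES_RC only), uF.
#' @param profile data.frame `time_ms`, `resistance_kohm` for
#'   PIECEWISE_PROFILE; linearly interpolated, constant beyond the ends.
#' @return List of class `"load_model"`.
#' @export
load_model <- function(kind = c("RESISTOR", "SERIES_RC", "PIECEWISE_PROFILE"),
                       resistance_kohm = 20, capacitance_uF = NULL,
                       profile = NULL) {
  kind <- match.arg(kind)
  if (kind == "PIECEWISE_PROFILE") {
    stopifnot(is.data.frame(profile),
              all(c("time_ms", "resistance_kohm") %in% names(profile)),
              all(profile$resistance_kohm > 0))
  } else {
    stopifnot(length(resistance_kohm) == 1, resistance_kohm > 0)
    if (kind == "SERIES_RC") stopifnot(is.numeric(capacitance_uF), capacitance_uF > 0)
  }
  structure(list(kind = kind, resistance_kohm = resistance_kohm,
                 capacitance_uF = capacitance_uF, profile = profile),
            class = "load_model")
}

#' Instantaneous resistive impedance of a load
#'
#' The resistive impedance used for the load voltage and the compliance
#' limit at time `t_ms`. For a series RC this is the resistive part (the
#' capacitor contributes no resistance at the instant of a step; its slow
#' charging is not part of the current-source dynamics modelled here).
#'
#' @param load a [load_model()].
#' @param t_ms time(s) in ms.
#' @return Impedance(s) in kOhm.
#' @export
load_impedance_at <- function(load, t_ms) {
  stopifnot(inherits(load, "load_model"))
  switch(load$kind,
    RESISTOR  = rep(load$resistance_kohm, length(t_ms)),
    SERIES_RC = rep(load$resistance_kohm, length(t_ms)),
    PIECEWISE_PROFILE =
      stats::approx(load$profile$time_ms, load$profile$resistance_kohm,
                    xout = t_ms, rule = 2)$y)
}

#' Simulate the delivered current for a set-point series
#'
#' Integrates the first-order response piecewise: after each set-point
#' change, delayed by the dead time, the current relaxes as
#' `I(t) = I_sp + (I_init - I_sp) * exp(-(t - t_change - t_delay) / tau)`,
#' exactly between change points (no integration error), sampled at
#' `fs_hz`. The commanded set-point is scaled by the gain error, seeded
#' Gaussian measurement noise is added to the recorded current, and the
#' result is clamped to the compliance ceiling `compliance_V / R(t)`.
#' The load voltage is current times instantaneous impedance.
#'
#' @param setpoints data.frame `time_ms`, `setpoint_uA`: commanded step
#'   series (times of SET commands and their values).
#' @param params a [plant_params()].
#' @param load a [load_model()].
#' @param fs_hz sampling rate of the recorded trace, Hz.
#' @param t_end_ms trace length; default holds 2 s past the last change.
#' @param init_uA current flowing before the first change.
#' @return data.frame of class `"tes_trace"`: `time_ms`, `setpoint_uA`
#'   (commanded, undelayed), `current_uA`, `load_voltage_V`,
#'   `impedance_kohm`.
#' @examples
#' tr <- simulate_response(data.frame(time_ms = 0, setpoint_uA = 250),
#'                         plant_params(), load_model(), fs_hz = 1000)
#' @export
simulate_response <- function(setpoints, params = plant_params(),
                              load = load_model(), fs_hz = 1000,
                              t_end_ms = NULL, init_uA = 0) {
  stopifnot(inherits(params, "plant_params"), inherits(load, "load_model"),
            is.data.frame(setpoints), nrow(setpoints) >= 1)
  if (fs_hz <= 0) stop("sampling rate must be positive", call. = FALSE)
  sp <- setpoints[order(setpoints$time_ms), , drop = FALSE]
  if (is.null(t_end_ms)) t_end_ms <- max(sp$time_ms) + 2000
  dt <- 1000 / fs_hz
  t <- seq(0, t_end_ms, by = dt)

  # segment boundaries: delayed change instants
  change_ms <- sp$time_ms + params$t_delay_ms
  targets <- sp$setpoint_uA * params$gain_error
  bounds <- c(-Inf, change_ms)
  seg_target <- c(init_uA, targets)       # target current within each segment
  seg <- findInterval(t, bounds)          # >= 1

  current <- numeric(length(t))
  idx_by_seg <- split(seq_along(t), seg)
  i_entry <- init_uA
  for (s in seq_along(seg_target)) {
    idx <- idx_by_seg[[as.character(s)]]
    start <- if (s == 1L) -Inf else bounds[s]
    tgt <- seg_target[s]
    if (length(idx)) {
      if (params$tau_ms <= 0 || s == 1L) {
        current[idx] <- if (s == 1L) i_entry else tgt
      } else {
        current[idx] <- tgt + (i_entry - tgt) * exp(-(t[idx] - start) / params$tau_ms)
      }
    }
    # exact exit value at the next boundary
    if (s < length(seg_target)) {
      nxt <- bounds[s + 1L]
      i_entry <- if (params$tau_ms <= 0 || s == 1L) {
        if (s == 1L) i_entry else tgt
      } else {
        tgt + (i_entry - tgt) * exp(-(nxt - start) / params$tau_ms)
      }
    }
  }

  if (params$noise_sd_nA > 0) {
    current <- current + .with_seed(params$rng_seed,
      stats::rnorm(length(t), 0, params$noise_sd_nA / 1000))
  }

  r_kohm <- load_impedance_at(load, t)
  i_max <- params$compliance_V / r_kohm * 1000   # uA ceiling at each sample
  current <- pmin(current, i_max)
  voltage <- current * r_kohm / 1000             # volts

  # commanded (undelayed) set-point held at each sample
  cmd_seg <- findInterval(t, c(-Inf, sp$time_ms))
  setpoint_held <- c(init_uA, sp$setpoint_uA)[cmd_seg]

  out <- data.frame(time_ms = t, setpoint_uA = setpoint_held,
                    current_uA = current, load_voltage_V = voltage,
                    impedance_kohm = r_kohm)
  class(out) <- c("tes_trace", "data.frame")
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
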