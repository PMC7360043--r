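#' Waveform specification for computer-controlled stimulation
#'
#' Describes a host-driven stimulation waveform. `TDCS` is a constant
#' current at `offset_uA`; `OTDCS` superimposes a sinusoid
#' `offset + amplitude * sin(2 pi f t)`; `TPCS` delivers rectangular pulses
#' of height `offset_uA` (width `pulse_width_ms` every `period_ms`);
#' `ARBITRARY` takes a user sample series. A linear fade-in/fade-out
#' envelope multiplies the waveform. Every emitted value must stay within
#' the deliverable range 0-250 uA — in particular an oscillation deeper
#' than its offset is rejected, since the hardware cannot source negative
#' current.
#'
#' @param kind `"TDCS"`, `"OTDCS"`, `"TPCS"` or `"ARBITRARY"`.
#' @param offset_uA DC level (TDCS plateau / OTDCS offset / TPCS pulse height).
#' @param amplitude_uA OTDCS oscillation amplitude, uA.
#' @param frequency_hz OTDCS frequency.
#' @param pulse_width_ms,period_ms TPCS pulse geometry.
#' @param fade_in_s,fade_out_s linear envelope ramps, s (0 = none).
#' @param duration_s total waveform duration, s.
#' @param update_rate_hz set-point update rate; 50 Hz by default, enough
#'   for at least 10 samples per cycle up to 5 Hz while staying within the
#'   serial link's command throughput.
#' @param samples data.frame `time_s`, `current_uA` (ARBITRARY only).
#' @return List of class `"waveform_spec"`.
#' @export
waveform_spec <- function(kind = c("TDCS", "OTDCS", "TPCS", "ARBITRARY"),
                          offset_uA = 0, amplitude_uA = 0, frequency_hz = 1,
                          pulse_width_ms = 100, period_ms = 1000,
                          fade_in_s = 0, fade_out_s = 0, duration_s = 60,
                          update_rate_hz = 50, samples = NULL) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0, update_rate_hz > 0,
            fade_in_s >= 0, fade_out_s >= 0,
            fade_in_s + fade_out_s <= duration_s)
  if (kind == "OTDCS") {
    stopifnot(frequency_hz > 0, amplitude_uA >= 0)
    if (offset_uA - amplitude_uA < 0)
      stop("OTDCS trough below zero: offset must be >= amplitude ",
           "(no negative current)", call. = FALSE)
    if (offset_uA + amplitude_uA > 250)
      stop("OTDCS peak exceeds 250 uA", call. = FALSE)
  } else if (kind == "TPCS") {
    stopifnot(pulse_width_ms > 0, period_ms >= pulse_width_ms)
  } else if (kind == "ARBITRARY") {
    stopifnot(is.data.frame(samples),
              all(c("time_s", "current_uA") %in% names(samples)))
    if (any(samples$current_uA < 0 | samples$current_uA > 250))
      stop("arbitrary waveform outside [0, 250] uA", call. = FALSE)
  }
  if (kind != "ARBITRARY" && (offset_uA < 0 || offset_uA > 250))
    stop("offset outside [0, 250] uA", call. = FALSE)
  structure(list(kind = kind, offset_uA = offset_uA,
                 amplitude_uA = amplitude_uA, frequency_hz = frequency_hz,
                 pulse_width_ms = pulse_width_ms, period_ms = period_ms,
                 fade_in_s = fade_in_s, fade_out_s = fade_out_s,
                 duration_s = duration_s, update_rate_hz = update_rate_hz,
                 samples = samples),
            class = "waveform_spec")
}

#' Generate the set-point series of a waveform
#'
#' Samples the waveform at its update rate and applies the fade envelope
#' (a multiplicative linear ramp, so an oscillation scales rather than
#' truncates during the fades).
#'
#' @param spec a [waveform_spec()].
#' @return data.frame `time_ms`, `setpoint_uA`; all values in `[0, 250]`.
#' @examples
#' s <- generate_series(waveform_spec("OTDCS", offset_uA = 100,
#'                                    amplitude_uA = 50, frequency_hz = 1,
#'                                    duration_s = 2))
#' range(s$setpoint_uA)  # 50 .. 150
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  t_s <- seq(0, spec$duration_s, by = 1 / spec$update_rate_hz)
  value <- switch(spec$kind,
    TDCS  = rep(spec$offset_uA, length(t_s)),
    OTDCS = spec$offset_uA +
            spec$amplitude_uA * sin(2 * pi * spec$frequency_hz * t_s),
    TPCS  = ifelse((t_s * 1000) %% spec$period_ms < spec$pulse_width_ms,
                   spec$offset_uA, 0),
    ARBITRARY = stats::approx(spec$samples$time_s, spec$samples$current_uA,
                              xout = t_s, rule = 2)$y)
  env <- rep(1, length(t_s))
  if (spec$fade_in_s > 0)
    env <- pmin(env, t_s / spec$fade_in_s)
  if (spec$fade_out_s > 0)
    env <- pmin(env, (spec$duration_s - t_s) / spec$fade_out_s)
  env <- pmax(env, 0)
  data.frame(time_ms = t_s * 1000, setpoint_uA = value * env)
}

#' Quantize a current series to the 0.25 uA register grid
#'
#' Rounds every value to the nearest multiple of 0.25 uA (halves up), the
#' resolution of the set-point register; the quantization error is at most
#' 0.125 uA.
#'
#' @param series data.frame with a `setpoint_uA` column, or a numeric vector.
#' @return Same shape with values on the 0.25 uA grid.
#' @examples
#' quantize_series(c(100.1, 100.125))  # 100.00 100.25
#' @export
quantize_series <- function(series) {
  vals <- if (is.data.frame(series)) series$setpoint_uA else series
  if (any(vals < 0 | vals > 255.75))
    stop("series value outside [0, 255.75] uA", call. = FALSE)
  q <- floor(vals * 4 + 0.5) / 4
  if (is.data.frame(series)) { series$setpoint_uA <- q; series } else q
}

#' Compile a quantized series into a minimal command schedule
#'
#' Consecutive samples differing by exactly one register count become
#' `+`/`-` commands; unchanged samples emit nothing; larger jumps (and the
#' first sample) become `I` set commands. Under that rule the schedule has
#' the minimum number of commands reproducing the series.
#'
#' @param series data.frame `time_ms`, `setpoint_uA` with values on the
#'   0.25 uA grid (see [quantize_series()]).
#' @return data.frame `time_ms`, `text`, `counts` (register value after the
#'   command), class `"command_schedule"`.
#' @examples
#' compile_schedule(data.frame(time_ms = 0:2 * 20,
#'                             setpoint_uA = c(100, 100.25, 100.5)))
#' @export
compile_schedule <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("time_ms", "setpoint_uA") %in% names(series)))
  counts <- round(series$setpoint_uA * 4)
  if (any(abs(counts * 0.25 - series$setpoint_uA) > 1e-9))
    stop("series is not on the 0.25 uA grid; quantize first", call. = FALSE)
  counts <- as.integer(counts)
  n <- length(counts)
  texts <- character(n); keep <- logical(n)
  texts[1] <- paste0("I", counts[1]); keep[1] <- TRUE
  if (n > 1) {
    d <- diff(counts)
    keep[-1] <- d != 0L
    texts[-1] <- ifelse(d == 1L, "+",
                 ifelse(d == -1L, "-", paste0("I", counts[-1])))
  }
  out <- data.frame(time_ms = series$time_ms[keep], text = texts[keep],
                    counts = counts[keep])
  class(out) <- c("command_schedule", "data.frame")
  out
}

#' Replay a command schedule against an emulated device
#'
#' Sends a compiled schedule through the hand-checked protocol to a
#' [computer_device()] and records the register value at each command time;
#' holding between commands reconstructs the delivered set-point series.
#'
#' @param schedule a [compile_schedule()] result.
#' @param dev a [computer_device()]; fresh by default.
#' @return list with the session `transcript` and the reconstructed
#'   `series` (`time_ms`, `setpoint_uA`).
#' @export
replay_schedule <- function(schedule, dev = computer_device()) {
  tr <- loopback_transport(dev)
  n <- nrow(schedule)
  reg <- integer(n)
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    rows[[j]] <- host_session(tr, schedule$text[j],
                              times_ms = schedule$time_ms[j])
    if (!all(rows[[j]]$ok | rows[[j]]$direction == "host"))
      stop("schedule replay halted at command ", schedule$text[j],
           call. = FALSE)
    reg[j] <- dev$setpoint_counts
  }
  list(transcript = do.call(rbind, rows),
       series = data.frame(time_ms = schedule$time_ms,
                           setpoint_uA = reg * 0.25))
}
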