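#' Emulated stimulator device
#'
#' Creates the firmware state machine on a discrete 1 ms time base. The
#' smallest fade sample period in range is 2 ms and the other firmware
#' clocks are 100 ms (telemetry), 250 ms (display refresh) and 1000 ms
#' (plateau countdown), so a 1 ms tick resolves every event exactly.
#'
#' The returned object is an environment (mutable, reference semantics, like
#' a connection). Drive it with [control_action()] and [device_tick()] or
#' run a whole session with [run_session()].
#'
#' Phases: `IDLE`, `FADE_IN`, `STIM`, `PAUSING` (fade-out toward pause),
#' `PAUSED`, `RESUMING` (fade-in from pause), `FADE_OUT`, `DONE`, `ABORTED`.
#'
#' @param settings a [stim_settings()] object.
#' @param load_kohm resistive load used to synthesise the ADC codes the
#'   firmware would measure; either a single value or a function of time in
#'   ms returning kOhm (see [load_model()] / [load_impedance_at()]).
#' @param source_voltage_V supply voltage feeding the battery check.
#' @param battery_threshold_V below this the device reports `LOW BAT`.
#' @param const a [conversion_constants()] list.
#' @return An environment of class `"tes_device"`.
#' @examples
#' dev <- tes_device(stim_settings(10, 10, 2, 2, 150))
#' dev <- control_action(dev, "START")
#' dev$phase
#' @export
tes_device <- function(settings, load_kohm = 20,
                       source_voltage_V = 9, battery_threshold_V = 7.2,
                       const = conversion_constants()) {
  stopifnot(inherits(settings, "stim_settings"))
  dev <- new.env(parent = emptyenv())
  dev$settings <- settings
  dev$const <- const
  dev$phase <- "IDLE"
  dev$setpoint_counts <- 0L
  dev$target_counts <- current_to_counts(settings$current_uA)
  dev$remaining_s <- settings$duration_s
  dev$tick_ms <- 0L
  dev$sample_rate_ms <- NA_integer_
  dev$next_fade_ms <- NA_integer_
  dev$stim_ms <- 0L          # plateau milliseconds accumulated
  dev$battery_ok <- source_voltage_V >= battery_threshold_V
  dev$warning_active <- FALSE
  dev$load_fun <- if (is.function(load_kohm)) load_kohm else function(t_ms) load_kohm
  dev$events <- list()       # accumulating event log
  dev$setpoint_changes <- list(list(time_ms = 0L, counts = 0L))
  class(dev) <- "tes_device"
  dev
}

#' @export
print.tes_device <- function(x, ...) {
  cat(sprintf("<tes_device> phase %s, set-point %d counts (%.2f uA), %d s remaining, t = %d ms\n",
              x$phase, x$setpoint_counts, x$setpoint_counts * 0.25,
              x$remaining_s, x$tick_ms))
  invisible(x)
}

.emit <- function(dev, event, payload = "") {
  dev$events[[length(dev$events) + 1L]] <-
    list(timestamp_ms = dev$tick_ms, event = event, payload = as.character(payload))
}

.set_setpoint <- function(dev, counts) {
  dev$setpoint_counts <- counts
  dev$setpoint_changes[[length(dev$setpoint_changes) + 1L]] <-
    list(time_ms = dev$tick_ms, counts = counts)
}

.begin_fade <- function(dev, phase, fade_s) {
  dev$phase <- phase
  dev$sample_rate_ms <- compute_sample_rate(dev$settings$current_uA, fade_s)
  dev$next_fade_ms <- dev$tick_ms + dev$sample_rate_ms
  .emit(dev, "phase", phase)
}

#' Apply a front-panel control action
#'
#' `START` arms a configured device (IDLE -> FADE_IN). `PAUSE` is legal only
#' during the plateau and triggers a full fade-out to `PAUSED`; the remaining
#' plateau time is frozen. `RESUME` replays the configured fade-in and
#' continues the plateau for the frozen remaining time, so the plateau
#' seconds delivered over the whole session equal the configured duration
#' regardless of how often it is paused. `ABORT` is legal only at zero
#' current (`PAUSED`) and terminates the session.
#'
#' @param dev a [tes_device()].
#' @param action one of `"START"`, `"PAUSE"`, `"RESUME"`, `"ABORT"`.
#' @return The device, invisibly (modified in place).
#' @export
control_action <- function(dev, action = c("START", "PAUSE", "RESUME", "ABORT")) {
  action <- match.arg(action)
  ok <- switch(action,
    START  = dev$phase == "IDLE",
    PAUSE  = dev$phase == "STIM",
    RESUME = dev$phase == "PAUSED",
    ABORT  = dev$phase == "PAUSED")
  if (!ok)
    stop(sprintf("action %s is illegal in phase %s", action, dev$phase),
         call. = FALSE)
  switch(action,
    START  = .begin_fade(dev, "FADE_IN", dev$settings$fade_in_s),
    PAUSE  = .begin_fade(dev, "PAUSING", dev$settings$fade_out_s),
    RESUME = .begin_fade(dev, "RESUMING", dev$settings$fade_in_s),
    ABORT  = { dev$phase <- "ABORTED"; .emit(dev, "phase", "ABORTED") })
  invisible(dev)
}

# ADC codes the firmware would read for the current set-point into the load
.measure_codes <- function(dev) {
  i_uA <- dev$setpoint_counts * 0.25
  r_kohm <- dev$load_fun(dev$tick_ms)
  v_load <- i_uA * 1e-6 * r_kohm * 1000          # volts across the load
  v_counts <- min(1023L, as.integer(.round_half_up(
    v_load / dev$const$divider_ratio_H / (dev$const$vdd_V / 1024))))
  list(adc_v_counts = v_counts, adc_i_counts = dev$setpoint_counts)
}

.telemetry_prefix <- function(phase) {
  switch(phase,
    FADE_IN = "+", RESUMING = "+",
    STIM = "*",
    PAUSED = "#",
    PAUSING = "-", FADE_OUT = "-",
    NA_character_)
}

#' Advance the emulated firmware by one millisecond
#'
#' Runs one tick of every firmware clock: the fade sample-rate timer (one
#' 0.25 uA step per period while in a fade phase), the 1 s plateau countdown
#' (`remaining_s` decreases only in `STIM`), the 250 ms display refresh
#' (which recomputes voltage, current and impedance and drives the
#' over-impedance buzzer warning), and the 100 ms telemetry frame when
#' enabled. Conditions become events, never errors.
#'
#' @param dev a [tes_device()] not yet `DONE`/`ABORTED`.
#' @param measured optional list with `adc_v_counts` and `adc_i_counts`
#'   overriding the codes synthesised from the attached load.
#' @return Invisibly, the list of events emitted during this tick (also
#'   appended to `dev$events`).
#' @export
device_tick <- function(dev, measured = NULL) {
  if (dev$phase %in% c("DONE", "ABORTED"))
    stop("device session has ended", call. = FALSE)
  n0 <- length(dev$events)
  dev$tick_ms <- dev$tick_ms + 1L
  t <- dev$tick_ms

  # fade sample-rate clock
  if (dev$phase %in% c("FADE_IN", "RESUMING", "PAUSING", "FADE_OUT") &&
      t >= dev$next_fade_ms) {
    step <- if (dev$phase %in% c("FADE_IN", "RESUMING")) 1L else -1L
    .set_setpoint(dev, dev$setpoint_counts + step)
    dev$next_fade_ms <- dev$next_fade_ms + dev$sample_rate_ms
    if (step > 0L && dev$setpoint_counts == dev$target_counts) {
      dev$phase <- "STIM"
      .emit(dev, "phase", "STIM")
    } else if (step < 0L && dev$setpoint_counts == 0L) {
      dev$phase <- if (dev$phase == "PAUSING") "PAUSED" else "DONE"
      .emit(dev, "phase", dev$phase)
    }
  } else if (dev$phase == "STIM") {
    # plateau countdown: one second of STIM per decrement
    dev$stim_ms <- dev$stim_ms + 1L
    if (dev$stim_ms %% 1000L == 0L) {
      dev$remaining_s <- dev$remaining_s - 1L
      .emit(dev, "countdown", dev$remaining_s)
      if (dev$remaining_s == 0L)
        .begin_fade(dev, "FADE_OUT", dev$settings$fade_out_s)
    }
  }

  active <- !(dev$phase %in% c("IDLE", "DONE", "ABORTED"))

  # display refresh clock (250 ms): voltage/current/impedance + warning
  if (active && t %% 250L == 0L) {
    m <- if (is.null(measured)) .measure_codes(dev) else measured
    z <- compute_impedance(m$adc_v_counts, m$adc_i_counts, dev$const)
    v_dV <- display_voltage_firmware(m$adc_v_counts)
    .emit(dev, "display_refresh",
          sprintf("I=%.2fuA V=%ddV Z=%skR rem=%ds",
                  m$adc_i_counts * 0.25, v_dV,
                  ifelse(is.na(z), "--", z), dev$remaining_s))
    over <- !is.na(z) && z > dev$settings$impedance_threshold_kohm
    if (over && !dev$warning_active) .emit(dev, "warning", "impedance over threshold")
    if (over) .emit(dev, "buzzer", "on")
    dev$warning_active <- over
  }

  # telemetry clock (100 ms)
  if (active && dev$settings$telemetry_enabled && t %% 100L == 0L) {
    m <- if (is.null(measured)) .measure_codes(dev) else measured
    z <- compute_impedance(m$adc_v_counts, m$adc_i_counts, dev$const)
    frame <- telemetry_frame(.telemetry_prefix(dev$phase),
                             if (is.na(z)) 0L else z)
    .emit(dev, "telemetry", format_telemetry_frame(frame))
  }

  invisible(dev$events[seq.int(n0 + 1L, length.out = length(dev$events) - n0)])
}

#' Run a standalone session to completion
#'
#' Starts the device and ticks the 1 ms clock until `DONE`/`ABORTED`,
#' applying scheduled control actions along the way (e.g. pause/resume).
#'
#' @param dev a [tes_device()] in `IDLE`.
#' @param actions optional data.frame with columns `at_ms` and `action`;
#'   each action is applied at the first tick at or after `at_ms` in which
#'   it is legal (a pause requested mid-fade waits for the plateau).
#' @param max_ms safety bound on the simulated clock.
#' @return The device invisibly; `dev$events` holds the full log and
#'   `dev$setpoint_changes` the commanded set-point series.
#' @export
run_session <- function(dev, actions = NULL, max_ms = 4e6) {
  if (dev$phase == "IDLE") control_action(dev, "START")
  pending <- if (is.null(actions)) NULL else actions[order(actions$at_ms), ]
  while (!(dev$phase %in% c("DONE", "ABORTED")) && dev$tick_ms < max_ms) {
    device_tick(dev)
    if (!is.null(pending) && nrow(pending) &&
        dev$tick_ms >= pending$at_ms[1]) {
      act <- as.character(pending$action[1])
      legal <- switch(act, PAUSE = dev$phase == "STIM",
                      RESUME = dev$phase == "PAUSED",
                      ABORT = dev$phase == "PAUSED", FALSE)
      if (legal) {
        control_action(dev, act)
        pending <- pending[-1, , drop = FALSE]
      }
    }
    if (dev$phase == "PAUSED" && (is.null(pending) || !nrow(pending)))
      stop("device is paused with no further scheduled action", call. = FALSE)
  }
  if (!(dev$phase %in% c("DONE", "ABORTED")))
    stop("session exceeded max_ms before completing", call. = FALSE)
  invisible(dev)
}

#' Event log as a data.frame
#'
#' @param dev a [tes_device()].
#' @return data.frame with columns `timestamp_ms`, `event`, `payload`.
#' @export
device_events <- function(dev) {
  if (!length(dev$events))
    return(data.frame(timestamp_ms = integer(0), event = character(0),
                      payload = character(0)))
  data.frame(
    timestamp_ms = vapply(dev$events, `[[`, integer(1), "timestamp_ms"),
    event = vapply(dev$events, `[[`, character(1), "event"),
    payload = vapply(dev$events, `[[`, character(1), "payload"))
}

#' Commanded set-point series of a session
#'
#' @param dev a [tes_device()] after [run_session()].
#' @return data.frame with columns `time_ms`, `setpoint_uA`.
#' @export
setpoint_series <- function(dev) {
  data.frame(
    time_ms = vapply(dev$setpoint_changes, `[[`, integer(1), "time_ms"),
    setpoint_uA = 0.25 * vapply(dev$setpoint_changes, `[[`, integer(1), "counts"))
}
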