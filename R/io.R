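#' Write / read a trace CSV
#'
#' Fixed dialect: comma separator, `.` decimal, mandatory header with
#' columns `time_s`, `setpoint_uA`, `current_uA`, `voltage_V`,
#' `impedance_kohm` (times stored in seconds on disk, milliseconds in
#' memory).
#'
#' @param trace a `"tes_trace"` data.frame (see [simulate_response()]).
#' @param path file path.
#' @return `write_trace_csv`: the path invisibly. `read_trace_csv`: the
#'   trace as a `"tes_trace"` data.frame.
#' @export
write_trace_csv <- function(trace, path) {
  out <- data.frame(time_s = trace$time_ms / 1000,
                    setpoint_uA = trace$setpoint_uA,
                    current_uA = trace$current_uA,
                    voltage_V = trace$load_voltage_V,
                    impedance_kohm = trace$impedance_kohm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  raw <- utils::read.csv(path)
  need <- c("time_s", "setpoint_uA", "current_uA", "voltage_V", "impedance_kohm")
  if (!all(need %in% names(raw)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- data.frame(time_ms = raw$time_s * 1000,
                    setpoint_uA = raw$setpoint_uA,
                    current_uA = raw$current_uA,
                    load_voltage_V = raw$voltage_V,
                    impedance_kohm = raw$impedance_kohm)
  class(out) <- c("tes_trace", "data.frame")
  out
}

#' Read a plain-text key = value configuration
#'
#' One `key = value` pair per line; `#` starts a comment; numeric-looking
#' values become numbers, `true`/`false` become logicals.
#'
#' @param path file path.
#' @return Named list.
#' @export
read_kv_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  parse1 <- function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  }
  stats::setNames(lapply(vals, parse1), keys)
}

#' Write a session event log
#'
#' Line-delimited records `timestamp_ms,source,event,payload` (CSV with
#' header), append-only by construction.
#'
#' @param events data.frame from [device_events()] (a `source` column is
#'   added if absent).
#' @param path file path.
#' @param source default source label for rows lacking one.
#' @return The path, invisibly.
#' @export
write_session_log <- function(events, path, source = "device") {
  if (!"source" %in% names(events)) events$source <- source
  out <- events[, c("timestamp_ms", "source", "event", "payload")]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Run a standalone stimulation end to end
#'
#' Wires the firmware emulation to the analog plant: runs the standalone
#' state machine (fade-in, plateau with countdown, fade-out, plus any
#' scheduled pause/resume), feeds its commanded set-point series through
#' [simulate_response()], and returns both the event log and the delivered
#' trace.
#'
#' @param settings a [stim_settings()].
#' @param params a [plant_params()].
#' @param load a [load_model()]; also drives the firmware's measured
#'   impedance (and hence warnings).
#' @param fs_hz trace sampling rate.
#' @param actions optional pause/resume schedule (see [run_session()]).
#' @return List of class `"standalone_run"`: `device`, `events`, `trace`.
#' @examples
#' run <- standalone_run(stim_settings(10, 10, 2, 2, 150), fs_hz = 100)
#' max(run$trace$current_uA)
#' @export
standalone_run <- function(settings, params = plant_params(),
                           load = load_model(), fs_hz = 100, actions = NULL) {
  dev <- tes_device(settings,
                    load_kohm = function(t_ms) load_impedance_at(load, t_ms))
  run_session(dev, actions = actions)
  series <- setpoint_series(dev)
  trace <- simulate_response(series, params, load, fs_hz = fs_hz,
                             t_end_ms = dev$tick_ms + 1000)
  structure(list(device = dev, events = device_events(dev), trace = trace),
            class = "standalone_run")
}

#' Run a computer-controlled waveform end to end
#'
#' Generates the waveform series, quantizes it to the register grid,
#' compiles the minimal command schedule, replays it through the
#' hand-checked protocol against an emulated device, and simulates the
#' delivered current through the plant.
#'
#' @param spec a [waveform_spec()].
#' @param params a [plant_params()].
#' @param load a [load_model()].
#' @param fs_hz trace sampling rate.
#' @return List of class `"driven_run"`: `schedule`, `transcript`,
#'   `series` (quantized set-points), `trace`.
#' @export
driven_run <- function(spec, params = plant_params(), load = load_model(),
                       fs_hz = 100) {
  series <- quantize_series(generate_series(spec))
  schedule <- compile_schedule(series)
  rep <- replay_schedule(schedule, computer_device(
    load_kohm = function(t_ms) load_impedance_at(load, t_ms)))
  trace <- simulate_response(
    data.frame(time_ms = rep$series$time_ms, setpoint_uA = rep$series$setpoint_uA),
    params, load, fs_hz = fs_hz,
    t_end_ms = max(series$time_ms) + 1000)
  structure(list(schedule = schedule, transcript = rep$transcript,
                 series = series, trace = trace),
            class = "driven_run")
}

#' Generate the bundled synthetic fixtures
#'
#' Deterministic fixture set used by the tests and the `analyze` CLI path:
#' a clean full-scale step edge, a noisy plateau, a session with drifting
#' load impedance crossing the warning threshold, and a golden protocol
#' transcript. Identical seeds give byte-identical files.
#'
#' @param seed integer seed for every random element.
#' @param out_dir directory to write into (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(seed = 1L, out_dir = tempfile("fixtures")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    step = file.path(out_dir, "step_edge.csv"),
    noisy = file.path(out_dir, "noisy_plateau.csv"),
    drift = file.path(out_dir, "drifting_impedance.csv"),
    transcript = file.path(out_dir, "golden_transcript.csv"))

  write_trace_csv(simulate_response(
    data.frame(time_ms = 0, setpoint_uA = 250),
    plant_params(noise_sd_nA = 0), load_model(), fs_hz = 1000,
    t_end_ms = 3000), paths["step"])

  write_trace_csv(simulate_response(
    data.frame(time_ms = 0, setpoint_uA = 200),
    plant_params(noise_sd_nA = 10, rng_seed = seed), load_model(),
    fs_hz = 100, t_end_ms = 5000), paths["noisy"])

  drift <- load_model("PIECEWISE_PROFILE", profile = data.frame(
    time_ms = c(0, 14000), resistance_kohm = c(20, 160)))
  run <- standalone_run(
    stim_settings(10, 10, 2, 2, impedance_threshold_kohm = 150,
                  telemetry_enabled = TRUE),
    plant_params(noise_sd_nA = 5, rng_seed = seed + 1L), drift, fs_hz = 100)
  write_trace_csv(run$trace, paths["drift"])

  sched <- compile_schedule(quantize_series(generate_series(
    waveform_spec("OTDCS", offset_uA = 100, amplitude_uA = 50,
                  frequency_hz = 1, duration_s = 2))))
  tra <- replay_schedule(sched)$transcript
  utils::write.csv(tra, paths["transcript"], row.names = FALSE)

  invisible(paths)
}
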