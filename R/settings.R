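#' Validated standalone stimulation settings
#'
#' Front-panel parameters of a standalone tDCS run, checked against the
#' device's ranges and increments: current 10-250 uA step 1, duration
#' 10-3600 s step 10, fade-in/out 2-60 s step 1, impedance warning threshold
#' 10-150 kOhm step 1. All violations are reported together, so a rejection
#' names every offending field.
#'
#' @param current_uA plateau current in uA.
#' @param duration_s plateau (stimulation) duration in s.
#' @param fade_in_s,fade_out_s linear ramp durations in s.
#' @param impedance_threshold_kohm warning threshold in kOhm; while the
#'   measured impedance exceeds it the device raises its buzzer warning.
#' @param telemetry_enabled emit a telemetry frame every 100 ms when active.
#' @return An object of class `"stim_settings"` (a validated list).
#' @examples
#' stim_settings(200, 1200, 10, 10, 50)
#' @export
stim_settings <- function(current_uA, duration_s, fade_in_s = 10L,
                          fade_out_s = fade_in_s,
                          impedance_threshold_kohm = 150L,
                          telemetry_enabled = FALSE) {
  raw <- list(current_uA = current_uA, duration_s = duration_s,
              fade_in_s = fade_in_s, fade_out_s = fade_out_s,
              impedance_threshold_kohm = impedance_threshold_kohm)
  problems <- character(0)
  chk <- function(name, lo, hi, step, unit) {
    x <- raw[[name]]
    if (length(x) != 1 || !is.finite(x) || x != floor(x)) {
      problems <<- c(problems, sprintf("%s must be a single integer", name))
      return()
    }
    if (x < lo || x > hi)
      problems <<- c(problems,
        sprintf("%s = %d out of range [%d, %d] %s", name, as.integer(x), lo, hi, unit))
    else if ((x - lo) %% step != 0)
      problems <<- c(problems,
        sprintf("%s = %d off the %d %s grid", name, as.integer(x), step, unit))
  }
  chk("current_uA", 10L, 250L, 1L, "uA")
  chk("duration_s", 10L, 3600L, 10L, "s")
  chk("fade_in_s", 2L, 60L, 1L, "s")
  chk("fade_out_s", 2L, 60L, 1L, "s")
  chk("impedance_threshold_kohm", 10L, 150L, 1L, "kOhm")
  if (length(problems))
    stop("invalid stimulation settings:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  out <- lapply(raw, as.integer)
  out$telemetry_enabled <- isTRUE(telemetry_enabled)
  class(out) <- "stim_settings"
  out
}

#' @export
print.stim_settings <- function(x, ...) {
  cat(sprintf(
    "<stim_settings> %d uA for %d s (fade-in %d s, fade-out %d s), warn > %d kOhm, telemetry %s\n",
    x$current_uA, x$duration_s, x$fade_in_s, x$fade_out_s,
    x$impedance_threshold_kohm, if (x$telemetry_enabled) "on" else "off"))
  invisible(x)
}

#' Validate candidate settings
#'
#' Thin wrapper over [stim_settings()] that returns the validated object, or
#' (with `quiet = TRUE`) a `settings_rejection` object carrying the full
#' list of violations instead of an error.
#'
#' @param raw a list with fields named as in [stim_settings()].
#' @param quiet return a `settings_rejection` on failure instead of raising.
#' @return `stim_settings` object, or a `settings_rejection` when `quiet`.
#' @export
validate_settings <- function(raw, quiet = FALSE) {
  res <- try(do.call(stim_settings, raw), silent = TRUE)
  if (inherits(res, "try-error")) {
    if (!quiet) stop(attr(res, "condition"))
    return(structure(
      list(problems = conditionMessage(attr(res, "condition"))),
      class = "settings_rejection"))
  }
  res
}
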