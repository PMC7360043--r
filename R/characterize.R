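#' Response time of a recorded edge
#'
#' Time from the command being sent to the first recorded sample whose
#' current exceeds 0.1 uA — the onset criterion of the step-response
#' protocol. No interpolation: the first-crossing sample is taken, so the
#' result overestimates the true dead time by up to one sample interval.
#'
#' @param trace a trace from [simulate_response()] (or [read_trace_csv()]).
#' @param send_time_ms when the set-point command was sent.
#' @param threshold_uA onset threshold (0.1 uA).
#' @return Response time in ms.
#' @export
detect_response_time <- function(trace, send_time_ms = 0, threshold_uA = 0.1) {
  after <- trace$time_ms >= send_time_ms
  idx <- which(after & trace$current_uA > threshold_uA)
  if (!length(idx))
    stop("current never exceeds the onset threshold", call. = FALSE)
  trace$time_ms[idx[1]] - send_time_ms
}

#' Settle times of a step response
#'
#' First time after the step at which the current enters the tolerance band
#' around the set-point and remains inside it until the end of the trace
#' ("enter and stay" criterion, robust to noise re-crossings). The band for
#' fraction f is `|I - I_sp| <= (1 - f) * I_sp`.
#'
#' @param trace single-edge trace (one step, monotone approach window).
#' @param setpoint_uA target current of the step.
#' @param fractions fractions of the set-point to settle to.
#' @param from_time_ms measure from this time (the step command instant).
#' @return Named numeric vector of settle times in ms (from `from_time_ms`);
#'   `NA` for a band never permanently entered.
#' @export
settle_times <- function(trace, setpoint_uA, fractions = c(0.99, 0.999),
                         from_time_ms = 0) {
  w <- trace[trace$time_ms >= from_time_ms, ]
  dev_abs <- abs(w$current_uA - setpoint_uA)
  out <- vapply(fractions, function(f) {
    band <- (1 - f) * setpoint_uA
    inside <- dev_abs <= band
    # last sample outside the band; settled one sample after it
    last_out <- max(c(0L, which(!inside)))
    if (last_out >= length(inside)) return(NA_real_)
    w$time_ms[last_out + 1L] - from_time_ms
  }, numeric(1))
  names(out) <- paste0("settle_", vapply(fractions, function(f)
    sub("^0\\.", "", format(f)), character(1)))
  out
}

#' Fit a first-order-with-dead-time model to a rising edge
#'
#' Least-squares fit of `I(t) = I_sp * (1 - exp(-(t - t_d) / tau))` for
#' `t > t_d` (zero before) to a recorded rising edge, via
#' Levenberg-Marquardt. Starting values come from the trace itself: the
#' plateau level, the 0.1 uA onset, and the 63.2 % crossing.
#'
#' @param trace single rising-edge trace starting at the step command.
#' @param window_ms optional `c(from, to)` restricting the fit window.
#' @return List `tau_ms`, `t_delay_ms`, `setpoint_uA`, plus the `fit`
#'   object from [minpack.lm::nlsLM()].
#' @export
fit_first_order <- function(trace, window_ms = NULL) {
  w <- trace
  if (!is.null(window_ms))
    w <- w[w$time_ms >= window_ms[1] & w$time_ms <= window_ms[2], ]
  if (nrow(w) < 10 || diff(range(w$current_uA)) < 1e-12)
    stop("degenerate fit window (flat or too short)", call. = FALSE)
  sp0 <- max(w$current_uA)
  td0 <- tryCatch(detect_response_time(w, w$time_ms[1]),
                  error = function(e) 0) + w$time_ms[1]
  i63 <- which(w$current_uA >= 0.632 * sp0)
  tau0 <- max(if (length(i63)) w$time_ms[i63[1]] - td0 else 1, 1)
  fit <- minpack.lm::nlsLM(
    current_uA ~ ifelse(time_ms <= td, 0, sp * (1 - exp(-(time_ms - td) / tau))),
    data = w,
    start = list(sp = sp0, td = max(td0, 1e-3), tau = tau0),
    lower = c(sp = 0, td = 0, tau = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  list(tau_ms = unname(est["tau"]), t_delay_ms = unname(est["td"]),
       setpoint_uA = unname(est["sp"]), fit = fit)
}

#' Step-response protocol
#'
#' Replays the characterization paradigm: repeated switching between 0 and
#' a full-scale set-point, recording each rising edge at `fs_hz` and
#' measuring per edge the response time (0.1 uA onset), the 99 % and 99.9 %
#' settle times, and the fitted first-order parameters; the report
#' aggregates mean and SD across edges.
#'
#' @param params a [plant_params()]; per-edge noise streams are derived
#'   from its `rng_seed`.
#' @param load a [load_model()].
#' @param n_edges number of rising edges (100 in the hardware protocol).
#' @param setpoint_uA high level of the switching pattern.
#' @param fs_hz acquisition rate (1 kHz in the hardware protocol).
#' @param edge_ms recorded length of each edge.
#' @param fit also fit the first-order model per edge (slower).
#' @return List of class `"step_report"`: `per_edge` data.frame and
#'   `summary` (mean/sd per measure).
#' @export
run_step_protocol <- function(params = plant_params(), load = load_model(),
                              n_edges = 100, setpoint_uA = 250,
                              fs_hz = 1000, edge_ms = 3000, fit = TRUE) {
  stopifnot(n_edges >= 1)
  rows <- vector("list", n_edges)
  for (e in seq_len(n_edges)) {
    p <- params
    p$rng_seed <- if (is.null(params$rng_seed)) NULL else params$rng_seed + e
    tr <- simulate_response(data.frame(time_ms = 0, setpoint_uA = setpoint_uA),
                            p, load, fs_hz = fs_hz, t_end_ms = edge_ms)
    st <- settle_times(tr, setpoint_uA * p$gain_error)
    f <- if (fit) fit_first_order(tr) else
      list(tau_ms = NA_real_, t_delay_ms = NA_real_, setpoint_uA = NA_real_)
    rows[[e]] <- data.frame(
      edge = e,
      response_time_ms = detect_response_time(tr),
      settle_99_ms = st[["settle_99"]],
      settle_999_ms = st[["settle_999"]],
      fitted_tau_ms = f$tau_ms,
      fitted_t_delay_ms = f$t_delay_ms,
      fitted_setpoint_uA = f$setpoint_uA)
  }
  per_edge <- do.call(rbind, rows)
  meas <- per_edge[, -1, drop = FALSE]
  summary <- data.frame(
    measure = names(meas),
    mean = vapply(meas, mean, numeric(1)),
    sd = vapply(meas, function(x) if (length(x) > 1) stats::sd(x) else 0,
                numeric(1)),
    row.names = NULL)
  structure(list(per_edge = per_edge, summary = summary,
                 n_edges = n_edges, fs_hz = fs_hz),
            class = "step_report")
}

#' @export
print.step_report <- function(x, ...) {
  cat(sprintf("<step_report> %d rising edges at %g Hz\n", x$n_edges, x$fs_hz))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Accuracy / precision protocol
#'
#' Replays the 26-level calibration protocol: set-points from 0 to 250 uA
#' in 10 uA increments, dwelling `dwell_s` each, in `reps` randomized
#' passes, analysing only the last `window_s` of each dwell (steady state).
#' Accuracy at a set-point is the signed mean of the repetition-mean errors
#' (delivered minus commanded); precision is the SD across the repetition
#' means.
#'
#' @param params a [plant_params()].
#' @param load a [load_model()].
#' @param setpoints_uA levels to test.
#' @param reps randomized repetitions of the full level set.
#' @param dwell_s seconds spent at each level.
#' @param window_s analysed tail of each dwell.
#' @param fs_hz acquisition rate (100 Hz in the hardware protocol).
#' @param seed seed for the randomized level order.
#' @return List of class `"accuracy_report"` with `table` (26 rows:
#'   `setpoint_uA`, `accuracy_nA`, `precision_nA`, `n_reps`) and the
#'   protocol geometry.
#' @export
run_accuracy_precision_protocol <- function(params = plant_params(),
                                            load = load_model(),
                                            setpoints_uA = seq(0, 250, by = 10),
                                            reps = 50, dwell_s = 5,
                                            window_s = 0.5, fs_hz = 100,
                                            seed = 1L) {
  order_sp <- .with_seed(seed,
    unlist(lapply(seq_len(reps), function(r) sample(setpoints_uA))))
  n <- length(order_sp)
  dwell_ms <- dwell_s * 1000
  series <- data.frame(time_ms = (seq_len(n) - 1L) * dwell_ms,
                       setpoint_uA = order_sp)
  tr <- simulate_response(series, params, load, fs_hz = fs_hz,
                          t_end_ms = n * dwell_ms - 1000 / fs_hz)
  # mean delivered current over the last window of each dwell
  dwell_idx <- findInterval(tr$time_ms, series$time_ms)
  in_window <- (tr$time_ms - (dwell_idx - 1L) * dwell_ms) >= (dwell_ms - window_s * 1000)
  mu <- tapply(tr$current_uA[in_window], dwell_idx[in_window], mean)
  err_nA <- (as.numeric(mu) - order_sp[as.integer(names(mu))]) * 1000
  sp_of_dwell <- order_sp[as.integer(names(mu))]
  tab <- data.frame(
    setpoint_uA = setpoints_uA,
    accuracy_nA = vapply(setpoints_uA,
      function(s) mean(err_nA[sp_of_dwell == s]), numeric(1)),
    precision_nA = vapply(setpoints_uA,
      function(s) stats::sd(err_nA[sp_of_dwell == s]), numeric(1)),
    n_reps = vapply(setpoints_uA,
      function(s) sum(sp_of_dwell == s), numeric(1)))
  structure(list(table = tab, reps = reps, dwell_s = dwell_s,
                 window_s = window_s, fs_hz = fs_hz, seed = seed),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d set-points x %d reps, last %g s at %g Hz\n",
              nrow(x$table), x$reps, x$window_s, x$fs_hz))
  print(utils::head(x$table, 5), row.names = FALSE)
  if (nrow(x$table) > 5) cat("  ...\n")
  invisible(x)
}

#' Fade-duration rounding-error surface
#'
#' Evaluates [fade_duration_error()] on the full settings grid
#' (current 10-250 uA x fade 2-60 s): the error every valid standalone
#' configuration incurs from the integer sample-rate declaration.
#'
#' @return data.frame `current_uA`, `fade_s`, `error_s` covering the whole
#'   grid (14,219 cells).
#' @export
rounding_error_surface <- function() {
  g <- expand.grid(current_uA = 10:250, fade_s = 2:60)
  g$error_s <- fade_duration_error(g$current_uA, g$fade_s)
  g
}

#' Displayed-voltage error curve
#'
#' [display_error_components()] over all 1024 ADC codes: the linear
#' coefficient-approximation component, the bounded integer-rounding
#' component, and their (exact) sum.
#'
#' @return data.frame with one row per code 0-1023.
#' @export
display_error_curve <- function() {
  display_error_components(0:1023)
}
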