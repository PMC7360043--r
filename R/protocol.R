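#' @name protocol
#' @title Serial command protocol
#' @description
#' The host drives the stimulator over a byte transport with single-letter
#' commands terminated by carriage return: `IX` writes X to the 10-bit
#' set-point register (0.25 uA per count), `+`/`-` step the register by one
#' count, `A` reads the register back, and `v`/`i` read the raw 10-bit ADC
#' conversions of the load-voltage and current channels. Every command is
#' acknowledged with a hand-check — the echo of its first character —
#' unless it failed, in which case the device replies with one of the error
#' literals `EOFBR` (receive buffer overflow), `ENOTCMD` (unknown command)
#' or `EOOL` (value out of limit). The host must wait for the hand-check
#' before sending the next command.
NULL

# protocol constants: CR terminator, 8-octet receive buffer ("I1000" + CR
# fits; anything longer overflows), 1000-count ceiling (250 uA)
.TERMINATOR <- "\r"
.CMD_BUFFER_OCTETS <- 8L
.SETPOINT_LIMIT <- 1000L

#' Parse one command frame
#'
#' Parses the text of a frame (terminator excluded) into a command object,
#' or a protocol error: `EOFBR` when the frame would overflow the 8-octet
#' receive buffer, `ENOTCMD` for an unrecognized command, `EOOL` for a SET
#' value above the 1000-count (250 uA) ceiling.
#'
#' @param text frame content, e.g. `"I400"`, `"+"`, `"A"`.
#' @return A list of class `"tes_command"` with `kind` (one of `SET`,
#'   `INC`, `DEC`, `READ_SETPOINT`, `READ_VOLTAGE`, `READ_CURRENT`) and
#'   `value` (SET only), or class `"tes_protocol_error"` with `code`.
#' @examples
#' parse_command("I400")$value  # 400 counts = 100 uA
#' parse_command("Z9")$code     # "ENOTCMD"
#' @export
parse_command <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (nchar(text) + 1L > .CMD_BUFFER_OCTETS)      # +1: the terminator octet
    return(.protocol_error("EOFBR"))
  if (nchar(text) == 0L)
    return(.protocol_error("ENOTCMD"))
  head <- substr(text, 1, 1)
  rest <- substring(text, 2)
  if (head == "I") {
    if (!grepl("^[0-9]+$", rest)) return(.protocol_error("ENOTCMD"))
    value <- as.integer(rest)
    if (value > .SETPOINT_LIMIT) return(.protocol_error("EOOL"))
    return(.command("SET", value))
  }
  if (nchar(rest) > 0L) return(.protocol_error("ENOTCMD"))
  switch(head,
    "+" = .command("INC"),
    "-" = .command("DEC"),
    "A" = .command("READ_SETPOINT"),
    "v" = .command("READ_VOLTAGE"),
    "i" = .command("READ_CURRENT"),
    .protocol_error("ENOTCMD"))
}

.command <- function(kind, value = NULL)
  structure(list(kind = kind, value = value), class = "tes_command")

.protocol_error <- function(code)
  structure(list(code = code), class = "tes_protocol_error")

#' Serialize a command to its wire text
#'
#' Inverse of [parse_command()] on valid commands (terminator excluded).
#'
#' @param cmd a `"tes_command"`.
#' @return Single string, e.g. `"I400"`.
#' @export
format_command <- function(cmd) {
  stopifnot(inherits(cmd, "tes_command"))
  switch(cmd$kind,
    SET = paste0("I", cmd$value),
    INC = "+", DEC = "-",
    READ_SETPOINT = "A", READ_VOLTAGE = "v", READ_CURRENT = "i")
}

#' Execute a command against a device in computer-controlled mode
#'
#' `SET` writes the register, `INC`/`DEC` move it one count (0.25 uA) and
#' clamp at 0 and at the 1000-count ceiling (never wrap), `A` reads the
#' register, `v`/`i` read the raw 10-bit ADC codes. The reply carries the
#' hand-check character (first character of the command) or, for a failed
#' parse, the error literal.
#'
#' @param dev a [computer_device()] (or a parse error to propagate).
#' @param cmd a `"tes_command"` or `"tes_protocol_error"`.
#' @return A list of class `"tes_reply"`: `handcheck_char`, `payload`
#'   (integer or `NULL`), `error` (code or `NULL`).
#' @export
execute_command <- function(dev, cmd) {
  if (inherits(cmd, "tes_protocol_error"))
    return(structure(list(handcheck_char = NULL, payload = NULL,
                          error = cmd$code), class = "tes_reply"))
  stopifnot(inherits(cmd, "tes_command"))
  payload <- NULL
  switch(cmd$kind,
    SET = { dev$set_setpoint(cmd$value) },
    INC = { dev$set_setpoint(min(.SETPOINT_LIMIT, dev$setpoint_counts + 1L)) },
    DEC = { dev$set_setpoint(max(0L, dev$setpoint_counts - 1L)) },
    READ_SETPOINT = { payload <- dev$setpoint_counts },
    READ_VOLTAGE  = { payload <- dev$measure()$adc_v_counts },
    READ_CURRENT  = { payload <- dev$measure()$adc_i_counts })
  structure(list(handcheck_char = substr(format_command(cmd), 1, 1),
                 payload = payload, error = NULL),
            class = "tes_reply")
}

#' @export
print.tes_reply <- function(x, ...) {
  cat("<tes_reply>", format_reply(x), "\n"); invisible(x)
}

#' Wire text of a reply
#'
#' Hand-check character followed by the ASCII decimal payload for the read
#' commands, or the bare error literal (terminator excluded).
#'
#' @param reply a `"tes_reply"`.
#' @return Single string, e.g. `"A800"`, `"I"`, `"EOOL"`.
#' @export
format_reply <- function(reply) {
  if (!is.null(reply$error)) return(reply$error)
  paste0(reply$handcheck_char,
         if (!is.null(reply$payload)) reply$payload else "")
}

#' Device register + measurement endpoint for computer-controlled mode
#'
#' A minimal device for the computer-controlled mode: the 10-bit set-point
#' register plus a measurement hook that synthesises the two ADC codes from
#' a load. The delivered current is taken as the register value (the analog
#' transient is modelled separately by [simulate_response()]); the
#' load-voltage channel sees the load voltage through the divide-by-six
#' amplifier against the 5 V ADC reference.
#'
#' @param load_kohm resistive load in kOhm, value or function of time (ms).
#' @param const a [conversion_constants()] list.
#' @return Environment of class `"computer_device"` with fields
#'   `setpoint_counts`, `set_setpoint(counts)`, `measure()`, `clock_ms`.
#' @export
computer_device <- function(load_kohm = 20, const = conversion_constants()) {
  dev <- new.env(parent = emptyenv())
  dev$setpoint_counts <- 0L
  dev$clock_ms <- 0L
  dev$const <- const
  dev$load_fun <- if (is.function(load_kohm)) load_kohm else function(t_ms) load_kohm
  dev$set_setpoint <- function(counts) dev$setpoint_counts <- as.integer(counts)
  dev$measure <- function() {
    i_uA <- dev$setpoint_counts * 0.25
    v_load <- i_uA * 1e-6 * dev$load_fun(dev$clock_ms) * 1000
    v_counts <- min(1023L, as.integer(.round_half_up(
      v_load / dev$const$divider_ratio_H / (dev$const$vdd_V / 1024))))
    list(adc_v_counts = v_counts, adc_i_counts = min(1023L, dev$setpoint_counts))
  }
  class(dev) <- "computer_device"
  dev
}

# ---- telemetry frames -------------------------------------------------------

.PREFIX_PHASE <- c("+" = "fade-in", "*" = "stimulating",
                   "#" = "paused", "-" = "fade-out")

#' Telemetry frame
#'
#' During stimulation the device reports the load impedance every 0.1 s as
#' `<prefix><integer>KR`, the prefix encoding the phase: `+` fade-in,
#' `*` stimulation in progress, `#` paused, `-` fade-out.
#'
#' @param phase_prefix one of `"+"`, `"*"`, `"#"`, `"-"`.
#' @param impedance_kohm non-negative integer impedance.
#' @return List of class `"telemetry_frame"`.
#' @export
telemetry_frame <- function(phase_prefix, impedance_kohm) {
  if (!phase_prefix %in% names(.PREFIX_PHASE))
    stop("invalid telemetry prefix: ", phase_prefix, call. = FALSE)
  if (impedance_kohm < 0 || impedance_kohm != floor(impedance_kohm))
    stop("impedance must be a non-negative integer (kOhm)", call. = FALSE)
  structure(list(phase_prefix = phase_prefix,
                 impedance_kohm = as.integer(impedance_kohm),
                 phase = unname(.PREFIX_PHASE[phase_prefix])),
            class = "telemetry_frame")
}

#' @rdname telemetry_frame
#' @param frame a `"telemetry_frame"`.
#' @export
format_telemetry_frame <- function(frame) {
  stopifnot(inherits(frame, "telemetry_frame"))
  paste0(frame$phase_prefix, frame$impedance_kohm, "KR")
}

#' @rdname telemetry_frame
#' @param text frame text such as `"*25KR"`.
#' @export
parse_telemetry_frame <- function(text) {
  m <- regmatches(text, regexec("^([-+*#])([0-9]+)KR$", text))[[1]]
  if (length(m) != 3)
    stop("malformed telemetry frame: ", text, call. = FALSE)
  telemetry_frame(m[2], as.integer(m[3]))
}

# ---- transport + host session ----------------------------------------------

#' In-memory loopback byte transport
#'
#' A pair of byte queues standing in for the serial link: the host writes
#' command bytes, the device end consumes them up to each terminator and
#' pushes reply bytes back. [serve_pending()] runs the device side;
#' buffer-overflow handling (frames of 8 octets or more yield `EOFBR` and
#' the remainder of the frame is discarded) lives here, as on the device.
#'
#' @param dev a [computer_device()] served by this transport.
#' @return Environment of class `"loopback_transport"` with `send(text)`,
#'   `recv()` (one reply frame or `NULL`), and `serve_pending()`.
#' @export
loopback_transport <- function(dev) {
  tr <- new.env(parent = emptyenv())
  tr$dev <- dev
  tr$to_device <- character(0)    # accumulated unframed bytes, host -> device
  tr$to_host <- character(0)      # complete reply frames, device -> host
  tr$send <- function(text) {
    tr$to_device <- c(tr$to_device, strsplit(paste0(text, .TERMINATOR), "")[[1]])
    invisible(NULL)
  }
  tr$serve_pending <- function() {
    repeat {
      term <- match(.TERMINATOR, tr$to_device)
      if (is.na(term)) break
      frame <- paste(tr$to_device[seq_len(term - 1L)], collapse = "")
      tr$to_device <- tr$to_device[-seq_len(term)]
      reply <- execute_command(tr$dev, parse_command(frame))
      tr$to_host <- c(tr$to_host, format_reply(reply))
    }
    invisible(NULL)
  }
  tr$recv <- function() {
    if (!length(tr$to_host)) return(NULL)
    out <- tr$to_host[1]
    tr$to_host <- tr$to_host[-1]
    out
  }
  class(tr) <- "loopback_transport"
  tr
}

#' Run a hand-checked command session
#'
#' Sends each command over the transport and waits for its reply before
#' sending the next — the hand-check discipline. An error reply (or a
#' hand-check character that does not echo the command) surfaces in the
#' transcript and halts the remaining schedule.
#'
#' @param transport a [loopback_transport()] (or compatible object with
#'   `send`/`recv`/`serve_pending`).
#' @param commands character vector of command texts, or list of
#'   `"tes_command"` objects.
#' @param times_ms optional send timestamps (defaults to 0, 1, 2, ... ms).
#' @return A transcript data.frame: `timestamp_ms`, `direction`
#'   (`"host"`/`"device"`), `text`, `ok`.
#' @export
host_session <- function(transport, commands, times_ms = NULL) {
  if (is.list(commands))
    commands <- vapply(commands, format_command, character(1))
  n <- length(commands)
  if (is.null(times_ms)) times_ms <- seq_len(n) - 1L
  stopifnot(length(times_ms) == n)
  rows <- vector("list", 2L * n)
  k <- 0L
  for (j in seq_len(n)) {
    transport$send(commands[j])
    k <- k + 1L
    rows[[k]] <- data.frame(timestamp_ms = times_ms[j], direction = "host",
                            text = commands[j], ok = TRUE)
    transport$serve_pending()
    reply <- transport$recv()
    if (is.null(reply)) stop("reply timeout", call. = FALSE)
    is_err <- reply %in% c("EOFBR", "ENOTCMD", "EOOL")
    echo_ok <- !is_err && substr(reply, 1, 1) == substr(commands[j], 1, 1)
    k <- k + 1L
    rows[[k]] <- data.frame(timestamp_ms = times_ms[j], direction = "device",
                            text = reply, ok = echo_ok)
    if (is_err || !echo_ok) break
  }
  if (k == 0L)
    return(data.frame(timestamp_ms = integer(0), direction = character(0),
                      text = character(0), ok = logical(0)))
  do.call(rbind, rows[seq_len(k)])
}
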