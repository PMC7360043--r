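# Firmware state machine: phase sequencing, clocks, warnings, pause/resume.

quick_settings <- function(...) stim_settings(10, 10, 2, 2, 150, ...)

test_that("a standalone session runs fade-in, plateau, fade-out on schedule", {
  dev <- tes_device(quick_settings())
  run_session(dev)
  expect_identical(dev$phase, "DONE")
  expect_identical(dev$tick_ms, 14000L)     # 2 + 10 + 2 s, sample rate exact
  ev <- device_events(dev)
  phases <- ev$payload[ev$event == "phase"]
  expect_identical(phases, c("FADE_IN", "STIM", "FADE_OUT", "DONE"))
  # countdown fires once per plateau second and reaches zero
  cd <- ev[ev$event == "countdown", ]
  expect_identical(nrow(cd), 10L)
  expect_identical(as.integer(cd$payload[10]), 0L)
  expect_true(all(diff(cd$timestamp_ms) == 1000L))
  # set-point ramps by one count per fade step and peaks at the plateau code
  sp <- setpoint_series(dev)
  expect_equal(max(sp$setpoint_uA), 10)
  expect_true(all(abs(diff(sp$setpoint_uA)) == 0.25))
  # conservation: fade-in increments sum to the plateau set-point exactly
  d <- diff(c(0, sp$setpoint_uA))
  expect_equal(sum(d[d > 0][1:40]), 10)
})

test_that("telemetry frames every 100 ms carry the phase prefix", {
  dev <- tes_device(quick_settings(telemetry_enabled = TRUE))
  run_session(dev)
  ev <- device_events(dev)
  tel <- ev[ev$event == "telemetry", ]
  expect_true(all(diff(tel$timestamp_ms) == 100L))
  prefix <- substr(tel$payload, 1, 1)
  # the fade completes and the countdown starts exactly on the 2 s / 12 s marks
  expect_identical(unique(prefix[tel$timestamp_ms < 2000]), "+")
  expect_identical(unique(prefix[tel$timestamp_ms >= 2000 & tel$timestamp_ms < 12000]), "*")
  expect_identical(unique(prefix[tel$timestamp_ms >= 12000]), "-")
  # every frame parses back
  frames <- lapply(tel$payload, parse_telemetry_frame)
  expect_true(all(vapply(frames, inherits, logical(1), "telemetry_frame")))
})

test_that("display refresh fires every 250 ms while the device is active", {
  dev <- tes_device(quick_settings())
  run_session(dev)
  ev <- device_events(dev)
  refresh <- ev[ev$event == "display_refresh", ]
  expect_true(all(diff(refresh$timestamp_ms) == 250L))
  expect_identical(refresh$timestamp_ms[1], 250L)
})

test_that("impedance above the threshold raises the buzzer warning", {
  # load drifting 20 -> 160 kOhm crosses the 150 kOhm ceiling once
  drifting <- function(t_ms) 20 + (160 - 20) * pmin(1, t_ms / 14000)
  dev <- tes_device(quick_settings(), load_kohm = drifting)
  run_session(dev)
  ev <- device_events(dev)
  expect_true(any(ev$event == "warning"))
  expect_true(any(ev$event == "buzzer"))
  expect_true(dev$warning_active)
  first_warn <- min(ev$timestamp_ms[ev$event == "warning"])
  expect_gt(first_warn, 12000)   # threshold crossed near the session end
  # a steady in-range load never warns
  dev2 <- tes_device(quick_settings(), load_kohm = 20)
  run_session(dev2)
  expect_false(any(device_events(dev2)$event == "warning"))
})

test_that("plateau time is conserved across arbitrary pause/resume sequences", {
  for (pauses in list(c(4000), c(3500, 9000), c(3000, 6000, 9000))) {
    acts <- do.call(rbind, lapply(seq_along(pauses), function(k)
      data.frame(at_ms = pauses[k] + c(0, 2500), action = c("PAUSE", "RESUME"))))
    acts <- acts[order(acts$at_ms), ]
    dev <- tes_device(stim_settings(10, 20, 2, 2, 150))
    run_session(dev, actions = acts)
    expect_identical(dev$phase, "DONE")
    expect_identical(dev$stim_ms, 20000L)   # plateau ms == duration_s * 1000
    phases <- device_events(dev)$payload
    expect_identical(sum(phases == "PAUSED"), length(pauses))
    expect_identical(sum(phases == "STIM"), length(pauses) + 1L)
  }
})

test_that("pause fades out, resume replays the fade-in with frozen countdown", {
  dev <- tes_device(stim_settings(10, 20, 2, 2, 150))
  run_session(dev, actions = data.frame(at_ms = c(5000, 12000),
                                        action = c("PAUSE", "RESUME")))
  ev <- device_events(dev)
  phases <- ev$payload[ev$event == "phase"]
  expect_identical(phases, c("FADE_IN", "STIM", "PAUSING", "PAUSED",
                             "RESUMING", "STIM", "FADE_OUT", "DONE"))
  # remaining_s is frozen across the pause gap
  cd <- ev[ev$event == "countdown", ]
  gap <- which(diff(cd$timestamp_ms) > 1000)
  expect_length(gap, 1)
  expect_identical(as.integer(cd$payload[gap]), as.integer(cd$payload[gap + 1]) + 1L)
})

test_that("illegal control transitions are rejected", {
  dev <- tes_device(quick_settings())
  expect_error(control_action(dev, "PAUSE"), "illegal in phase IDLE")
  expect_error(control_action(dev, "RESUME"), "illegal")
  control_action(dev, "START")
  expect_error(control_action(dev, "START"), "illegal")
  expect_error(control_action(dev, "PAUSE"), "illegal")  # still fading in
  # abort is only legal from PAUSED (zero current)
  while (dev$phase != "STIM") device_tick(dev)
  expect_error(control_action(dev, "ABORT"), "illegal")
  control_action(dev, "PAUSE")
  while (dev$phase != "PAUSED") device_tick(dev)
  control_action(dev, "ABORT")
  expect_identical(dev$phase, "ABORTED")
  expect_error(device_tick(dev), "ended")
})
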