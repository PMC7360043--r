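# Command grammar, hand-check discipline, error codes, telemetry dialect.

test_that("command grammar parses and serializes round-trip", {
  cmd <- parse_command("I400")
  expect_identical(cmd$kind, "SET")
  expect_identical(cmd$value, 400L)
  for (txt in c("I0", "I1", "I1000", "+", "-", "A", "v", "i")) {
    parsed <- parse_command(txt)
    expect_s3_class(parsed, "tes_command")
    expect_identical(format_command(parsed), txt)
  }
})

test_that("protocol errors: unknown command, out-of-limit value, buffer overflow", {
  expect_identical(parse_command("Z9")$code, "ENOTCMD")
  expect_identical(parse_command("")$code, "ENOTCMD")
  expect_identical(parse_command("Ix")$code, "ENOTCMD")
  expect_identical(parse_command("++")$code, "ENOTCMD")
  expect_identical(parse_command("I2000")$code, "EOOL")
  expect_identical(parse_command("I1001")$code, "EOOL")
  expect_s3_class(parse_command("I1000"), "tes_command")   # ceiling is legal
  # 8-octet receive buffer: a frame whose bytes (with terminator) exceed it
  expect_identical(parse_command("I1000000")$code, "EOFBR")
  expect_identical(parse_command("ABCDEFGH")$code, "EOFBR")
})

test_that("register commands execute with read-after-write and clamping", {
  dev <- computer_device()
  r <- execute_command(dev, parse_command("I800"))
  expect_identical(r$handcheck_char, "I")
  expect_null(r$error)
  a <- execute_command(dev, parse_command("A"))
  expect_identical(a$payload, 800L)
  # one '+' moves the register one count = 0.25 uA
  execute_command(dev, parse_command("I400"))
  execute_command(dev, parse_command("+"))
  expect_identical(dev$setpoint_counts, 401L)
  # clamped at the 1000-count ceiling and at zero, never wrapping
  execute_command(dev, parse_command("I1000"))
  execute_command(dev, parse_command("+"))
  expect_identical(dev$setpoint_counts, 1000L)
  execute_command(dev, parse_command("I0"))
  execute_command(dev, parse_command("-"))
  expect_identical(dev$setpoint_counts, 0L)
})

test_that("v returns the ADC code of the divided load voltage", {
  # 200 uA into 20 kOhm -> 4 V across the load, /6 amplifier, 5 V / 1024 ADC
  dev <- computer_device(load_kohm = 20)
  execute_command(dev, parse_command("I800"))
  v <- execute_command(dev, parse_command("v"))
  expect_identical(v$payload, 137L)
  expect_identical(v$handcheck_char, "v")
  i <- execute_command(dev, parse_command("i"))
  expect_identical(i$payload, 800L)
})

test_that("telemetry frame grammar round-trips and rejects malformed text", {
  expect_identical(format_telemetry_frame(telemetry_frame("*", 25)), "*25KR")
  expect_identical(format_telemetry_frame(telemetry_frame("#", 25)), "#25KR")
  f <- parse_telemetry_frame("+0KR")
  expect_identical(f$phase, "fade-in")
  expect_identical(f$impedance_kohm, 0L)
  for (pfx in c("+", "*", "#", "-")) for (z in c(0L, 25L, 150L)) {
    fr <- telemetry_frame(pfx, z)
    expect_identical(parse_telemetry_frame(format_telemetry_frame(fr))$phase_prefix,
                     pfx)
  }
  expect_error(parse_telemetry_frame("25KR"), "malformed")
  expect_error(parse_telemetry_frame("*25"), "malformed")
  expect_error(telemetry_frame("!", 25), "prefix")
})

test_that("hand-check discipline: one in-order reply per command", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    cmds <- vapply(seq_len(n), function(j) {
      k <- sample(4, 1)
      switch(k, paste0("I", sample(0:1000, 1)), "+", "-", "A")
    }, character(1))
    tr <- loopback_transport(computer_device())
    transcript <- host_session(tr, cmds)
    host_rows <- transcript[transcript$direction == "host", ]
    dev_rows <- transcript[transcript$direction == "device", ]
    # exactly one reply per command, order preserved
    expect_identical(nrow(host_rows), n)
    expect_identical(nrow(dev_rows), n)
    expect_identical(host_rows$text, cmds)
    expect_identical(substr(dev_rows$text, 1, 1), substr(cmds, 1, 1))
    expect_true(all(dev_rows$ok))
  }
})

test_that("an error reply surfaces and halts the remaining schedule", {
  tr <- loopback_transport(computer_device())
  transcript <- host_session(tr, c("I100", "I2000", "I200"))
  expect_identical(sum(transcript$direction == "host"), 2L)  # third never sent
  expect_identical(transcript$text[transcript$direction == "device"][2], "EOOL")
  expect_false(transcript$ok[4])
  # empty command sequence gives an empty transcript
  empty <- host_session(loopback_transport(computer_device()), character(0))
  expect_identical(nrow(empty), 0L)
})
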