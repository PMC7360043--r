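# Characterization pipeline: onset detection, settle times, model fitting,
# step and accuracy/precision protocols.

test_that("response time is the first sample above 0.1 uA after the send", {
  p <- plant_params(noise_sd_nA = 0)
  tr <- simulate_response(data.frame(time_ms = 0, setpoint_uA = 250), p,
                          load_model(), fs_hz = 1000, t_end_ms = 100)
  rt <- detect_response_time(tr)
  expect_gte(rt, p$t_delay_ms)          # cannot precede the dead time
  expect_lte(rt, p$t_delay_ms + 1)      # within one 1 kHz sample of it
  ideal <- simulate_response(data.frame(time_ms = 0, setpoint_uA = 250),
                             plant_params(tau_ms = 0, t_delay_ms = 0),
                             load_model(), fs_hz = 1000, t_end_ms = 10)
  expect_lte(detect_response_time(ideal), 1)
  flat <- simulate_response(data.frame(time_ms = 0, setpoint_uA = 0),
                            plant_params(), load_model(), fs_hz = 1000,
                            t_end_ms = 10)
  expect_error(detect_response_time(flat), "never exceeds")
})

test_that("settle times match the first-order closed form on random draws", {
  set.seed(2024)
  for (k in 1:100) {
    tau <- runif(1, 20, 400)
    delay <- runif(1, 0, 30)
    fs <- 1000
    tr <- simulate_response(data.frame(time_ms = 0, setpoint_uA = 250),
                            plant_params(tau_ms = tau, t_delay_ms = delay,
                                         noise_sd_nA = 0),
                            load_model(), fs_hz = fs,
                            t_end_ms = delay + tau * 8)
    st <- settle_times(tr, 250)
    expect_lte(abs(st[["settle_99"]] - (delay + tau * log(100))), 1000 / fs)
    expect_lte(abs(st[["settle_999"]] - (delay + tau * log(1000))), 1000 / fs)
  }
})

test_that("a noisy trace settles late or not at all, and reports NA cleanly", {
  p <- plant_params(noise_sd_nA = 5000, rng_seed = 5L)  # 5 uA noise >> band
  tr <- simulate_response(data.frame(time_ms = 0, setpoint_uA = 250), p,
                          load_model(), fs_hz = 1000, t_end_ms = 3000)
  st <- settle_times(tr, 250)
  clean <- plant_params(noise_sd_nA = 0)
  ref <- settle_times(simulate_response(
    data.frame(time_ms = 0, setpoint_uA = 250), clean, load_model(),
    fs_hz = 1000, t_end_ms = 3000), 250)
  expect_true(is.na(st[["settle_999"]]) ||
                st[["settle_999"]] >= ref[["settle_999"]])
})

test_that("first-order fit recovers tau and dead time within 1 % (noiseless)", {
  for (pars in list(c(194.5, 14.21), c(35, 14.21))) {
    p <- plant_params(tau_ms = pars[1], t_delay_ms = pars[2], noise_sd_nA = 0)
    tr <- simulate_response(data.frame(time_ms = 0, setpoint_uA = 250), p,
                            load_model(), fs_hz = 1000, t_end_ms = 3000)
    f <- fit_first_order(tr)
    expect_lt(abs(f$tau_ms - pars[1]) / pars[1], 0.01)
    expect_lt(abs(f$t_delay_ms - pars[2]) / pars[2], 0.01)
    expect_lt(abs(f$setpoint_uA - 250) / 250, 0.01)
  }
})

test_that("first-order fit recovers tau within 5 % at 1 % noise", {
  p <- plant_params(noise_sd_nA = 2500, rng_seed = 11L)  # 2.5 uA = 1 % of 250
  tr <- simulate_response(data.frame(time_ms = 0, setpoint_uA = 250), p,
                          load_model(), fs_hz = 1000, t_end_ms = 3000)
  f <- fit_first_order(tr)
  expect_lt(abs(f$tau_ms - p$tau_ms) / p$tau_ms, 0.05)
})

test_that("fit rejects a degenerate flat window", {
  flat <- data.frame(time_ms = 0:100, current_uA = rep(0, 101))
  expect_error(fit_first_order(flat), "degenerate")
})

test_that("step protocol aggregates per-edge measures deterministically", {
  rep1 <- run_step_protocol(n_edges = 3, fit = FALSE)
  expect_identical(nrow(rep1$per_edge), 3L)
  # noiseless emulation: every edge identical, SD zero
  expect_equal(rep1$summary$sd[rep1$summary$measure == "response_time_ms"], 0)
  expect_equal(rep1$summary$sd[rep1$summary$measure == "settle_99_ms"], 0)
  # single-edge report degrades cleanly
  rep2 <- run_step_protocol(n_edges = 1, fit = FALSE)
  expect_identical(nrow(rep2$per_edge), 1L)
  expect_equal(rep2$summary$sd, rep(0, nrow(rep2$summary)))
  # identical seeds give identical reports end to end
  p <- plant_params(noise_sd_nA = 10, rng_seed = 3L)
  a <- run_step_protocol(p, n_edges = 2, fit = FALSE)
  b <- run_step_protocol(p, n_edges = 2, fit = FALSE)
  expect_identical(a$per_edge, b$per_edge)
  # and the mean settle times stay within two samples of the closed form
  cf99 <- p$t_delay_ms + p$tau_ms * log(100)
  expect_lte(abs(mean(a$per_edge$settle_99_ms) - cf99), 2)
})

test_that("accuracy is zero on a noiseless calibrated emulator", {
  rep <- run_accuracy_precision_protocol(plant_params(noise_sd_nA = 0),
                                         reps = 4)
  expect_identical(nrow(rep$table), 26L)
  expect_identical(rep$table$setpoint_uA, seq(0, 250, by = 10))
  # every set-point is a multiple of 0.25 uA: representable exactly; only a
  # sub-picoampere exponential transient tail remains in the 0.5 s window
  expect_lt(max(abs(rep$table$accuracy_nA)), 1e-3)
  expect_true(all(rep$table$precision_nA >= 0 | is.na(rep$table$precision_nA)))
})

test_that("a gain error shows up as a proportional accuracy bias", {
  rep <- run_accuracy_precision_protocol(
    plant_params(gain_error = 1.001, noise_sd_nA = 0), reps = 2)
  expect_equal(rep$table$accuracy_nA, rep$table$setpoint_uA * 1000 * 0.001,
               tolerance = 1e-6)
})

test_that("precision under seeded noise matches the repetition-mean scaling", {
  # 10 nA white noise, 50 samples per window mean -> SD of means ~ 1.41 nA
  rep <- run_accuracy_precision_protocol(
    plant_params(noise_sd_nA = 10, rng_seed = 21L), reps = 50, seed = 2L)
  mid <- rep$table$precision_nA[rep$table$setpoint_uA > 0]
  expect_gt(mean(mid), 1.0)
  expect_lt(mean(mid), 1.9)
  # determinism end to end
  rep2 <- run_accuracy_precision_protocol(
    plant_params(noise_sd_nA = 10, rng_seed = 21L), reps = 50, seed = 2L)
  expect_identical(rep$table, rep2$table)
})

test_that("error surfaces cover their full grids", {
  surf <- rounding_error_surface()
  expect_identical(nrow(surf), 14219L)
  expect_identical(sort(unique(surf$current_uA)), 10:250)
  expect_identical(sort(unique(surf$fade_s)), 2:60)
  curve <- display_error_curve()
  expect_identical(curve$d_val, 0:1023)
})
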