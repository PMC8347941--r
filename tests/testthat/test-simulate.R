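test_that("noise-free simulation yields one clean pulse per step per channel", {
  rec <- simulate_recording("normal", n_steps = 5)
  pulses <- detect_all_pulses(rec)
  counts <- table(pulses$channel)
  expect_true(all(counts[gait_channels()] == 5))
  expect_true(all(rec$voltages >= 0 &
                    rec$voltages <= rec$truth$electrical$supply_voltage))
})

test_that("identical seed and arguments reproduce the recording bit for bit", {
  a <- simulate_recording("scrolling", n_steps = 4, noise_sd = 0.08,
                          drift = 0.002, seed = 11)
  b <- simulate_recording("scrolling", n_steps = 4, noise_sd = 0.08,
                          drift = 0.002, seed = 11)
  expect_identical(a$voltages, b$voltages)
  c <- simulate_recording("scrolling", n_steps = 4, noise_sd = 0.08,
                          drift = 0.002, seed = 12)
  expect_false(identical(b$voltages, c$voltages))
})

test_that("straight-leg gait keeps the right heel loaded longer than the forefoot", {
  rec <- simulate_recording("straight_leg", n_steps = 6)
  params <- extract_gait_parameters(rec)
  d <- as.data.frame(params)
  st <- d[d$parameter == "stance", ]
  expect_gt(mean(st$value[st$channel == "R3"]),
            mean(st$value[st$channel == "R1"]))
})

test_that("unknown gait modes and invalid noise are rejected", {
  expect_error(simulate_recording("moonwalk"), "unknown gait mode")
  expect_error(simulate_recording("normal", noise_sd = -0.1))
})

test_that("extraction round-trips the configured phase fractions on clean signals", {
  # property over several cadences and phase models: recovered fractions
  # match the configured ones within one sample period per cycle
  cases <- list(
    list(cadence = 1.0, stance = 0.60, ds = 0.20),   # symmetric alternation
    list(cadence = 0.8, stance = 0.65, ds = 0.30),   # symmetric, slow cycle
    list(cadence = 1.0, stance = 0.55, ds = 0.15))   # shifted single episode
  for (cs in cases) {
    pm <- gait_phase_model(cs$stance, cs$ds)
    rec <- simulate_recording("normal", cadence = cs$cadence, n_steps = 8,
                              phase_model = pm)
    pf <- phase_fractions(rec)
    tol <- (1 / rec$sampling_rate) * cs$cadence  # one sample as cycle fraction
    expect_equal(unname(pf$stance_fraction[["left"]]), cs$stance,
                 tolerance = tol / cs$stance)
    expect_equal(unname(pf$stance_fraction[["right"]]), cs$stance,
                 tolerance = tol / cs$stance)
    expect_equal(pf$double_support_fraction, cs$ds, tolerance = 2 * tol / cs$ds)
    expect_equal(pf$cycle, 1 / cs$cadence, tolerance = tol)
  }
})

test_that("simulated drift shifts the trace linearly without breaking detection", {
  rec <- simulate_recording("normal", n_steps = 5, drift = 0.005, seed = 3)
  counts <- table(detect_all_pulses(rec)$channel)
  expect_true(all(counts[gait_channels()] == 5))
})
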