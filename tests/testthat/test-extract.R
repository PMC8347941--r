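test_that("amplitude, stance and abruptness tables are simple per-pulse arithmetic", {
  pulses <- rbind(
    make_pulses("L1", onsets = c(1.0, 2.0), widths = c(0.6, 0.6),
                amps = c(1.0, 3.0), rise = 0.15),
    make_pulses("R1", onsets = c(1.5, 2.5), widths = c(0.5, 0.55),
                amps = c(2.0, 2.0), rise = 0.1))
  a <- extract_amplitudes(pulses)
  expect_equal(a$value[a$channel == "L1"], c(1.0, 3.0))
  expect_equal(mean(a$value[a$channel == "L1"]), 2.0)
  s <- extract_stance_durations(pulses)
  expect_equal(s$value[s$channel == "L1"], c(0.6, 0.6))
  expect_equal(s$value[s$channel == "R1"], c(0.5, 0.55))
  d <- extract_abruptness(pulses)
  expect_equal(d$value[d$channel == "L1"], c(0.15, 0.15))
})

test_that("per-foot aggregate stance equals the configured 0.60 s on clean signals", {
  rec <- simulate_recording("normal", cadence = 1, n_steps = 6)
  env <- foot_envelopes(detect_all_pulses(rec))
  expect_equal(env$left$end - env$left$start, rep(0.6, 6), tolerance = 0.017)
  expect_equal(env$right$end - env$right$start, rep(0.6, 6), tolerance = 0.017)
})

test_that("extracted abruptness matches the analytic edge-crossing oracle", {
  # heel channel L3 of the normal profile: continuous raised-cosine load,
  # mapped through the divider; the oracle finds the continuous time at
  # which the voltage first reaches 90% of its plateau value
  rec <- simulate_recording("normal", cadence = 1, n_steps = 6,
                            rise_time = 0.2)
  prof <- rec$truth$profile
  em <- rec$truth$electrical
  win <- prof$windows["L3", ]
  width <- (win[2] - win[1]) * 0.6
  rf <- min(0.2 / width, 0.45)              # heel rise scale is 1.0
  v0 <- load_voltage(0, em)
  vpk <- load_voltage(prof$peaks[["L3"]], em)
  vshape <- function(t) {                   # t seconds after channel onset
    u <- t / width
    load <- prof$peaks[["L3"]] *
      ifelse(u < rf, 0.5 * (1 - cos(pi * u / rf)), 1)
    load_voltage(load, em)
  }
  t90 <- uniroot(function(t) vshape(t) - (v0 + 0.9 * (vpk - v0)),
                 c(1e-6, rf * width))$root
  d <- as.data.frame(extract_gait_parameters(rec))
  d90 <- mean(d$value[d$parameter == "abruptness" & d$channel == "L3"])
  expect_equal(d90, t90, tolerance = 2 / rec$sampling_rate / t90)
})

test_that("unevenness pairing matches the exhaustive nearest-onset oracle", {
  # perfectly alternating gait, cycle 1.0 s
  pulses <- rbind(
    make_pulses("L1", onsets = c(0, 1, 2, 3), widths = 0.6, amps = 2),
    make_pulses("R1", onsets = c(0.5, 1.5, 2.5, 3.5), widths = 0.6, amps = 2))
  u <- extract_unevenness(pulses)
  expect_true(all(u$value[u$parameter == "unevenness_LR"] == 0.5))
  expect_true(all(u$value[u$parameter == "unevenness_RL"] == 0.5))

  # left foot delayed: right onsets 0.4 after left, so L-R = 0.4, R-L = 0.6
  pulses2 <- rbind(
    make_pulses("L2", onsets = c(0, 1, 2, 3), widths = 0.6, amps = 2),
    make_pulses("R2", onsets = c(0.4, 1.4, 2.4, 3.4), widths = 0.6, amps = 2))
  u2 <- extract_unevenness(pulses2)
  expect_equal(u2$value[u2$parameter == "unevenness_LR"], rep(0.4, 4))
  expect_equal(u2$value[u2$parameter == "unevenness_RL"], rep(0.6, 3))

  # exhaustive pairing oracle on irregular onsets
  set.seed(7)
  lon <- sort(cumsum(runif(5, 0.8, 1.2)))
  ron <- sort(lon[1:5] + runif(5, 0.3, 0.7))
  pulses3 <- rbind(make_pulses("L3", lon, 0.5, 2),
                   make_pulses("R3", ron, 0.5, 2))
  u3 <- extract_unevenness(pulses3)
  expected_lr <- vapply(lon, function(t0) {
    nxt <- ron[ron > t0]; if (length(nxt)) nxt[1] - t0 else NA_real_
  }, numeric(1))
  expect_equal(u3$value[u3$parameter == "unevenness_LR"],
               expected_lr[!is.na(expected_lr)])
  # antisymmetry under strict alternation: L-R + R-L spans one cycle
  pulses4 <- rbind(make_pulses("L1", 0:4, 0.6, 2),
                   make_pulses("R1", 0:4 + 0.5, 0.6, 2))
  u4 <- extract_unevenness(pulses4)
  lr <- u4$value[u4$parameter == "unevenness_LR"]
  rl <- u4$value[u4$parameter == "unevenness_RL"]
  expect_equal(lr[1:4] + rl[1:4], rep(1.0, 4))
})

test_that("a foot without pulses on a paired sensor gives an empty shift column", {
  pulses <- make_pulses("L1", onsets = c(0, 1), widths = 0.6, amps = 2)
  expect_warning(u <- extract_unevenness(pulses), "sensor pair")
  expect_equal(nrow(u), 0)
})

test_that("symmetric shuffling gait has near-equal L-R and R-L shifts", {
  rec <- simulate_recording("scrolling", n_steps = 6)
  d <- as.data.frame(extract_gait_parameters(rec))
  for (k in 1:3) {
    lr <- mean(d$value[d$parameter == "unevenness_LR" &
                         d$channel == paste0("L", k)])
    rl <- mean(d$value[d$parameter == "unevenness_RL" &
                         d$channel == paste0("R", k)])
    expect_equal(lr, rl, tolerance = 0.12)
  }
})

test_that("load distribution ranking, dominance and tie-breaks behave as documented", {
  pulses <- rbind(make_pulses("R1", 0:1, 0.5, c(2.1, 2.1)),
                  make_pulses("R2", 0:1 + 0.05, 0.5, c(0.4, 0.4)),
                  make_pulses("R3", 0:1 + 0.02, 0.5, c(0.6, 0.6)),
                  make_pulses("L1", 0:1 + 0.5, 0.5, c(1.0, 1.0)))
  dist <- load_distribution_summary(extract_amplitudes(pulses))
  expect_identical(unname(dist$dominant[["right"]]), "R1")
  rr <- dist$ranking[dist$ranking$foot == "right", ]
  expect_identical(rr$channel, c("R1", "R3", "R2"))
  # exact tie: lower channel index wins
  tie <- rbind(make_pulses("L1", 0:1, 0.5, 1.5),
               make_pulses("L2", 0:1 + 0.03, 0.5, 1.5))
  dist2 <- load_distribution_summary(extract_amplitudes(tie))
  expect_identical(unname(dist2$dominant[["left"]]), "L1")
})

test_that("turnaround recordings are dominated by the left heel and right forefoot", {
  rec <- simulate_recording("turnaround", n_steps = 5)
  dist <- load_distribution_summary(extract_gait_parameters(rec))
  expect_identical(unname(dist$dominant[["left"]]), "L3")
  expect_identical(unname(dist$dominant[["right"]]), "R2")
})

test_that("extracted amplitudes match the forward-computed divider voltages", {
  set.seed(33)
  peaks <- stats::setNames(runif(6, 3, 20), gait_channels())
  prof <- gait_mode_profile("normal", peaks = peaks)
  rec <- simulate_recording(profile = prof, n_steps = 5)
  d <- as.data.frame(extract_gait_parameters(rec))
  for (ch in gait_channels()) {
    got <- mean(d$value[d$parameter == "amplitude" & d$channel == ch])
    expect_equal(got, oracle_amplitude(prof, ch), tolerance = 0.02)
  }
})

test_that("per-channel step counts differ by at most one between feet", {
  for (seed in 1:5) {
    rec <- simulate_recording("upstairs", n_steps = 5, noise_sd = 0.1,
                              seed = 600 + seed)
    amp <- extract_amplitudes(detect_all_pulses(rec))
    counts <- table(amp$channel)
    for (k in 1:3) {
      nl <- counts[paste0("L", k)]; nr <- counts[paste0("R", k)]
      expect_lte(abs(nl - nr), 1)
    }
  }
})
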