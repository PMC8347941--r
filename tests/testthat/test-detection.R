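# hand-built signature for rule tests
fake_signature <- function(dominant_left = "L3", dominant_right = "R3",
                           ratio = 1, imbalance = 0, cv = 0.03,
                           stance_asym = 0) {
  structure(list(
    dominant = c(left = dominant_left, right = dominant_right),
    amplitude_ratio = ratio,
    stance_asymmetry = stance_asym,
    shift_imbalance = c(pair1 = imbalance, pair2 = imbalance,
                        pair3 = imbalance),
    abruptness = stats::setNames(rep(0.12, 6), gait_channels()),
    step_cv = cv,
    n_steps = c(left = 6, right = 6)), class = "gait_signature")
}

test_that("a symmetric normal gait yields a balanced signature", {
  rec <- simulate_recording("normal", n_steps = 6)
  sig <- compute_signature(extract_gait_parameters(rec))
  expect_equal(sig$amplitude_ratio, 1, tolerance = 0.02)
  expect_lt(sig$stance_asymmetry, 0.02)
  expect_true(all(sig$shift_imbalance < 0.03))
  expect_lt(sig$step_cv, 0.02)
})

test_that("signature aggregation equals a direct loop over the table", {
  rec <- simulate_recording("turnaround", n_steps = 5, noise_sd = 0.05,
                            seed = 9)
  params <- extract_gait_parameters(rec)
  sig <- compute_signature(params)
  d <- as.data.frame(params)
  amp <- d[d$parameter == "amplitude", ]
  lv <- amp$value[amp$foot == "left"]; rv <- amp$value[amp$foot == "right"]
  expect_equal(sig$amplitude_ratio, mean(lv) / mean(rv))
  st <- d[d$parameter == "stance", ]
  expect_equal(sig$stance_asymmetry,
               abs(mean(st$value[st$foot == "left"]) -
                     mean(st$value[st$foot == "right"])))
  for (k in 1:3) {
    a <- d$value[d$parameter == "unevenness_LR" & d$channel == paste0("L", k)]
    b <- d$value[d$parameter == "unevenness_RL" & d$channel == paste0("R", k)]
    expect_equal(unname(sig$shift_imbalance[k]), abs(mean(a) - mean(b)))
  }
})

test_that("too few steps is an explicit error", {
  rec <- simulate_recording("normal", n_steps = 1)
  expect_error(compute_signature(extract_gait_parameters(rec)),
               "at least 2 steps")
})

test_that("rulebook scoring recognises the documented signatures", {
  # left heel + right forefoot dominance with a heavier left foot: turnaround
  s1 <- fake_signature("L3", "R2", ratio = 1.4)
  expect_identical(classify_mode(s1)$predicted_mode, "turnaround")
  # dominant R1 with symmetric shifts: shuffling
  s2 <- fake_signature("L3", "R1", ratio = 0.8)
  expect_identical(classify_mode(s2)$predicted_mode, "scrolling")
  # same dominance as turnaround but balanced with a rhythm shift:
  # straight leg
  s3 <- fake_signature("L3", "R2", ratio = 1.0, imbalance = 0.3)
  expect_identical(classify_mode(s3)$predicted_mode, "straight_leg")
  # determinism
  expect_identical(classify_mode(s1), classify_mode(s1))
})

test_that("the classifier recovers every generating mode on clean recordings", {
  for (m in gait_modes()) {
    rec <- simulate_recording(m, n_steps = 6)
    sig <- compute_signature(extract_gait_parameters(rec))
    expect_identical(classify_mode(sig)$predicted_mode, m)
  }
})

test_that("classification stays accurate under measurement noise", {
  # reduced replicate count for the routine suite; the acceptance test
  # runs the full 50 per mode
  correct <- 0; total <- 0
  for (m in gait_modes()) for (i in 1:6) {
    rec <- simulate_recording(m, n_steps = 6, noise_sd = 0.1,
                              seed = 5000 + 100 * match(m, gait_modes()) + i)
    sig <- suppressWarnings(compute_signature(extract_gait_parameters(rec)))
    correct <- correct + (classify_mode(sig)$predicted_mode == m)
    total <- total + 1
  }
  expect_gte(correct / total, 0.9)
})

test_that("no anomalies are flagged when the signature equals its baseline", {
  s <- fake_signature()
  res <- flag_anomalies(s, s)
  expect_length(res$flags, 0)
  expect_true(all(res$scores <= 1))
})

test_that("a straight-leg gait against a normal baseline raises phase asymmetry", {
  base <- compute_signature(extract_gait_parameters(
    simulate_recording("normal", n_steps = 6)))
  sig <- compute_signature(extract_gait_parameters(
    simulate_recording("straight_leg", n_steps = 6)))
  res <- flag_anomalies(sig, base)
  expect_true("phase_asymmetry" %in% res$flags)
  # imbalance injected by the simulator is ~0.3 s
  expect_equal(max(sig$shift_imbalance), 0.3, tolerance = 0.1)
})

test_that("the phase flag activates exactly at the configured threshold", {
  base <- fake_signature()
  sweep <- seq(0, 0.5, by = 0.05)
  scores <- numeric(length(sweep))
  for (i in seq_along(sweep)) {
    res <- flag_anomalies(fake_signature(imbalance = sweep[i]), base)
    scores[i] <- res$scores[["phase_asymmetry"]]
    expect_identical("phase_asymmetry" %in% res$flags, sweep[i] > 0.25)
  }
  expect_true(all(diff(scores) >= 0))  # monotone in injected asymmetry
})

test_that("a missing baseline falls back to population defaults with a warning", {
  expect_warning(res <- flag_anomalies(fake_signature(ratio = 1.6)),
                 "baseline")
  expect_true("load_asymmetry" %in% res$flags)
})
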