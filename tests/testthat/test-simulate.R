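test_that("the same seed reproduces a trial bit for bit", {
  spec <- trial_spec("G3", n_cycles = 4, seed = 99)
  a <- simulate_trial(spec)
  b <- simulate_trial(spec)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  expect_identical(a$imu$wrist_left$acc_z, b$imu$wrist_left$acc_z)
  expect_identical(a$markers$ski_right$z, b$markers$ski_right$z)
})

test_that("ground-truth phase identities hold exactly from the event times", {
  for (tech in c("G2", "G3", "G4")) {
    gt <- schedule_events(trial_spec(tech, n_cycles = 10, seed = 7))
    ev <- gt$events
    for (sd_ in c("left", "right")) {
      on <- sort(ev$time[ev$etype == "S_ON" & ev$side == sd_])
      off <- sort(ev$time[ev$etype == "S_OFF" & ev$side == sd_])
      n <- length(on) - 1L
      s_ct <- off[1:n] - on[1:n]
      s_sw <- on[2:(n + 1)] - off[1:n]
      s_cy <- diff(on)
      expect_equal(s_ct + s_sw, s_cy, tolerance = 1e-12)
      expect_true(all(s_ct > 0) && all(s_sw > 0))
    }
  }
})

test_that("scheduled events validate as an event series for 100 seeds", {
  for (seed in 1:100) {
    gt <- schedule_events(trial_spec("mixed", n_cycles = 6, seed = seed))
    expect_s3_class(ground_truth_events(gt), "event_series")
  }
})

test_that("zero-jitter schedules realise the technique templates", {
  g3 <- schedule_events(noiseless_spec("G3", n_cycles = 8, seed = 2))
  ph3 <- cycle_phases(ground_truth_events(g3))
  expect_true(all(ph3$n_pole_plants == 2L))
  expect_true(all(ph3$delay_Pon_Son <= 0.035))

  g2 <- schedule_events(noiseless_spec("G2", n_cycles = 8, seed = 2))
  ph2 <- cycle_phases(ground_truth_events(g2))
  T <- 1 / 0.9
  expect_true(all(ph2$n_pole_plants == 1L))
  expect_true(all(ph2$delay_Pon_Son >= 0.15 * T - 1e-9))
  expect_true(all(ph2$delay_Pon_Son <= 0.25 * T + 1e-9))

  g4 <- schedule_events(noiseless_spec("G4", n_cycles = 8, seed = 2))
  ph4 <- cycle_phases(ground_truth_events(g4))
  expect_true(all(ph4$n_pole_plants == 1L))
  expect_true(all(ph4$delay_Pon_Son <= 0.035))
})

test_that("infeasible jitter raises the generator error", {
  expect_error(
    schedule_events(trial_spec("G3", n_cycles = 10, jitter_sd_s = 0.4, seed = 1)),
    class = "skatephase_error_generator_infeasible"
  )
})

test_that("marker tracks stay near the ground plane with flat contact plateaus", {
  tr <- clean_trial("G3")
  for (track in tr$markers) expect_gte(min(track$z), -1e-9)

  noisy <- noisy_trial("G3")
  for (track in noisy$markers) expect_gte(min(track$z), -0.006)

  # plateau samples sit within 5 mm of the ground
  gt <- gt_events_of(tr)
  track <- tr$markers$ski_left
  on <- sort(gt$time[gt$etype == "S_ON" & gt$side == "left"])
  off <- sort(gt$time[gt$etype == "S_OFF" & gt$side == "left"])
  plateau <- unlist(purrr::map2(on, off, function(a, b) {
    which(track$time > a + 0.02 & track$time < b - 0.02)
  }))
  expect_lt(mean(abs(track$z[plateau])), 0.005)
})

test_that("doubling the gyro bias leaves the drift-removed anchors in place", {
  s1 <- noiseless_spec("G3", n_cycles = 8, seed = 5, gyro_bias = 0.5)
  s2 <- noiseless_spec("G3", n_cycles = 8, seed = 5, gyro_bias = 1.0)
  a1 <- segment_wrist_cycles(simulate_trial(s1)$imu$wrist_left)$anchor
  a2 <- segment_wrist_cycles(simulate_trial(s2)$imu$wrist_left)$anchor
  expect_identical(length(a1), length(a2))
  expect_lt(max(abs(a1 - a2)), 1 / 256 + 1e-9)
})

test_that("the IMU pipeline stays above 99% recovery at default noise", {
  tr <- noisy_trial("G3", seed = 41)
  gt <- gt_events_of(tr)
  ev <- detect_imu_events(tr)
  n_gt <- 0L; n_match <- 0L
  for (et in c("P_ON", "P_OFF", "S_ON", "S_OFF")) {
    for (sd_ in c("left", "right")) {
      m <- recovery_errors(gt, ev, et, sd_)
      n_gt <- n_gt + nrow(gt[gt$etype == et & gt$side == sd_, ])
      n_match <- n_match + nrow(m$pairs)
    }
  }
  expect_gte(100 * n_match / n_gt, 99)
})

test_that("batch specifications derive distinct per-trial seeds deterministically", {
  a <- batch_specs(2, 10, seed = 42)
  b <- batch_specs(2, 10, seed = 42)
  expect_identical(
    vapply(a, function(s) s$seed, integer(1)),
    vapply(b, function(s) s$seed, integer(1))
  )
  expect_identical(vapply(a, function(s) s$subtech, character(1)),
                   rep(c("G2", "G3", "G4"), each = 2))
  expect_identical(anyDuplicated(vapply(a, function(s) s$seed, integer(1))), 0L)
})
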