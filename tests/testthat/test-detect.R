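make_rec <- function(location, yaw_gyro = NULL, roll_gyro = NULL, yaw_acc = NULL,
                     fs = 256, n = NULL, t0 = 0) {
  n <- n %||% max(lengths(list(yaw_gyro, roll_gyro, yaw_acc)))
  z0 <- rep(0, n)
  acc <- data.frame(x = z0, y = z0, z = yaw_acc %||% z0)
  gyr <- data.frame(x = roll_gyro %||% z0, y = z0, z = yaw_gyro %||% z0)
  imu_recording(acc, gyr, fs = fs, location = location, t0 = t0)
}

test_that("wrist segmentation finds one anchor per arm cycle of a pure oscillation", {
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  rec <- make_rec("wrist_left", yaw_gyro = 360 * sin(2 * pi * 0.8 * t), fs = fs)
  seg <- segment_wrist_cycles(rec)
  expect_gte(nrow(seg), 7L)
  expect_lte(nrow(seg), 9L)
  expect_equal(mean(diff(seg$anchor)), 1.25, tolerance = 0.02 / 1.25)

  expect_error(segment_wrist_cycles(make_rec("wrist_left", yaw_gyro = rep(0, fs * 5))),
    class = "skatephase_error_insufficient_cycles"
  )
})

test_that("wrist anchors are invariant to a constant gyro bias", {
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  base <- 360 * sin(2 * pi * 0.8 * t)
  a0 <- segment_wrist_cycles(make_rec("wrist_left", yaw_gyro = base, fs = fs))$anchor
  a1 <- segment_wrist_cycles(make_rec("wrist_left", yaw_gyro = base + 0.5, fs = fs))$anchor
  expect_identical(length(a0), length(a1))
  expect_lt(max(abs(a0 - a1)), 1 / fs + 1e-9)
})

test_that("ski segmentation anchors positive-going roll-rate zero crossings", {
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  rec <- make_rec("ski_left", roll_gyro = 90 * sin(2 * pi * 0.7 * t), fs = fs)
  seg <- segment_ski_cycles(rec)
  expect_gte(nrow(seg), 6L)
  expect_lte(nrow(seg), 8L)

  set.seed(2)
  noisy <- make_rec("ski_left",
    roll_gyro = 90 * sin(2 * pi * 0.7 * t) + rnorm(length(t), 0, 10), fs = fs
  )
  expect_identical(nrow(segment_ski_cycles(noisy)), nrow(seg))

  expect_error(segment_ski_cycles(make_rec("ski_left", roll_gyro = rep(0, fs * 5))),
    class = "skatephase_error_insufficient_cycles"
  )
})

test_that("noiseless pole events are recovered at the rendered transients", {
  tr <- clean_trial("G3")
  gt <- gt_events_of(tr)
  fs <- tr$spec$fs_imu
  for (sd_ in c("left", "right")) {
    rec <- tr$imu[[paste0("wrist_", sd_)]]
    seg <- segment_wrist_cycles(rec)
    on <- detect_pole_on(rec, seg)
    m <- recovery_errors(gt, on, "P_ON", sd_)
    expect_identical(length(m$missed_ref), 0L)
    expect_lt(max(abs(m$pairs$error_s)), 1.5 / fs)
    off <- detect_pole_off(rec, seg)
    m <- recovery_errors(gt, off, "P_OFF", sd_)
    expect_identical(length(m$missed_ref), 0L)
    expect_lt(max(abs(m$pairs$error_s)), 2.5 / fs)
  }
})

test_that("cycles without a qualifying acceleration peak are counted as misses", {
  tr <- clean_trial("G3")
  rec <- tr$imu$wrist_left
  seg <- segment_wrist_cycles(rec)
  flat <- make_rec("wrist_left",
    yaw_gyro = rec$gyr_z, yaw_acc = rep(0, nrow(rec)),
    fs = tr$spec$fs_imu, t0 = rec$time[1]
  )
  res <- detect_pole_on(flat, seg)
  expect_identical(nrow(res), 0L)
  expect_identical(attr(res, "n_missed"), attr(res, "n_cycles"))
  expect_gt(attr(res, "n_cycles"), 0L)
})

test_that("pole event times are invariant to doubling the acceleration amplitude", {
  tr <- clean_trial("G3")
  rec <- tr$imu$wrist_left
  seg <- segment_wrist_cycles(rec)
  doubled <- make_rec("wrist_left",
    yaw_gyro = rec$gyr_z, yaw_acc = 2 * rec$acc_z,
    fs = tr$spec$fs_imu, t0 = rec$time[1]
  )
  expect_equal(detect_pole_on(doubled, seg)$time, detect_pole_on(rec, seg)$time)
  expect_equal(detect_pole_off(doubled, seg)$time, detect_pole_off(rec, seg)$time)
})

test_that("a trace with no content above 5 Hz yields only pole-release misses", {
  tr <- clean_trial("G3")
  rec <- tr$imu$wrist_left
  seg <- segment_wrist_cycles(rec)
  t <- rec$time
  smooth <- make_rec("wrist_left",
    yaw_gyro = rec$gyr_z, yaw_acc = 3 * sin(2 * pi * 1 * t),
    fs = tr$spec$fs_imu, t0 = t[1]
  )
  res <- detect_pole_off(smooth, seg)
  expect_identical(nrow(res), 0L)
  expect_identical(attr(res, "n_missed"), attr(res, "n_cycles"))
})

test_that("widening the release search window does not move unique transients", {
  # G4: one plant per cycle, so no neighbouring-cycle transient falls within
  # the widened window (the example's uniqueness precondition)
  tr <- clean_trial("G4")
  rec <- tr$imu$wrist_left
  seg <- segment_wrist_cycles(rec)
  narrow <- detect_pole_off(rec, seg, detection_config(near_window_s = 0.15))
  wide <- detect_pole_off(rec, seg, detection_config(near_window_s = 0.30))
  expect_equal(narrow$time, wide$time)
})

test_that("noiseless ski events are recovered at the rendered spikes, in order", {
  tr <- clean_trial("G3")
  gt <- gt_events_of(tr)
  fs <- tr$spec$fs_imu
  for (sd_ in c("left", "right")) {
    rec <- tr$imu[[paste0("ski_", sd_)]]
    seg <- segment_ski_cycles(rec)
    on <- detect_ski_on(rec, seg)
    m <- recovery_errors(gt, on, "S_ON", sd_)
    expect_identical(length(m$missed_ref), 0L)
    expect_lt(max(abs(m$pairs$error_s)), 2.5 / fs)
    off <- detect_ski_off(rec, seg)
    m2 <- recovery_errors(gt, off, "S_OFF", sd_)
    expect_identical(length(m2$missed_ref), 0L)
    expect_lt(max(abs(m2$pairs$error_s)), 2.5 / fs)
    # each cycle's release follows its plant
    both <- dplyr::arrange(dplyr::bind_rows(tibble::as_tibble(on), tibble::as_tibble(off)), time)
    expect_true(all(both$etype[c(TRUE, FALSE)] == "S_ON"))
  }
})

test_that("two-wheel landings snap to the larger spike within the wheel gap", {
  spec <- noiseless_spec("G3", n_cycles = 10, seed = 9, p_two_wheel = 1)
  tr <- simulate_trial(spec)
  gt <- gt_events_of(tr)
  rec <- tr$imu$ski_left
  seg <- segment_ski_cycles(rec)
  on <- detect_ski_on(rec, seg)
  m <- recovery_errors(gt, on, "S_ON", "left")
  expect_identical(length(m$missed_ref), 0L)
  # detections land on wheel one (error ~0) or wheel two (error in [-gap, 0])
  expect_true(all(m$pairs$error_s > -(spec$two_wheel_gap_s + 0.01)))
  expect_true(all(m$pairs$error_s < 0.01))
})

test_that("flat vertical acceleration yields ski misses, never fabricated events", {
  tr <- clean_trial("G3")
  rec <- tr$imu$ski_left
  seg <- segment_ski_cycles(rec)
  flat <- make_rec("ski_left",
    roll_gyro = rec$gyr_x, yaw_acc = rep(0, nrow(rec)),
    fs = tr$spec$fs_imu, t0 = rec$time[1]
  )
  for (f in list(detect_ski_on, detect_ski_off)) {
    res <- f(flat, seg)
    expect_identical(nrow(res), 0L)
    expect_identical(attr(res, "n_missed"), attr(res, "n_cycles"))
  }
})

test_that("the assembled pipeline recovers nearly all events and alternates", {
  tr <- clean_trial("G2")
  gt <- gt_events_of(tr)
  ev <- detect_imu_events(tr)
  n_gt <- 0L; n_match <- 0L
  for (et in c("P_ON", "P_OFF", "S_ON", "S_OFF")) {
    for (sd_ in c("left", "right")) {
      m <- recovery_errors(gt, ev, et, sd_)
      n_gt <- n_gt + nrow(gt[gt$etype == et & gt$side == sd_, ])
      n_match <- n_match + sum(abs(m$pairs$error_s) <= 2 / tr$spec$fs_imu + 1e-9)
    }
  }
  expect_gte(100 * n_match / n_gt, 99.9)
  # events inside the ground-truth span alternate strictly per limb
  span <- range(gt$time)
  inside <- ev[ev$time >= span[1] & ev$time <= span[2], ]
  expect_identical(nrow(check_event_series(inside)), 0L)
})

test_that("detection is equivariant under a uniform time shift", {
  tr <- clean_trial("G3")
  base <- detect_imu_events(tr)
  delta <- 3.7
  shifted_imu <- lapply(tr$imu, function(rec) {
    imu_recording(
      acc = rec[, c("acc_x", "acc_y", "acc_z")],
      gyro = rec[, c("gyr_x", "gyr_y", "gyr_z")],
      fs = attr(rec, "fs"), location = attr(rec, "location"),
      axis_map = attr(rec, "axis_map"), t0 = rec$time[1] + delta
    )
  })
  moved <- detect_imu_events(shifted_imu)
  expect_identical(nrow(moved), nrow(base))
  expect_lt(max(abs(moved$time - (base$time + delta))), 1 / tr$spec$fs_imu + 1e-9)
})

test_that("per-segment accounting conserves detections plus misses", {
  tr <- noisy_trial("G4")
  ev <- detect_imu_events(tr)
  misses <- attr(ev, "misses")
  counts <- dplyr::count(tibble::as_tibble(ev), etype, side)
  joined <- dplyr::left_join(misses, counts, by = c("etype", "side"))
  joined$n[is.na(joined$n)] <- 0L
  expect_true(all(joined$n + joined$n_missed == joined$n_cycles))
})

test_that("a known inter-system clock offset is removed on request", {
  spec <- noiseless_spec("G3", n_cycles = 6, seed = 21, imu_offset_s = 0.25)
  tr <- simulate_trial(spec)
  gt <- gt_events_of(tr)
  ev <- detect_imu_events(tr) # offset taken from the trial spec
  m <- recovery_errors(gt, ev, "P_OFF", "left")
  expect_lt(max(abs(m$pairs$error_s)), 2.5 / tr$spec$fs_imu)
})
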