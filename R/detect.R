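#' Detection configuration for the IMU pipeline
#'
#' Houses the filter cutoffs, peak-prominence gate and search windows used by
#' the wrist and ski detectors. Defaults follow the published pipeline: a
#' 2nd-order 0.1 Hz high-pass removes integration drift from gyro angles, a
#' 2nd-order 5 Hz high-pass isolates the pole-release transient, a 2nd-order
#' 2 Hz low-pass extracts the leg-cycle rhythm from the ski roll rate, and
#' acceleration peaks must exceed a prominence of 1 m/s^2. Search windows
#' ("close to" an angle extremum) are not stated numerically in the source
#' method and default to 0.15 s.
#'
#' @param hp_drift_hz Drift-removal high-pass cutoff (Hz, default 0.1).
#' @param hp_poleoff_hz Pole-release high-pass cutoff (Hz, default 5).
#' @param lp_ski_hz Ski-rhythm low-pass cutoff (Hz, default 2).
#' @param min_prominence_acc Acceleration peak-prominence gate (m/s^2, default 1).
#' @param min_prominence_angle_deg Yaw-angle peak-prominence gate used for
#'   wrist cycle anchors (deg, default 5).
#' @param near_window_s Half-width of "close to" search windows (s, default 0.15).
#' @param filter_order Order of every Butterworth filter (default 2).
#' @param cycle_band_s Plausible anchor-spacing band in seconds
#'   (default `c(0.4, 4)`).
#' @param ski_off_fraction Final portion of a ski cycle searched for the roll
#'   minimum (default 0.4).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(hp_drift_hz = 0.1, hp_poleoff_hz = 5, lp_ski_hz = 2,
                             min_prominence_acc = 1, min_prominence_angle_deg = 5,
                             near_window_s = 0.15, filter_order = 2L,
                             cycle_band_s = c(0.4, 4), ski_off_fraction = 0.4) {
  if (near_window_s <= 0) abort_invalid("`near_window_s` must be > 0")
  if (any(c(hp_drift_hz, hp_poleoff_hz, lp_ski_hz) <= 0)) {
    abort_invalid("filter cutoffs must be > 0")
  }
  if (length(cycle_band_s) != 2L || cycle_band_s[1] <= 0 || diff(cycle_band_s) <= 0) {
    abort_invalid("`cycle_band_s` must be an increasing positive pair")
  }
  structure(list(
    hp_drift_hz = hp_drift_hz, hp_poleoff_hz = hp_poleoff_hz, lp_ski_hz = lp_ski_hz,
    min_prominence_acc = min_prominence_acc,
    min_prominence_angle_deg = min_prominence_angle_deg,
    near_window_s = near_window_s, filter_order = as.integer(filter_order),
    cycle_band_s = cycle_band_s, ski_off_fraction = ski_off_fraction
  ), class = "detection_config")
}

check_cfg_nyquist <- function(cfg, fs) {
  cuts <- c(cfg$hp_drift_hz, cfg$hp_poleoff_hz, cfg$lp_ski_hz)
  if (any(cuts >= fs / 2)) {
    abort_invalid("detection-config cutoffs must be below the recording Nyquist frequency")
  }
}

new_segmentation <- function(anchors, source_limb) {
  structure(
    tibble::tibble(anchor = anchors),
    source_limb = source_limb,
    class = c("cycle_segmentation", "tbl_df", "tbl", "data.frame")
  )
}

# enforce plausible anchor spacing by dropping the lesser-prominence anchor
# of a violating pair
enforce_spacing <- function(times, prominences, band) {
  repeat {
    if (length(times) < 2L) break
    gaps <- diff(times)
    bad <- which(gaps < band[1])
    if (!length(bad)) break
    i <- bad[1]
    drop <- if (prominences[i] <= prominences[i + 1L]) i else i + 1L
    times <- times[-drop]
    prominences <- prominences[-drop]
  }
  list(times = times, prominences = prominences)
}

abort_insufficient_cycles <- function(n_found) {
  rlang::abort(
    sprintf("fewer than 2 cycle anchors found (%d)", n_found),
    class = "skatephase_error_insufficient_cycles",
    n_anchors = n_found
  )
}

#' Segment wrist cycles from the yaw angle
#'
#' Integrates the wrist yaw angular velocity, removes drift with the
#' 0.1 Hz high-pass, and anchors one poling cycle at each positive local
#' maximum of the resulting yaw angle (prominence >=
#' `min_prominence_angle_deg`). Anchor pairs closer than the lower edge of
#' `cycle_band_s` are thinned by dropping the lesser-prominence anchor.
#'
#' @param rec A wrist [imu_recording()].
#' @param cfg A [detection_config()].
#' @return A `cycle_segmentation` tibble with column `anchor` (times in
#'   seconds, strictly increasing).
#' @export
segment_wrist_cycles <- function(rec, cfg = detection_config()) {
  loc <- attr(rec, "location")
  if (!grepl("^wrist", loc)) abort_invalid("`rec` must be a wrist recording")
  check_cfg_nyquist(cfg, attr(rec, "fs"))
  ang <- wrist_yaw_angle(rec, cfg)
  pk <- find_peaks(ang, min_prominence = cfg$min_prominence_angle_deg, sign = "positive")
  kept <- enforce_spacing(pk$time, pk$prominence, cfg$cycle_band_s)
  if (length(kept$times) < 2L) abort_insufficient_cycles(length(kept$times))
  new_segmentation(kept$times, loc)
}

wrist_yaw_angle <- function(rec, cfg) {
  butter_filter(integrate_signal(imu_channel(rec, "gyro", "yaw")),
    cfg$hp_drift_hz, order = cfg$filter_order, mode = "highpass"
  )
}

ski_roll_angle <- function(rec, cfg) {
  butter_filter(integrate_signal(imu_channel(rec, "gyro", "roll")),
    cfg$hp_drift_hz, order = cfg$filter_order, mode = "highpass"
  )
}

#' Segment ski cycles from the low-passed roll rate
#'
#' Low-passes the ski roll angular velocity at `lp_ski_hz` to isolate the
#' leg-cycle rhythm and anchors one cycle at each positive-going zero
#' crossing. A crossing counts only when flanked by sustained (>= 50 ms)
#' lobes beyond a hysteresis band of 10% of the signal's 95th-percentile
#' magnitude, so residual noise and filter edge transients cannot mint
#' anchors. Anchor spacing is thinned to the plausible cycle band as for the
#' wrist.
#'
#' @param rec A ski [imu_recording()].
#' @param cfg A [detection_config()].
#' @return A `cycle_segmentation` tibble with column `anchor`.
#' @export
segment_ski_cycles <- function(rec, cfg = detection_config()) {
  loc <- attr(rec, "location")
  if (!grepl("^ski", loc)) abort_invalid("`rec` must be a ski recording")
  check_cfg_nyquist(cfg, attr(rec, "fs"))
  lp <- butter_filter(imu_channel(rec, "gyro", "roll"), cfg$lp_ski_hz,
    order = cfg$filter_order, mode = "lowpass"
  )
  v <- lp$value
  # positive-going zero crossings with hysteresis: the rate must swing below
  # -h before the crossing counts, so residual noise near zero cannot add
  # spurious anchors at the trial edges
  h <- 0.1 * stats::quantile(abs(v), 0.95, names = FALSE)
  nz <- which(abs(v) > h)
  if (length(nz) < 2L) abort_insufficient_cycles(0L)
  sgn <- sign(v[nz])
  runs <- rle(sgn)
  run_end <- cumsum(runs$lengths)
  min_run <- max(3L, round(0.05 * attr(rec, "fs")))
  cross <- which(runs$values[-length(runs$values)] < 0 & runs$values[-1] > 0)
  cross <- cross[runs$lengths[cross] >= min_run & runs$lengths[cross + 1L] >= min_run]
  up <- vapply(cross, function(k) {
    lo <- nz[run_end[k]]
    hi <- nz[run_end[k] + 1L]
    lo + which(v[lo:hi] >= 0)[1] - 1L
  }, integer(1))
  if (length(up) < 2L) abort_insufficient_cycles(length(up))
  times <- lp$time[up]
  # amplitude of the filtered oscillation around each crossing as "prominence"
  amp <- vapply(up, function(i) {
    win <- max(1L, i - 50L):min(length(v), i + 50L)
    max(v[win]) - min(v[win])
  }, numeric(1))
  kept <- enforce_spacing(times, amp, cfg$cycle_band_s)
  if (length(kept$times) < 2L) abort_insufficient_cycles(length(kept$times))
  new_segmentation(kept$times, loc)
}

segment_windows <- function(seg) {
  a <- seg$anchor
  tibble::tibble(t0 = a[-length(a)], t1 = a[-1])
}

make_detect_result <- function(rows, segments, side, trial_id) {
  ev <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(etype = character(0), side = character(0),
                   time = numeric(0), source = character(0), cycle = integer(0))
  }
  out <- event_series(ev, trial_id = trial_id, validate = FALSE)
  attr(out, "segments") <- segments
  attr(out, "n_cycles") <- nrow(segments)
  attr(out, "n_missed") <- sum(is.na(segments$time))
  out
}

window_signal <- function(sig, t0, t1) {
  idx <- which(sig$time >= t0 & sig$time <= t1)
  if (length(idx) < 3L) return(NULL)
  list(idx = idx, values = sig$value[idx], times = sig$time[idx])
}

sub_signal <- function(sig, idx) {
  uniform_signal(sig$value[idx], fs = signal_fs(sig), t0 = sig$time[idx[1]])
}

#' Detect pole initial contacts (P_ON) from a wrist IMU
#'
#' Per poling cycle (anchor to anchor): starting at the yaw-angle maximum,
#' scans forward for the first positive-valued yaw-acceleration peak with
#' prominence at least `min_prominence_acc`; P_ON is the last negative-valued
#' acceleration peak strictly before that positive peak, searching back no
#' further than the anchor. A cycle missing either peak yields no event and
#' counts as a miss.
#'
#' @param rec A wrist [imu_recording()].
#' @param seg The [segment_wrist_cycles()] result for the same recording.
#' @param cfg A [detection_config()].
#' @param trial_id Identifier stored on the output series.
#' @return An [event_series()] (`source = "imu"`) with per-cycle attribution;
#'   attributes `segments` (per-cycle outcomes), `n_cycles`, `n_missed`.
#' @export
detect_pole_on <- function(rec, seg, cfg = detection_config(), trial_id = "") {
  side <- sub("^wrist_", "", attr(rec, "location"))
  acc <- imu_channel(rec, "acc", "yaw")
  wins <- segment_windows(seg)
  wins$time <- NA_real_
  rows <- list()
  for (k in seq_len(nrow(wins))) {
    w <- window_signal(acc, wins$t0[k], wins$t1[k])
    if (is.null(w)) next
    sub <- sub_signal(acc, w$idx)
    pos <- find_peaks(sub, min_prominence = cfg$min_prominence_acc, sign = "positive")
    pos <- pos[pos$value > 0, ]
    if (!nrow(pos)) next
    ipos <- pos$index[1]
    neg <- find_peaks(sub, min_prominence = 0, sign = "negative")
    neg <- neg[neg$index < ipos & neg$value < 0, ]
    if (!nrow(neg)) next
    t_ev <- w$times[neg$index[nrow(neg)]]
    wins$time[k] <- t_ev
    rows[[length(rows) + 1L]] <- tibble::tibble(
      etype = "P_ON", side = side, time = t_ev, source = "imu", cycle = k
    )
  }
  make_detect_result(rows, wins, side, trial_id)
}

#' Detect pole final contacts (P_OFF) from a wrist IMU
#'
#' Per poling cycle: locates the yaw-angle minimum, then takes P_OFF as the
#' most negative peak of the 5 Hz high-passed yaw acceleration within
#' `near_window_s` of that minimum (peaks gated at `min_prominence_acc`, so a
#' trace with no high-frequency content yields misses, not noise events).
#'
#' @inheritParams detect_pole_on
#' @return An [event_series()] as for [detect_pole_on()].
#' @export
detect_pole_off <- function(rec, seg, cfg = detection_config(), trial_id = "") {
  side <- sub("^wrist_", "", attr(rec, "location"))
  ang <- wrist_yaw_angle(rec, cfg)
  acc_hp <- butter_filter(imu_channel(rec, "acc", "yaw"), cfg$hp_poleoff_hz,
    order = cfg$filter_order, mode = "highpass"
  )
  wins <- segment_windows(seg)
  wins$time <- NA_real_
  rows <- list()
  for (k in seq_len(nrow(wins))) {
    wa <- window_signal(ang, wins$t0[k], wins$t1[k])
    if (is.null(wa)) next
    t_min <- wa$times[which.min(wa$values)]
    wn <- window_signal(acc_hp, t_min - cfg$near_window_s, t_min + cfg$near_window_s)
    if (is.null(wn)) next
    sub <- sub_signal(acc_hp, wn$idx)
    neg <- find_peaks(sub, min_prominence = cfg$min_prominence_acc, sign = "negative")
    neg <- neg[neg$value < 0, ]
    if (!nrow(neg)) next
    t_ev <- wn$times[neg$index[which.min(neg$value)]]
    wins$time[k] <- t_ev
    rows[[length(rows) + 1L]] <- tibble::tibble(
      etype = "P_OFF", side = side, time = t_ev, source = "imu", cycle = k
    )
  }
  make_detect_result(rows, wins, side, trial_id)
}

#' Detect ski initial contacts (S_ON) from a ski IMU
#'
#' Per leg cycle: a coarse landing time is the maximum of the drift-removed
#' integrated roll angle within the cycle; the precise S_ON is the maximal
#' raw vertical-axis (yaw) acceleration peak within `near_window_s` of the
#' coarse time. When a roller-ski landing splits into two wheel impacts the
#' detector snaps to the larger spike.
#'
#' @param rec A ski [imu_recording()].
#' @param seg The [segment_ski_cycles()] result for the same recording.
#' @inheritParams detect_pole_on
#' @return An [event_series()] as for [detect_pole_on()].
#' @export
detect_ski_on <- function(rec, seg, cfg = detection_config(), trial_id = "") {
  side <- sub("^ski_", "", attr(rec, "location"))
  ang <- ski_roll_angle(rec, cfg)
  acc <- imu_channel(rec, "acc", "yaw")
  wins <- segment_windows(seg)
  wins$time <- NA_real_
  rows <- list()
  for (k in seq_len(nrow(wins))) {
    wa <- window_signal(ang, wins$t0[k], wins$t1[k])
    if (is.null(wa)) next
    t_coarse <- wa$times[which.max(wa$values)]
    wn <- window_signal(acc, t_coarse - cfg$near_window_s, t_coarse + cfg$near_window_s)
    if (is.null(wn)) next
    sub <- sub_signal(acc, wn$idx)
    pos <- find_peaks(sub, min_prominence = cfg$min_prominence_acc, sign = "positive")
    pos <- pos[pos$value > 0, ]
    if (!nrow(pos)) next
    t_ev <- wn$times[pos$index[which.max(pos$value)]]
    wins$time[k] <- t_ev
    rows[[length(rows) + 1L]] <- tibble::tibble(
      etype = "S_ON", side = side, time = t_ev, source = "imu", cycle = k
    )
  }
  make_detect_result(rows, wins, side, trial_id)
}

#' Detect ski final contacts (S_OFF) from a ski IMU
#'
#' Per leg cycle: locates the minimum of the drift-removed roll angle in the
#' final portion (`ski_off_fraction`) of the cycle, then takes S_OFF as the
#' most negative raw vertical-axis acceleration peak within `near_window_s`
#' of it.
#'
#' @inheritParams detect_ski_on
#' @return An [event_series()] as for [detect_pole_on()].
#' @export
detect_ski_off <- function(rec, seg, cfg = detection_config(), trial_id = "") {
  side <- sub("^ski_", "", attr(rec, "location"))
  ang <- ski_roll_angle(rec, cfg)
  acc <- imu_channel(rec, "acc", "yaw")
  wins <- segment_windows(seg)
  wins$time <- NA_real_
  rows <- list()
  for (k in seq_len(nrow(wins))) {
    t_tail <- wins$t1[k] - cfg$ski_off_fraction * (wins$t1[k] - wins$t0[k])
    wa <- window_signal(ang, t_tail, wins$t1[k])
    if (is.null(wa)) next
    t_min <- wa$times[which.min(wa$values)]
    wn <- window_signal(acc, t_min - cfg$near_window_s, t_min + cfg$near_window_s)
    if (is.null(wn)) next
    sub <- sub_signal(acc, wn$idx)
    neg <- find_peaks(sub, min_prominence = cfg$min_prominence_acc, sign = "negative")
    neg <- neg[neg$value < 0, ]
    if (!nrow(neg)) next
    t_ev <- wn$times[neg$index[which.min(neg$value)]]
    wins$time[k] <- t_ev
    rows[[length(rows) + 1L]] <- tibble::tibble(
      etype = "S_OFF", side = side, time = t_ev, source = "imu", cycle = k
    )
  }
  make_detect_result(rows, wins, side, trial_id)
}

#' Run the full IMU detection pipeline on a trial
#'
#' Segments each wrist and ski recording into cycles and runs the four event
#' detectors, returning one combined event series. When the recordings carry
#' a known clock offset relative to the reference system, subtract it via
#' `clock_offset_s` so all times share the trial clock.
#'
#' @param imu Named list of four [imu_recording()]s (`wrist_left`,
#'   `wrist_right`, `ski_left`, `ski_right`), or a `ski_trial`.
#' @param cfg A [detection_config()].
#' @param clock_offset_s Known IMU-minus-reference clock offset to remove (s).
#' @param trial_id Identifier stored on the output series.
#' @return An [event_series()] (`source = "imu"`); attribute `misses` holds a
#'   tibble of per-(etype, side) processed-cycle and miss counts.
#' @export
detect_imu_events <- function(imu, cfg = detection_config(), clock_offset_s = 0,
                              trial_id = "") {
  if (inherits(imu, "ski_trial")) {
    if (missing(clock_offset_s)) clock_offset_s <- imu$spec$imu_offset_s
    imu <- imu$imu
  }
  parts <- list()
  misses <- list()
  take <- function(res, etype, side) {
    parts[[length(parts) + 1L]] <<- res
    misses[[length(misses) + 1L]] <<- tibble::tibble(
      etype = etype, side = side,
      n_cycles = attr(res, "n_cycles"), n_missed = attr(res, "n_missed")
    )
  }
  for (side in c("left", "right")) {
    wr <- imu[[paste0("wrist_", side)]]
    seg <- segment_wrist_cycles(wr, cfg)
    take(detect_pole_on(wr, seg, cfg, trial_id), "P_ON", side)
    take(detect_pole_off(wr, seg, cfg, trial_id), "P_OFF", side)
    sk <- imu[[paste0("ski_", side)]]
    seg <- segment_ski_cycles(sk, cfg)
    take(detect_ski_on(sk, seg, cfg, trial_id), "S_ON", side)
    take(detect_ski_off(sk, seg, cfg, trial_id), "S_OFF", side)
  }
  ev <- dplyr::bind_rows(lapply(parts, function(p) {
    tibble::as_tibble(p)[, c("etype", "side", "time", "source", "cycle")]
  }))
  ev$time <- ev$time - clock_offset_s
  out <- event_series(dplyr::arrange(ev, .data$time), trial_id = trial_id, validate = FALSE)
  attr(out, "misses") <- dplyr::bind_rows(misses)
  attr(out, "detector_segments") <- purrr::map(parts, attr, "segments")
  out
}
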