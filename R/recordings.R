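#' Construct an IMU recording
#'
#' Bundles the six channels of one inertial unit (3-axis accelerometer in
#' m/s^2, 3-axis gyroscope in deg/s) sampled on a common uniform time grid,
#' bound to a body/equipment location and an axis convention mapping the
#' semantic axes (yaw, roll, pitch) onto the physical channels (x, y, z).
#'
#' @param acc,gyro Numeric matrices or data frames with columns x, y, z.
#' @param fs Sampling rate in Hz (nominally 256).
#' @param location One of `"wrist_left"`, `"wrist_right"`, `"ski_left"`, `"ski_right"`.
#' @param axis_map Named list/character vector mapping `yaw`, `roll`, `pitch`
#'   to `"x"`, `"y"`, `"z"` (a bijection). Default: yaw = z, roll = x, pitch = y.
#' @param t0 Time of the first sample (s).
#'
#' @return A tibble of class `imu_recording` with columns `time`, `acc_x`,
#'   `acc_y`, `acc_z`, `gyr_x`, `gyr_y`, `gyr_z`.
#' @export
imu_recording <- function(acc, gyro, fs, location, axis_map = default_axis_map(), t0 = 0) {
  location <- rlang::arg_match(location, imu_locations())
  acc <- as.data.frame(acc)
  gyro <- as.data.frame(gyro)
  if (ncol(acc) != 3L || ncol(gyro) != 3L || nrow(acc) != nrow(gyro)) {
    abort_invalid("`acc` and `gyro` must both have 3 columns and equal length")
  }
  am <- unlist(axis_map)[c("yaw", "roll", "pitch")]
  if (anyNA(am) || !setequal(am, c("x", "y", "z"))) {
    abort_invalid("`axis_map` must map yaw/roll/pitch bijectively onto x/y/z")
  }
  vals <- cbind(acc, gyro)
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1)))) {
    abort_invalid("IMU channels must be finite")
  }
  out <- tibble::tibble(
    time = t0 + (seq_len(nrow(acc)) - 1) / fs,
    acc_x = acc[[1]], acc_y = acc[[2]], acc_z = acc[[3]],
    gyr_x = gyro[[1]], gyr_y = gyro[[2]], gyr_z = gyro[[3]]
  )
  structure(out,
    fs = as.numeric(fs), t0 = as.numeric(t0), location = location,
    axis_map = as.list(am),
    class = c("imu_recording", class(out))
  )
}

imu_locations <- function() c("wrist_left", "wrist_right", "ski_left", "ski_right")
marker_locations <- function() c("pole_tip_left", "pole_tip_right", "ski_left", "ski_right")

#' @rdname imu_recording
#' @export
default_axis_map <- function() list(yaw = "z", roll = "x", pitch = "y")

#' Extract one semantic channel from an IMU recording
#'
#' @param rec An [imu_recording()].
#' @param sensor `"acc"` or `"gyro"`.
#' @param axis Semantic axis: `"yaw"`, `"roll"` or `"pitch"`.
#' @return A [uniform_signal()].
#' @export
imu_channel <- function(rec, sensor = c("acc", "gyro"), axis = c("yaw", "roll", "pitch")) {
  sensor <- rlang::arg_match(sensor)
  axis <- rlang::arg_match(axis)
  phys <- attr(rec, "axis_map")[[axis]]
  col <- paste0(if (sensor == "acc") "acc_" else "gyr_", phys)
  uniform_signal(rec[[col]],
    fs = attr(rec, "fs"), t0 = rec$time[1],
    label = paste(attr(rec, "location"), sensor, axis, sep = "_"),
    units = if (sensor == "acc") "m/s^2" else "deg/s"
  )
}

#' Construct a marker track (vertical position)
#'
#' Holds the vertical trajectory of one reflective marker (pole tip or ski),
#' as observed by the optical reference system (nominally 200 Hz).
#'
#' @param z Numeric vector of vertical positions in metres (finite).
#' @param fs Sampling rate in Hz.
#' @param location One of `"pole_tip_left"`, `"pole_tip_right"`, `"ski_left"`,
#'   `"ski_right"`.
#' @param t0 Time of the first sample (s).
#' @return A tibble of class `marker_track` with columns `time` and `z`.
#' @export
marker_track <- function(z, fs, location, t0 = 0) {
  location <- rlang::arg_match(location, marker_locations())
  s <- uniform_signal(z, fs = fs, t0 = t0, label = location, units = "m")
  out <- tibble::tibble(time = s$time, z = s$value)
  structure(out,
    fs = as.numeric(fs), t0 = as.numeric(t0), location = location,
    class = c("marker_track", class(out))
  )
}

marker_signal <- function(track) {
  uniform_signal(track$z,
    fs = attr(track, "fs"), t0 = track$time[1],
    label = attr(track, "location"), units = "m"
  )
}

event_types <- function() c("P_ON", "P_OFF", "S_ON", "S_OFF")
event_sides <- function() c("left", "right", "merged")
event_sources <- function() c("reference", "imu", "ground_truth")

#' Construct a validated event series
#'
#' An event series is a time-ordered tibble of typed, sided contact events
#' (`P_ON`/`P_OFF` for poles, `S_ON`/`S_OFF` for skis). Validation enforces,
#' per (event family, side): strict ON/OFF alternation (starting with either),
#' and a refractory bound of `refractory_s` between consecutive events of
#' identical (etype, side).
#'
#' @param events Data frame with columns `etype`, `side`, `time`, `source`
#'   (and optionally `cycle`).
#' @param trial_id Trial identifier carried as an attribute.
#' @param validate If `TRUE` (default) violations abort; detector output with
#'   missed events may legitimately break alternation and is built with
#'   `validate = FALSE`.
#' @param refractory_s Minimum spacing between same-(etype, side) events.
#' @return A tibble of class `event_series`, sorted by time.
#' @export
event_series <- function(events, trial_id = "", validate = TRUE, refractory_s = 0.05) {
  ev <- tibble::as_tibble(events)
  needed <- c("etype", "side", "time", "source")
  if (!all(needed %in% names(ev))) {
    abort_invalid(paste("event series needs columns:", paste(needed, collapse = ", ")))
  }
  bad_type <- setdiff(unique(ev$etype), event_types())
  if (length(bad_type)) abort_invalid(paste("unknown event type:", paste(bad_type, collapse = ", ")))
  bad_side <- setdiff(unique(ev$side), event_sides())
  if (length(bad_side)) abort_invalid(paste("unknown side:", paste(bad_side, collapse = ", ")))
  ev <- dplyr::arrange(ev, .data$time)
  if (validate) {
    issues <- check_event_series(ev, refractory_s = refractory_s)
    if (nrow(issues)) {
      rlang::abort(
        paste0("invalid event series: ", paste(utils::head(issues$problem, 3), collapse = "; ")),
        class = "skatephase_error_invalid_events"
      )
    }
  }
  structure(ev,
    trial_id = trial_id,
    class = unique(c("event_series", class(ev)))
  )
}

#' @rdname event_series
#' @return `check_event_series()` returns a tibble of violations (zero rows
#'   when the series is valid).
#' @export
check_event_series <- function(events, refractory_s = 0.05) {
  ev <- dplyr::arrange(tibble::as_tibble(events), .data$time)
  probs <- character(0)
  fam <- ifelse(ev$etype %in% c("P_ON", "P_OFF"), "pole", "ski")
  for (key in unique(paste(fam, ev$side))) {
    sub <- ev[paste(fam, ev$side) == key, ]
    onoff <- grepl("_ON$", sub$etype)
    if (nrow(sub) >= 2 && any(diff(onoff) == 0)) {
      probs <- c(probs, sprintf("ON/OFF alternation broken for %s", key))
    }
    for (et in unique(sub$etype)) {
      tt <- sub$time[sub$etype == et]
      if (length(tt) >= 2 && any(diff(tt) < refractory_s)) {
        probs <- c(probs, sprintf(
          "events of type %s (%s) closer than %g s", et, key, refractory_s
        ))
      }
    }
  }
  tibble::tibble(problem = probs)
}
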