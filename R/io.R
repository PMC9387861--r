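#' Read and write IMU recordings as CSV with a JSON sidecar
#'
#' The CSV dialect has the exact header
#' `time_s,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z`, one file per sensor
#' location; location, nominal rate and axis convention live in a JSON
#' sidecar (same path with extension `.json`). Reading checks the header,
#' finiteness, strict time monotonicity (errors name the offending line) and
#' grid uniformity: the maximum deviation of the sample interval from `1/fs`
#' must stay below a tenth of a sample, otherwise the file is refused rather
#' than silently resampled.
#'
#' @param rec An [imu_recording()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `read_imu_csv()` returns an [imu_recording()];
#'   `write_imu_csv()` returns `path` invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  df <- tibble::as_tibble(rec)
  names(df)[1] <- "time_s"
  readr::write_csv(df, path)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(list(
    location = attr(rec, "location"),
    fs = attr(rec, "fs"),
    axis_map = attr(rec, "axis_map")
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

abort_parse <- function(msg) rlang::abort(msg, class = "skatephase_error_parse")

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (!file.exists(sidecar)) abort_parse(paste("missing sidecar JSON:", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  want <- c("time_s", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  if (!identical(hdr, want)) {
    abort_parse(paste0("malformed header at line 1: expected '",
                       paste(want, collapse = ","), "'"))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  t <- df$time_s
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    abort_parse(sprintf("non-monotone or duplicated timestamp at line %d", bad[1] + 2L))
  }
  if (!all(vapply(df, function(v) all(is.finite(v)), logical(1)))) {
    row <- which(!stats::complete.cases(is.finite(as.matrix(df))))[1]
    abort_parse(sprintf("non-finite value at line %d", row + 1L))
  }
  fs <- meta$fs
  if (max(abs(diff(t) - 1 / fs)) >= 0.1 / fs) {
    abort_parse("time grid deviates from the sidecar rate by more than 0.1 samples; refusing to resample")
  }
  imu_recording(
    acc = df[, c("acc_x", "acc_y", "acc_z")],
    gyro = df[, c("gyr_x", "gyr_y", "gyr_z")],
    fs = fs, location = meta$location,
    axis_map = as.list(meta$axis_map), t0 = t[1]
  )
}

#' Read and write marker tracks as CSV with a JSON sidecar
#'
#' Header `time_s,z_m`, one file per marker; location and rate in a JSON
#' sidecar as for [write_imu_csv()].
#'
#' @param track A [marker_track()].
#' @param path CSV path.
#' @return `read_marker_csv()` returns a [marker_track()].
#' @export
write_marker_csv <- function(track, path) {
  readr::write_csv(tibble::tibble(time_s = track$time, z_m = track$z), path)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(list(
    location = attr(track, "location"), fs = attr(track, "fs")
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path) {
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (!file.exists(sidecar)) abort_parse(paste("missing sidecar JSON:", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(hdr, c("time_s", "z_m"))) {
    abort_parse("malformed header at line 1: expected 'time_s,z_m'")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    abort_parse(sprintf("non-monotone or duplicated timestamp at line %d", bad[1] + 2L))
  }
  marker_track(df$z_m, fs = meta$fs, location = meta$location, t0 = df$time_s[1])
}

#' Read and write event series as JSON
#'
#' Schema: `{"trial_id": ..., "events": [{"etype", "side", "time", "source"},
#' ...]}` with times in seconds rounded to 6 decimals (microsecond precision,
#' far below one sample at 256 Hz). Reading sorts out-of-order events with a
#' warning (documented leniency) and, when `validate = TRUE`, checks the
#' alternation/refractory invariants.
#'
#' @param events An event tibble.
#' @param path JSON path.
#' @param trial_id Trial identifier (defaults to the series attribute).
#' @param validate Validate invariants on read (default `TRUE`).
#' @return `read_events_json()` returns an [event_series()].
#' @export
write_events_json <- function(events, path, trial_id = NULL) {
  trial_id <- trial_id %||% (attr(events, "trial_id") %||% "")
  ev <- tibble::as_tibble(events)[, c("etype", "side", "time", "source")]
  ev$time <- round(ev$time, 6)
  jsonlite::write_json(list(trial_id = trial_id, events = ev), path,
    auto_unbox = TRUE, digits = 6
  )
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path, validate = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$events) || !all(c("etype", "side", "time", "source") %in% names(obj$events))) {
    abort_parse("events JSON must contain an 'events' array with etype/side/time/source")
  }
  ev <- tibble::as_tibble(obj$events)
  if (is.unsorted(ev$time, strictly = FALSE)) {
    rlang::warn("events out of time order in JSON; sorting on read")
    ev <- ev[order(ev$time), ]
  }
  event_series(ev, trial_id = obj$trial_id %||% "", validate = validate)
}

#' Read and write cycle tables as CSV
#'
#' Column layout:
#' `cycle_id,t_start,t_end,S_CY,S_CT_left,S_SW_left,S_CT_right,S_SW_right,P_CT,P_SW,delay_Pon_Son,delay_Soff_Poff,n_pole_plants,subtech`
#' (`n_pole_plants` carries the merged plant count the decision tree needs).
#' An undetermined sub-technique is serialised as the literal `NaN`.
#'
#' @param records Phase/classification table ([cycle_phases()] +
#'   [classify_cycles()]).
#' @param path CSV path.
#' @return `read_cycles_csv()` returns a tibble.
#' @export
write_cycles_csv <- function(records, path) {
  cols <- c("cycle_id", "t_start", "t_end", "S_CY", "S_CT_left", "S_SW_left",
            "S_CT_right", "S_SW_right", "P_CT", "P_SW",
            "delay_Pon_Son", "delay_Soff_Poff", "n_pole_plants", "subtech")
  df <- records
  if (!"subtech" %in% names(df)) df$subtech <- NA_character_
  df <- df[, cols]
  df$subtech[is.na(df$subtech)] <- "NaN"
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_cycles_csv
#' @export
read_cycles_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df$subtech[df$subtech == "NaN"] <- NA_character_
  df
}

#' Bundle and persist a run configuration
#'
#' Collects the detection, classification and matching settings (and any
#' generator overrides) into one object that round-trips losslessly through
#' JSON.
#'
#' @param detection A [detection_config()].
#' @param tree A [tree_config()].
#' @param sync_window_s Pole-merge window (s).
#' @param max_gap_s Event-attribution bound (`NULL`: half the median cycle).
#' @param generator Named list of [trial_spec()] overrides.
#' @param log_level One of `"quiet"`, `"info"`, `"debug"`.
#' @param out_dir Output directory for report writers.
#' @return A list of class `run_config`.
#' @export
run_config <- function(detection = detection_config(), tree = tree_config(),
                       sync_window_s = 0.12, max_gap_s = NULL,
                       generator = list(), log_level = "info", out_dir = ".") {
  structure(list(
    detection = detection, tree = tree, sync_window_s = sync_window_s,
    max_gap_s = max_gap_s, generator = generator,
    log_level = log_level, out_dir = out_dir
  ), class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- do.call(detection_config, as.list(obj$detection))
  tre <- do.call(tree_config, as.list(obj$tree))
  run_config(
    detection = det, tree = tre,
    sync_window_s = obj$sync_window_s,
    max_gap_s = obj$max_gap_s,
    generator = as.list(obj$generator),
    log_level = obj$log_level, out_dir = obj$out_dir
  )
}

#' Write the validation report tables
#'
#' Writes `table1.csv` (event attribution percentages per event type and
#' sub-technique plus the classification row), `table2.csv` (inter-trial
#' bias/precision of events and phases, in ms and in percent of phase
#' duration, per sub-technique and pooled) and `posthoc.csv` (Kruskal-Wallis
#' and pairwise DSCF comparisons of the per-trial precision across
#' sub-techniques, per phase).
#'
#' @param study A `skate_validation` from [run_validation_study()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_validation_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- study$detection_table
  det$label <- event_labels()[det$etype]
  cls <- dplyr::group_by(study$per_trial_classification, .data$subtech)
  cls <- dplyr::summarise(cls,
    n_gt = sum(.data$n_cycles), n_matched = sum(.data$n_correct), .groups = "drop"
  )
  cls_all <- tibble::tibble(
    subtech = "All Gear",
    n_gt = sum(cls$n_gt), n_matched = sum(cls$n_matched)
  )
  cls <- dplyr::bind_rows(cls, cls_all)
  cls$etype <- "subtech"; cls$label <- "Sub-technique"
  cls$pct <- detection_rate(cls$n_gt, cls$n_matched)
  t1 <- dplyr::bind_rows(det, cls)[, c("label", "subtech", "n_gt", "n_matched", "pct")]
  t1$pct <- round(t1$pct, 1)
  readr::write_csv(t1, file.path(dir, "table1.csv"))

  ev <- study$event_stats; ev$block <- "event_ms"; ev$name <- ev$etype
  ph <- study$phase_stats; ph$block <- "phase_ms"; ph$name <- ph$phase
  pr <- study$phase_stats_rel; pr$block <- "phase_pct"; pr$name <- pr$phase
  t2 <- dplyr::bind_rows(
    ev[, c("block", "name", "gear", "b_mu", "b_sigma", "sigma_mu", "sigma_sigma", "n_trials")],
    ph[, c("block", "name", "gear", "b_mu", "b_sigma", "sigma_mu", "sigma_sigma", "n_trials")],
    pr[, c("block", "name", "gear", "b_mu", "b_sigma", "sigma_mu", "sigma_sigma", "n_trials")]
  )
  readr::write_csv(t2, file.path(dir, "table2.csv"))

  ph_trials <- study$per_trial_phases
  rows <- list()
  for (p in unique(ph_trials$phase)) {
    sub <- ph_trials[ph_trials$phase == p & is.finite(ph_trials$precision_ms), ]
    if (length(unique(sub$subtech)) < 2L || nrow(sub) < 3L) next
    kw <- kruskal_wallis(sub, .data$precision_ms, .data$subtech)
    ds <- dscf_posthoc(sub, .data$precision_ms, .data$subtech)
    ds$phase <- p
    ds$kw_H <- kw$statistic; ds$kw_p <- kw$p_value
    rows[[p]] <- ds
  }
  if (length(rows)) {
    readr::write_csv(dplyr::bind_rows(rows), file.path(dir, "posthoc.csv"))
  }
  invisible(dir)
}
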