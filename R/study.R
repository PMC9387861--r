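#' Phase occurrences of one detection system
#'
#' Lists every realised inner-cycle phase with the time of its opening event
#' and its duration: per-side ski contact (`S_CT`) and swing (`S_SW`) times,
#' cycle times (`S_CY`, left ski plant to left ski plant), and merged-pole
#' contact (`P_CT`) and swing (`P_SW`) times. Used to pair phase occurrences
#' between two systems by their opening events.
#'
#' @param events Event tibble with per-side ski events and pole events (pole
#'   sides are merged internally).
#' @param sync_window_s Pole-merge window (s).
#' @return A tibble: `phase`, `side`, `t_key` (opening event time),
#'   `duration`.
#' @export
phase_occurrences <- function(events, sync_window_s = 0.12) {
  merged <- merge_pole_sides(events, sync_window_s)
  rows <- list()
  seqd <- function(on, off) {
    # pair each ON with the first OFF before the next ON
    out <- tibble::tibble(t_on = numeric(0), t_off = numeric(0), t_next = numeric(0))
    for (i in seq_along(on)) {
      nxt <- if (i < length(on)) on[i + 1L] else Inf
      o <- off[off > on[i] & off < nxt]
      if (length(o)) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          t_on = on[i], t_off = o[1],
          t_next = if (is.finite(nxt)) nxt else NA_real_
        ))
      }
    }
    out
  }
  for (side in c("left", "right")) {
    on <- sort(events$time[events$etype == "S_ON" & events$side == side])
    off <- sort(events$time[events$etype == "S_OFF" & events$side == side])
    pr <- seqd(on, off)
    rows[[paste0("sct_", side)]] <- tibble::tibble(
      phase = "S_CT", side = side, t_key = pr$t_on, duration = pr$t_off - pr$t_on
    )
    ok <- !is.na(pr$t_next)
    rows[[paste0("ssw_", side)]] <- tibble::tibble(
      phase = "S_SW", side = side, t_key = pr$t_off[ok], duration = pr$t_next[ok] - pr$t_off[ok]
    )
  }
  lon <- sort(events$time[events$etype == "S_ON" & events$side == "left"])
  if (length(lon) >= 2L) {
    rows$scy <- tibble::tibble(
      phase = "S_CY", side = "left", t_key = lon[-length(lon)], duration = diff(lon)
    )
  }
  pon <- sort(merged$time[merged$etype == "P_ON"])
  poff <- sort(merged$time[merged$etype == "P_OFF"])
  pp <- seqd(pon, poff)
  rows$pct <- tibble::tibble(
    phase = "P_CT", side = "merged", t_key = pp$t_on, duration = pp$t_off - pp$t_on
  )
  ok <- !is.na(pp$t_next)
  rows$psw <- tibble::tibble(
    phase = "P_SW", side = "merged", t_key = pp$t_off[ok], duration = pp$t_next[ok] - pp$t_off[ok]
  )
  dplyr::bind_rows(rows)
}

half_median_cycle <- function(events) {
  lon <- sort(events$time[events$etype == "S_ON" & events$side == "left"])
  if (length(lon) >= 3L) stats::median(diff(lon)) / 2 else 0.6
}

#' Compare two event series of one trial
#'
#' Matches events per (etype, side) between a reference series and an IMU
#' series, and pairs phase occurrences via their opening events, yielding
#' per-event and per-phase error tables with the `ref - imu` sign convention
#' (positive error: detected earlier on the IMU).
#'
#' @param ref,imu Event tibbles for the same trial.
#' @param max_gap_s Attribution bound; default half the median reference
#'   cycle duration.
#' @param sync_window_s Pole-merge window (s).
#' @return A list of class `trial_comparison`: `event_errors` (tibble
#'   `etype`, `side`, `ref_time`, `error_s`), `phase_errors` (tibble `phase`,
#'   `side`, `error_s`, `ref_duration_s`, `rel_pct`), `attribution` (tibble
#'   `etype`, `side`, `n_ref`, `n_matched`, `n_spurious`).
#' @export
compare_events <- function(ref, imu, max_gap_s = NULL, sync_window_s = 0.12) {
  if (is.null(max_gap_s)) max_gap_s <- half_median_cycle(ref)
  ev_err <- list(); attr_rows <- list()
  for (et in event_types()) {
    for (sd in c("left", "right")) {
      r <- ref[ref$etype == et & ref$side == sd, ]
      i <- imu[imu$etype == et & imu$side == sd, ]
      if (!nrow(r) && !nrow(i)) next
      m <- match_events(r, i, max_gap_s)
      ev_err[[paste(et, sd)]] <- tibble::tibble(
        etype = et, side = sd,
        ref_time = m$pairs$ref_time, error_s = m$pairs$error_s
      )
      attr_rows[[paste(et, sd)]] <- tibble::tibble(
        etype = et, side = sd, n_ref = nrow(r),
        n_matched = nrow(m$pairs), n_spurious = length(m$spurious_imu)
      )
    }
  }
  ph_r <- phase_occurrences(ref, sync_window_s)
  ph_i <- phase_occurrences(imu, sync_window_s)
  ph_err <- list()
  for (key in unique(paste(ph_r$phase, ph_r$side))) {
    r <- ph_r[paste(ph_r$phase, ph_r$side) == key, ]
    i <- ph_i[paste(ph_i$phase, ph_i$side) == key, ]
    if (!nrow(r) || !nrow(i)) next
    m <- match_events(r$t_key, i$t_key, max_gap_s)
    if (!nrow(m$pairs)) next
    rd <- r$duration[match(m$pairs$ref_time, r$t_key)]
    id <- i$duration[match(m$pairs$imu_time, i$t_key)]
    err <- rd - id
    ph_err[[key]] <- tibble::tibble(
      phase = r$phase[1], side = r$side[1],
      error_s = err, ref_duration_s = rd,
      rel_pct = 100 * err / rd
    )
  }
  structure(list(
    event_errors = dplyr::bind_rows(ev_err),
    phase_errors = dplyr::bind_rows(ph_err),
    attribution = dplyr::bind_rows(attr_rows),
    max_gap_s = max_gap_s
  ), class = "trial_comparison")
}

event_labels <- function() {
  c(P_ON = "Pole initial contact", P_OFF = "Pole final contact",
    S_ON = "Ski initial contact", S_OFF = "Ski final contact")
}
phase_names <- function() c("P_CT", "P_SW", "S_CT", "S_SW", "S_CY")

#' Simulate, detect and validate one trial end to end
#'
#' Runs the full pipeline on one [trial_spec()]: simulate, detect events with
#' both systems, compare IMU against the optical reference, score detections
#' against ground truth, and classify sub-techniques from the IMU events.
#'
#' @param spec A [trial_spec()].
#' @param cfg A [detection_config()].
#' @param tree_cfg A [tree_config()].
#' @return A list: `subtech`, `comparison` (see [compare_events()]),
#'   `gt_detection` (per etype/side ground-truth attribution counts),
#'   `classification` (see [classify_trial()]), `n_cycles`.
#' @export
validate_trial <- function(spec, cfg = detection_config(), tree_cfg = tree_config()) {
  tr <- simulate_trial(spec)
  gt <- tr$ground_truth
  gt_ev <- gt$events[!gt$events$pad, ]
  imu_ev <- detect_imu_events(tr, cfg)
  ref_ev <- detect_reference_trial(tr$markers)
  max_gap <- half_median_cycle(gt_ev)

  gt_rows <- list()
  for (et in event_types()) {
    for (sd in c("left", "right")) {
      g <- gt_ev[gt_ev$etype == et & gt_ev$side == sd, ]
      i <- imu_ev[imu_ev$etype == et & imu_ev$side == sd, ]
      m <- match_events(g, i, max_gap)
      gt_rows[[paste(et, sd)]] <- tibble::tibble(
        etype = et, side = sd, n_gt = nrow(g), n_matched = nrow(m$pairs)
      )
    }
  }

  cmp <- compare_events(ref_ev, imu_ev, max_gap_s = max_gap)
  records <- classify_cycles(cycle_phases(imu_ev), tree_cfg)
  cls <- classify_trial(records, truth = gt$cycles, cfg = tree_cfg)

  list(
    subtech = spec$subtech,
    comparison = cmp,
    gt_detection = dplyr::bind_rows(gt_rows),
    classification = cls,
    n_cycles = nrow(gt$cycles)
  )
}

#' Run a multi-trial validation study on synthetic data
#'
#' Simulates a batch of trials (by default 10 per sub-technique), runs both
#' detection systems and the classifier on each, and pools the results into
#' the validation summaries: attribution percentages per event type and
#' sub-technique, inter-trial bias/precision of events and inner-cycle
#' phases (absolute and relative), and per-cycle classification accuracy.
#'
#' @param n_per_tech Trials per sub-technique.
#' @param n_cycles Cycles per trial.
#' @param seed Root seed for the batch.
#' @param cfg A [detection_config()].
#' @param tree_cfg A [tree_config()].
#' @param ... Further [trial_spec()] arguments applied to every trial.
#' @return A list of class `skate_validation`; see [summary.skate_validation()]
#'   and [glance.skate_validation()]. Key elements: `detection_table`,
#'   `event_stats`, `phase_stats`, `phase_stats_rel`, `headline` (overall
#'   detection %, worst phase `sigma_mu` in ms and in % of phase duration,
#'   classification %), and the per-trial tables they were computed from.
#' @export
run_validation_study <- function(n_per_tech = 10L, n_cycles = 50L, seed = 42L,
                                 cfg = detection_config(), tree_cfg = tree_config(),
                                 ...) {
  specs <- batch_specs(n_per_tech, n_cycles, seed, ...)
  per_event <- list(); per_phase <- list(); per_det <- list(); per_cls <- list()
  for (ti in seq_along(specs)) {
    vt <- validate_trial(specs[[ti]], cfg, tree_cfg)
    tech <- vt$subtech
    ee <- vt$comparison$event_errors
    if (nrow(ee)) {
      ee <- dplyr::group_by(ee, .data$etype)
      ee <- dplyr::summarise(ee, intra_trial_stats(.data$error_s), .groups = "drop")
      ee$trial <- ti; ee$subtech <- tech
      per_event[[ti]] <- ee
    }
    pe <- vt$comparison$phase_errors
    if (nrow(pe)) {
      pe <- dplyr::group_by(pe, .data$phase)
      pe <- dplyr::summarise(
        pe,
        intra_trial_stats(.data$error_s),
        bias_rel = mean(.data$rel_pct), precision_rel = stats::sd(.data$rel_pct),
        .groups = "drop"
      )
      pe$trial <- ti; pe$subtech <- tech
      per_phase[[ti]] <- pe
    }
    det <- vt$gt_detection
    det$trial <- ti; det$subtech <- tech
    per_det[[ti]] <- det
    per_cls[[ti]] <- tibble::tibble(
      trial = ti, subtech = tech,
      n_cycles = vt$n_cycles,
      n_correct = sum(vt$classification$aligned$correct)
    )
  }
  per_event <- dplyr::bind_rows(per_event)
  per_phase <- dplyr::bind_rows(per_phase)
  per_det <- dplyr::bind_rows(per_det)
  per_cls <- dplyr::bind_rows(per_cls)

  pool_stats <- function(df, keyvar, biasvar = "bias_ms", precvar = "precision_ms") {
    groups <- list(G2 = "G2", G3 = "G3", G4 = "G4", `All Gear` = c("G2", "G3", "G4"))
    out <- list()
    for (gname in names(groups)) {
      sub <- df[df$subtech %in% groups[[gname]], ]
      if (!nrow(sub)) next
      st <- dplyr::group_by(sub, .data[[keyvar]])
      st <- dplyr::summarise(
        st,
        inter_trial_stats(data.frame(
          bias_ms = .data[[biasvar]], precision_ms = .data[[precvar]]
        )),
        .groups = "drop"
      )
      st$gear <- gname
      out[[gname]] <- st
    }
    dplyr::bind_rows(out)
  }

  event_stats <- pool_stats(per_event, "etype")
  phase_stats <- pool_stats(per_phase, "phase")
  phase_stats_rel <- pool_stats(per_phase, "phase", "bias_rel", "precision_rel")

  det_tab <- dplyr::group_by(per_det, .data$etype, .data$subtech)
  det_tab <- dplyr::summarise(det_tab,
    n_gt = sum(.data$n_gt), n_matched = sum(.data$n_matched), .groups = "drop"
  )
  det_all <- dplyr::group_by(per_det, .data$etype)
  det_all <- dplyr::summarise(det_all,
    n_gt = sum(.data$n_gt), n_matched = sum(.data$n_matched), .groups = "drop"
  )
  det_all$subtech <- "All Gear"
  detection_table <- dplyr::bind_rows(det_tab, det_all)
  detection_table$pct <- detection_rate(detection_table$n_gt, detection_table$n_matched)

  all_ms <- phase_stats[phase_stats$gear == "All Gear" & phase_stats$phase %in% phase_names(), ]
  all_rel <- phase_stats_rel[phase_stats_rel$gear == "All Gear" &
                               phase_stats_rel$phase %in% phase_names(), ]
  headline <- list(
    detection_pct = detection_rate(sum(per_det$n_gt), sum(per_det$n_matched)),
    worst_sigma_mu_ms = max(all_ms$sigma_mu, na.rm = TRUE),
    worst_sigma_mu_rel_pct = max(abs(all_rel$sigma_mu), na.rm = TRUE),
    classification_pct = 100 * sum(per_cls$n_correct) / sum(per_cls$n_cycles)
  )

  structure(list(
    detection_table = detection_table,
    event_stats = event_stats,
    phase_stats = phase_stats,
    phase_stats_rel = phase_stats_rel,
    per_trial_events = per_event,
    per_trial_phases = per_phase,
    per_trial_detection = per_det,
    per_trial_classification = per_cls,
    headline = headline,
    n_per_tech = n_per_tech, n_cycles = n_cycles, seed = seed
  ), class = "skate_validation")
}
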