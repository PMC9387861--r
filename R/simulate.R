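#' Specify a synthetic skating trial
#'
#' A trial specification fixes the study conditions under which a synthetic
#' trial is generated: sub-technique, cycle rate, number of cycles, sensor
#' rates, noise levels, gyroscope bias, per-event timing jitter, inter-system
#' clock offset and the random seed. Defaults emulate treadmill roller-ski
#' skating with wrist/ski IMUs at 256 Hz and a 200 Hz optical reference.
#'
#' @param subtech `"G2"`, `"G3"`, `"G4"` or `"mixed"` (block-wise changes).
#' @param n_cycles Number of ground-truth cycles (>= 2).
#' @param cycle_rate Cycles per second; `NULL` uses the per-technique default
#'   (G2 0.9, G3 0.8, G4 0.7 Hz, matching typical uphill/moderate/flat paces).
#' @param fs_imu,fs_ref IMU and reference sampling rates (Hz).
#' @param noise_acc_sd Accelerometer white-noise SD (m/s^2).
#' @param noise_gyro_sd Gyroscope white-noise SD (deg/s).
#' @param gyro_bias Constant gyroscope bias (deg/s), integrating into drift.
#' @param jitter_sd_s SD of independent Gaussian jitter on every event time (s).
#' @param imu_offset_s Known constant clock offset of the IMU streams relative
#'   to the marker tracks (s).
#' @param p_two_wheel Probability that a ski landing is split into two wheel
#'   impacts (the dominant source of initial-contact ambiguity on roller skis).
#' @param two_wheel_gap_s Maximum gap between the two wheel impacts (s).
#' @param marker_noise_sd_m Marker vertical-position noise SD (m).
#' @param seed Integer seed; the same seed reproduces the trial bit-for-bit.
#'
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(subtech = c("G3", "G2", "G4", "mixed"),
                       n_cycles = 50L,
                       cycle_rate = NULL,
                       fs_imu = 256, fs_ref = 200,
                       noise_acc_sd = 0.5, noise_gyro_sd = 2,
                       gyro_bias = 0.5,
                       jitter_sd_s = 0.010,
                       imu_offset_s = 0,
                       p_two_wheel = 0.30, two_wheel_gap_s = 0.060,
                       marker_noise_sd_m = 0.001,
                       seed = 1L) {
  subtech <- rlang::arg_match(subtech)
  if (n_cycles < 2L) abort_invalid("`n_cycles` must be >= 2")
  for (nm in c("fs_imu", "fs_ref")) {
    if (get(nm) <= 0) abort_invalid(paste0("`", nm, "` must be > 0"))
  }
  for (nm in c("noise_acc_sd", "noise_gyro_sd", "jitter_sd_s", "p_two_wheel",
               "two_wheel_gap_s", "marker_noise_sd_m")) {
    if (get(nm) < 0) abort_invalid(paste0("`", nm, "` must be >= 0"))
  }
  structure(list(
    subtech = subtech, n_cycles = as.integer(n_cycles),
    cycle_rate = cycle_rate,
    fs_imu = fs_imu, fs_ref = fs_ref,
    noise_acc_sd = noise_acc_sd, noise_gyro_sd = noise_gyro_sd,
    gyro_bias = gyro_bias, jitter_sd_s = jitter_sd_s,
    imu_offset_s = imu_offset_s,
    p_two_wheel = p_two_wheel, two_wheel_gap_s = two_wheel_gap_s,
    marker_noise_sd_m = marker_noise_sd_m,
    seed = as.integer(seed)
  ), class = "trial_spec")
}

default_cycle_rate <- function(tech) {
  c(G2 = 0.9, G3 = 0.8, G4 = 0.7)[[tech]]
}

# technique sequence over ground-truth cycles (mixed: blocks of 8)
cycle_techs <- function(spec) {
  if (spec$subtech != "mixed") {
    rep(spec$subtech, spec$n_cycles)
  } else {
    blocks <- rep(c("G3", "G2", "G4"), length.out = ceiling(spec$n_cycles / 8))
    rep(blocks, each = 8)[seq_len(spec$n_cycles)]
  }
}

# phase-fraction template shared by schedule and renderers
.ski_duty <- 0.55   # ski contact fraction of the cycle, per side
.pole_duty <- 0.30  # pole contact fraction of the cycle

#' Schedule ground-truth events for a synthetic trial
#'
#' Lays out, per cycle of duration `T = 1/cycle_rate`: the left ski plant at
#' the cycle start and the right ski plant near `T/2`, ski contacts of
#' `0.55 T` per side, and the technique's pole pattern: G3 poles with every
#' leg push (two near-synchronous double-pole actions per cycle), G4 poles
#' once per cycle synchronously with the left ski plant, and G2 poles once
#' per cycle offset from the nearest ski plant by 0.15-0.25 `T`. Pole contact
#' lasts `0.30 T`; left/right pole events of one action are split by a small
#' side asynchrony (larger, asymmetric in G2). Independent Gaussian jitter
#' (`jitter_sd_s`) is added to every event; cycles whose jitter violates
#' ordering or the 50 ms refractory bound are re-jittered, and the generator
#' fails if more than 10% of cycles cannot be repaired.
#'
#' One pad cycle is scheduled before and after the ground-truth span (flagged
#' `pad = TRUE`) so that renderers and detectors have complete cycles at the
#' trial boundaries; pad events are not part of the ground truth.
#'
#' @param spec A [trial_spec()].
#' @param seed Optional seed override (defaults to `spec$seed`).
#' @return A list of class `ski_ground_truth` with elements `events` (tibble:
#'   `etype`, `side`, `time`, `source`, `cycle`, `pad`), `cycles` (tibble:
#'   `cycle_id`, `t_start`, `t_end`, `subtech`) and `spec`.
#' @export
schedule_events <- function(spec, seed = NULL) {
  set.seed(seed %||% spec$seed)
  n <- spec$n_cycles
  techs <- cycle_techs(spec)
  techs_pad <- c(techs[1], techs, techs[n])        # cycles 0 .. n+1
  rates <- if (is.null(spec$cycle_rate)) {
    unname(vapply(techs_pad, default_cycle_rate, numeric(1)))
  } else rep(spec$cycle_rate, n + 2L)
  Tk <- 1 / rates
  starts <- cumsum(c(-Tk[1], Tk[-length(Tk)]))     # pad cycle 0 starts at -T

  one_cycle <- function(k) {                        # k in 0..n+1 (index k+1)
    i <- k + 1L
    s <- starts[i]; T <- Tk[i]; tech <- techs_pad[i]
    ski <- tibble::tibble(
      etype = c("S_ON", "S_OFF", "S_ON", "S_OFF"),
      side = c("left", "left", "right", "right"),
      nominal = c(s, s + .ski_duty * T, s + 0.5 * T, s + (0.5 + .ski_duty) * T),
      action = c(1L, 1L, 1L, 1L)
    )
    acts <- switch(tech,
      G3 = c(s + stats::runif(1, -0.03, 0.03), s + 0.5 * T + stats::runif(1, -0.03, 0.03)),
      G4 = s + stats::runif(1, -0.03, 0.03),
      G2 = s + stats::runif(1, 0.15, 0.25) * T
    )
    dside <- if (tech == "G2") 0.040 else 0.012
    pole <- purrr::map_dfr(seq_along(acts), function(a) {
      on_l <- acts[a] - dside / 2
      on_r <- acts[a] + dside / 2
      tibble::tibble(
        etype = c("P_ON", "P_OFF", "P_ON", "P_OFF"),
        side = c("left", "left", "right", "right"),
        nominal = c(on_l, on_l + .pole_duty * T, on_r, on_r + .pole_duty * T),
        action = a
      )
    })
    out <- dplyr::bind_rows(ski, pole)
    out$cycle <- k
    out$subtech <- tech
    out
  }

  ev <- purrr::map_dfr(0:(n + 1L), one_cycle)
  ev$jitter <- stats::rnorm(nrow(ev), 0, spec$jitter_sd_s)

  bad_cycles <- function(ev) {
    ev$time <- ev$nominal + ev$jitter
    flagged <- integer(0)
    fam <- ifelse(ev$etype %in% c("P_ON", "P_OFF"), "pole", "ski")
    for (key in unique(paste(fam, ev$side))) {
      sub <- ev[paste(fam, ev$side) == key, ]
      sub <- sub[order(sub$nominal), ]
      if (nrow(sub) < 2) next
      dt <- diff(sub$time)
      viol <- which(dt <= 0)
      same <- sub$etype[-1] == sub$etype[-nrow(sub)]
      viol <- union(viol, which(same & dt < 0.05))
      if (length(viol)) {
        flagged <- union(flagged, unique(c(sub$cycle[viol], sub$cycle[viol + 1L])))
      }
    }
    flagged
  }

  bad <- bad_cycles(ev)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    redo <- ev$cycle %in% bad
    ev$jitter[redo] <- stats::rnorm(sum(redo), 0, spec$jitter_sd_s)
    bad <- bad_cycles(ev)
    tries <- tries + 1L
  }
  if (length(bad) > 0.10 * n) {
    rlang::abort(
      sprintf("jitter makes %d of %d cycles infeasible (overlapping phases)", length(bad), n),
      class = "skatephase_error_generator_infeasible"
    )
  }
  ev$time <- ev$nominal + ev$jitter
  ev$pad <- ev$cycle < 1L | ev$cycle > n
  ev$source <- "ground_truth"
  ev <- dplyr::arrange(ev, .data$time)

  left_on <- ev[ev$etype == "S_ON" & ev$side == "left", ]
  left_on <- left_on[order(left_on$cycle), ]
  gt_rows <- match(1:n, left_on$cycle)
  cycles <- tibble::tibble(
    cycle_id = 1:n,
    t_start = left_on$time[gt_rows],
    t_end = left_on$time[gt_rows + 1L],
    subtech = techs
  )

  structure(list(
    events = ev[, c("etype", "side", "time", "source", "cycle", "pad")],
    cycles = cycles,
    spec = spec
  ), class = "ski_ground_truth")
}

#' @rdname schedule_events
#' @param gt A `ski_ground_truth`.
#' @return `ground_truth_events()` returns the non-pad events as a validated
#'   [event_series()].
#' @export
ground_truth_events <- function(gt) {
  event_series(gt$events[!gt$events$pad, c("etype", "side", "time", "source", "cycle")],
    trial_id = paste0("sim_seed", gt$spec$seed)
  )
}

# piecewise half-cosine interpolant through (knot_t, knot_v); C1 (zero slope
# at every knot), constant beyond the first/last knot. Returns value and
# analytic derivative on grid t.
piecewise_cosine <- function(t, knot_t, knot_v) {
  j <- findInterval(t, knot_t)
  val <- numeric(length(t))
  der <- numeric(length(t))
  val[j == 0] <- knot_v[1]
  m <- length(knot_t)
  val[j >= m] <- knot_v[m]
  inside <- j >= 1 & j < m
  ji <- j[inside]
  L <- knot_t[ji + 1L] - knot_t[ji]
  u <- (t[inside] - knot_t[ji]) / L
  dv <- knot_v[ji + 1L] - knot_v[ji]
  val[inside] <- knot_v[ji] + dv * (1 - cos(pi * u)) / 2
  der[inside] <- dv * pi / (2 * L) * sin(pi * u)
  list(value = val, deriv = der)
}

# add Gaussian bumps amp*exp(-((t-c)/w)^2/2) into v (grid t, uniform)
add_bumps <- function(v, t, centers, amps, widths) {
  fs <- 1 / (t[2] - t[1])
  n <- length(v)
  widths <- rep_len(widths, length(centers))
  amps <- rep_len(amps, length(centers))
  for (i in seq_along(centers)) {
    c0 <- centers[i]; w <- widths[i]
    i0 <- max(1L, floor((c0 - 6 * w - t[1]) * fs) + 1L)
    i1 <- min(n, ceiling((c0 + 6 * w - t[1]) * fs) + 1L)
    if (i0 > n || i1 < 1L || i0 > i1) next
    idx <- i0:i1
    v[idx] <- v[idx] + amps[i] * exp(-0.5 * ((t[idx] - c0) / w)^2)
  }
  v
}

loc_events <- function(gt, family, side) {
  ev <- gt$events
  types <- if (family == "pole") c("P_ON", "P_OFF") else c("S_ON", "S_OFF")
  sub <- ev[ev$etype %in% types & ev$side == side, ]
  sub[order(sub$time), ]
}

trial_time_span <- function(gt, margin = 0.3) {
  c(min(gt$events$time) - margin, max(gt$events$time) + margin)
}

#' Render marker vertical trajectories for a scheduled trial
#'
#' For each pole tip and ski, builds the vertical position the optical
#' reference would observe: a near-zero plateau while in contact with the
#' ground, and a smooth raised-cosine flight arc between a final contact and
#' the next initial contact, C1-continuous at the junctions, where the
#' curvature maxima coincide with the ground-truth contact times by
#' construction. Sampled at `fs_ref` with additive Gaussian noise
#' (`marker_noise_sd_m`).
#'
#' @param gt A `ski_ground_truth` from [schedule_events()].
#' @param spec The [trial_spec()] (defaults to `gt$spec`).
#' @param seed Optional seed override for noise and arc heights.
#' @return Named list of [marker_track()]s: `pole_tip_left`, `pole_tip_right`,
#'   `ski_left`, `ski_right`.
#' @export
render_marker_tracks <- function(gt, spec = gt$spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- trial_time_span(gt)
  t <- seq(span[1], span[2], by = 1 / spec$fs_ref)
  out <- list()
  for (loc in marker_locations()) {
    family <- if (grepl("pole", loc)) "pole" else "ski"
    side <- if (grepl("left", loc)) "left" else "right"
    ev <- loc_events(gt, family, side)
    on_t <- ev$time[grepl("_ON$", ev$etype)]
    off_t <- ev$time[grepl("_OFF$", ev$etype)]
    h_rng <- if (family == "pole") c(0.12, 0.25) else c(0.05, 0.12)
    # flights: off_i -> on_{i+1}, plus virtual lead-in/lead-out arcs
    flights <- tibble::tibble(
      t0 = off_t[-length(off_t)][off_t[-length(off_t)] < on_t[-1]],
      t1 = on_t[-1][off_t[-length(off_t)] < on_t[-1]]
    )
    mean_fl <- mean(flights$t1 - flights$t0)
    flights <- dplyr::bind_rows(
      tibble::tibble(t0 = on_t[1] - mean_fl, t1 = on_t[1]),
      flights,
      tibble::tibble(t0 = off_t[length(off_t)], t1 = off_t[length(off_t)] + mean_fl)
    )
    z <- numeric(length(t))
    hts <- stats::runif(nrow(flights), h_rng[1], h_rng[2])
    for (i in seq_len(nrow(flights))) {
      idx <- which(t > flights$t0[i] & t < flights$t1[i])
      if (!length(idx)) next
      u <- (t[idx] - flights$t0[i]) / (flights$t1[i] - flights$t0[i])
      z[idx] <- hts[i] / 2 * (1 - cos(2 * pi * u))
    }
    z <- z + stats::rnorm(length(z), 0, spec$marker_noise_sd_m)
    loc_name <- if (family == "pole") paste0("pole_tip_", side) else paste0("ski_", side)
    out[[loc_name]] <- marker_track(z, fs = spec$fs_ref, location = loc_name, t0 = t[1])
  }
  out
}

#' Render the four IMU streams for a scheduled trial
#'
#' Builds, per wrist: a yaw angular-velocity oscillation whose integrated
#' angle peaks 35 ms before each pole plant and bottoms out at each pole
#' release, a smooth swing-deceleration dip into each plant, a negative-then-positive acceleration doublet at each pole plant
#' (the impact signature the wrist detector keys on) and a short (10 ms)
#' negative transient at each pole release. Per ski: a roll angular-velocity
#' oscillation at the leg-cycle rate whose integrated angle peaks at each ski
#' plant and bottoms at each ski release, a positive vertical-acceleration
#' spike at each ski plant (optionally split into two wheel impacts up to
#' `two_wheel_gap_s` apart) and a negative spike at each release. All gyro
#' channels carry the constant `gyro_bias`; all channels carry white Gaussian
#' noise; streams are shifted by `imu_offset_s` relative to the marker tracks.
#'
#' @inheritParams render_marker_tracks
#' @return Named list of [imu_recording()]s: `wrist_left`, `wrist_right`,
#'   `ski_left`, `ski_right`.
#' @export
render_imu_streams <- function(gt, spec = gt$spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- trial_time_span(gt)
  t <- seq(span[1], span[2], by = 1 / spec$fs_imu)  # trial clock
  nsamp <- length(t)
  am <- default_axis_map()
  noise <- function(sd) stats::rnorm(nsamp, 0, sd)
  out <- list()

  for (side in c("left", "right")) {
    # --- wrist -----------------------------------------------------------
    pe <- loc_events(gt, "pole", side)
    p_on <- pe$time[pe$etype == "P_ON"]
    p_off <- pe$time[pe$etype == "P_OFF"]
    knots <- rbind(
      data.frame(tt = p_on - 0.035, vv = 30),
      data.frame(tt = p_off, vv = -30)
    )
    knots <- knots[order(knots$tt), ]
    pc <- piecewise_cosine(t, knots$tt, knots$vv)
    gyr_yaw <- pc$deriv + spec$gyro_bias + noise(spec$noise_gyro_sd)
    acc_yaw <- numeric(nsamp)
    # smooth swing-deceleration dip into the plant (baseline arm motion)
    acc_yaw <- add_bumps(acc_yaw, t, p_on, -5.0, 0.020)
    acc_yaw <- add_bumps(acc_yaw, t, p_on, -6.0, 0.006)
    acc_yaw <- add_bumps(acc_yaw, t, p_on + 0.025, 7.5, 0.006)
    acc_yaw <- add_bumps(acc_yaw, t, p_off, -5.0, 0.004)
    acc_yaw <- acc_yaw + noise(spec$noise_acc_sd)
    acc <- data.frame(x = noise(spec$noise_acc_sd), y = noise(spec$noise_acc_sd), z = acc_yaw)
    gyr <- data.frame(
      x = spec$gyro_bias + noise(spec$noise_gyro_sd),
      y = spec$gyro_bias + noise(spec$noise_gyro_sd),
      z = gyr_yaw
    )
    out[[paste0("wrist_", side)]] <- imu_recording(
      acc, gyr, fs = spec$fs_imu, location = paste0("wrist_", side),
      axis_map = am, t0 = t[1] + spec$imu_offset_s
    )

    # --- ski -------------------------------------------------------------
    se <- loc_events(gt, "ski", side)
    s_on <- se$time[se$etype == "S_ON"]
    s_off <- se$time[se$etype == "S_OFF"]
    T_est <- stats::median(diff(sort(s_on)))
    knots <- rbind(
      data.frame(tt = s_on, vv = 25),
      data.frame(tt = s_off, vv = -25),
      # trailing half-cycle rise so the roll rhythm (and with it the final
      # cycle anchor) does not freeze at the last rendered release
      data.frame(tt = max(s_off) + 0.45 * T_est, vv = 25)
    )
    knots <- knots[order(knots$tt), ]
    pc <- piecewise_cosine(t, knots$tt, knots$vv)
    gyr_roll <- pc$deriv + spec$gyro_bias + noise(spec$noise_gyro_sd)
    acc_vert <- numeric(nsamp)
    split <- stats::runif(length(s_on)) < spec$p_two_wheel
    amp1 <- stats::runif(length(s_on), 5, 10)
    amp1[!split] <- stats::runif(sum(!split), 7, 10)
    gap <- stats::runif(length(s_on), 0.010, max(0.011, spec$two_wheel_gap_s))
    amp2 <- stats::runif(length(s_on), 5, 10)
    acc_vert <- add_bumps(acc_vert, t, s_on, amp1, 0.008)
    if (any(split)) {
      acc_vert <- add_bumps(acc_vert, t, (s_on + gap)[split], amp2[split], 0.008)
    }
    acc_vert <- add_bumps(acc_vert, t, s_off, -stats::runif(length(s_off), 7, 10), 0.008)
    acc_vert <- acc_vert + noise(spec$noise_acc_sd)
    acc <- data.frame(x = noise(spec$noise_acc_sd), y = noise(spec$noise_acc_sd), z = acc_vert)
    gyr <- data.frame(
      x = gyr_roll,
      y = spec$gyro_bias + noise(spec$noise_gyro_sd),
      z = spec$gyro_bias + noise(spec$noise_gyro_sd)
    )
    out[[paste0("ski_", side)]] <- imu_recording(
      acc, gyr, fs = spec$fs_imu, location = paste0("ski_", side),
      axis_map = am, t0 = t[1] + spec$imu_offset_s
    )
  }
  out
}

#' Simulate a complete synthetic trial
#'
#' Schedules ground-truth events, then renders the marker tracks and the four
#' IMU streams, using child seeds derived deterministically from `spec$seed`
#' (one per stage) so each stage is independently reproducible.
#'
#' @param spec A [trial_spec()].
#' @return A list of class `ski_trial` with elements `spec`, `ground_truth`,
#'   `markers` (list of [marker_track()]) and `imu` (list of [imu_recording()]).
#' @examples
#' tr <- simulate_trial(trial_spec("G3", n_cycles = 6, seed = 7))
#' names(tr$imu)
#' @export
simulate_trial <- function(spec) {
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  gt <- schedule_events(spec, seed = seeds[1])
  markers <- render_marker_tracks(gt, spec, seed = seeds[2])
  imu <- render_imu_streams(gt, spec, seed = seeds[3])
  structure(list(spec = spec, ground_truth = gt, markers = markers, imu = imu),
    class = "ski_trial"
  )
}

#' Specifications for a multi-trial validation batch
#'
#' @param n_per_tech Trials per sub-technique (G2, G3, G4).
#' @param n_cycles Cycles per trial.
#' @param seed Root seed; per-trial seeds are drawn deterministically from it.
#' @param ... Further arguments passed to every [trial_spec()].
#' @return List of [trial_spec()]s of length `3 * n_per_tech`.
#' @export
batch_specs <- function(n_per_tech = 10L, n_cycles = 50L, seed = 42L, ...) {
  set.seed(seed)
  techs <- rep(c("G2", "G3", "G4"), each = n_per_tech)
  seeds <- sample.int(.Machine$integer.max - 1L, length(techs))
  purrr::map2(techs, seeds, function(tech, s) {
    trial_spec(subtech = tech, n_cycles = n_cycles, seed = s, ...)
  })
}
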