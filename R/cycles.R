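#' Define skiing cycles from left-ski initial contacts
#'
#' A skiing cycle starts when the left ski hits the ground and ends at the
#' next left-ski initial contact (half-open interval, so each event belongs
#' to exactly one cycle); the last initial contact opens no cycle.
#'
#' @param events An event tibble ([event_series()] or compatible) containing
#'   at least two left-ski `S_ON` events.
#' @return A tibble with columns `cycle_id`, `t_start`, `t_end`.
#' @examples
#' ev <- tibble::tibble(
#'   etype = "S_ON", side = "left", time = c(1.0, 2.2, 3.4), source = "reference"
#' )
#' define_cycles(ev)
#' @export
define_cycles <- function(events) {
  on <- sort(events$time[events$etype == "S_ON" & events$side == "left"])
  if (length(on) < 2L) {
    rlang::abort(
      sprintf("need at least 2 left-ski S_ON events to define cycles, got %d", length(on)),
      class = "skatephase_error_no_cycles"
    )
  }
  tibble::tibble(
    cycle_id = seq_len(length(on) - 1L),
    t_start = on[-length(on)],
    t_end = on[-1]
  )
}

# optimal non-crossing pairing between two sorted time vectors with pair
# distance capped at `window`; minimises total |difference|
pair_times <- function(left, right, window) {
  n <- length(left); m <- length(right)
  if (n == 0L || m == 0L) return(tibble::tibble(i = integer(0), j = integer(0)))
  INF <- 1e18
  cost <- matrix(0, n + 1L, m + 1L)
  take <- matrix(FALSE, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      skip <- min(cost[i, j + 1L], cost[i + 1L, j])
      d <- abs(left[i] - right[j])
      pair <- if (d <= window) cost[i, j] + d - 1 else INF  # -1 rewards pairing
      if (pair < skip) {
        cost[i + 1L, j + 1L] <- pair
        take[i + 1L, j + 1L] <- TRUE
      } else {
        cost[i + 1L, j + 1L] <- skip
      }
    }
  }
  pi <- integer(0); pj <- integer(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (take[i + 1L, j + 1L]) {
      pi <- c(i, pi); pj <- c(j, pj)
      i <- i - 1L; j <- j - 1L
    } else if (cost[i, j + 1L] <= cost[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  tibble::tibble(i = pi, j = pj)
}

#' Merge left and right pole events into one poling sequence
#'
#' Left/right pole events of the same type occurring within `sync_window_s`
#' of each other stem from one double-poling action and merge into a single
#' event at their mean time (side `"merged"`); unpaired events pass through
#' unchanged. Pairing maximises the number of within-window pairs and, among
#' those, minimises the total time difference.
#'
#' @param events An event tibble containing pole events of both sides (ski
#'   events, if present, are passed through untouched).
#' @param sync_window_s Maximum left-right asynchrony to merge (default 0.12 s).
#' @return An event tibble sorted by time, with paired pole events replaced
#'   by merged ones.
#' @examples
#' ev <- tibble::tibble(
#'   etype = "P_ON", side = c("left", "right"), time = c(5.00, 5.04),
#'   source = "imu"
#' )
#' merge_pole_sides(ev)$time # 5.02
#' @export
merge_pole_sides <- function(events, sync_window_s = 0.12) {
  ev <- tibble::as_tibble(events)
  is_pole <- ev$etype %in% c("P_ON", "P_OFF")
  keep <- ev[!is_pole, , drop = FALSE]
  merged <- list()
  for (et in c("P_ON", "P_OFF")) {
    lt <- sort(ev$time[is_pole & ev$etype == et & ev$side == "left"])
    rt <- sort(ev$time[is_pole & ev$etype == et & ev$side == "right"])
    pr <- pair_times(lt, rt, sync_window_s)
    rows <- tibble::tibble(
      etype = et,
      side = "merged",
      time = (lt[pr$i] + rt[pr$j]) / 2,
      source = if (nrow(ev)) ev$source[1] else character(0)
    )
    solo_l <- lt[setdiff(seq_along(lt), pr$i)]
    solo_r <- rt[setdiff(seq_along(rt), pr$j)]
    if (length(solo_l) + length(solo_r)) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        etype = et,
        side = c(rep("left", length(solo_l)), rep("right", length(solo_r))),
        time = c(solo_l, solo_r),
        source = ev$source[1]
      ))
    }
    merged[[et]] <- rows
  }
  out <- dplyr::bind_rows(keep[, c("etype", "side", "time", "source")],
                          dplyr::bind_rows(merged))
  dplyr::arrange(out, .data$time)
}

next_after <- function(times, t) {
  cand <- times[times > t]
  if (length(cand)) cand[1] else NA_real_
}
last_before <- function(times, t) {
  cand <- times[times < t]
  if (length(cand)) cand[length(cand)] else NA_real_
}

#' Compute inner-cycle temporal parameters
#'
#' For each cycle: per-side ski contact time `S_CT` (final minus initial
#' contact), ski swing time `S_SW` (next initial contact minus final
#' contact), cycle time `S_CY`, merged-pole contact and swing times `P_CT`
#' and `P_SW` (averaged over the cycle's poling actions when the technique
#' poles twice per cycle), the pole-ski plant delay `delay_Pon_Son` (absolute
#' value of the shortest time difference between a pole plant and a ski plant
#' in the cycle) and the release delay `delay_Soff_Poff` (pole release minus
#' nearest preceding ski release; positive when the pole leaves the ground
#' after the ski). Phases whose constituent events are missing are `NA`,
#' never imputed.
#'
#' Pole plants are attributed to cycles through their nearest ski plant
#' (rather than by raw interval membership): the techniques pole in fixed
#' relation to the leg pushes, and a plant nominally synchronous with the
#' cycle-opening ski plant would otherwise flicker between neighbouring
#' cycles under timing jitter.
#'
#' @param cycles Cycle table from [define_cycles()].
#' @param ski_events Event tibble with per-side ski events.
#' @param pole_events Event tibble with merged pole events (see
#'   [merge_pole_sides()]).
#' @return A tibble with one row per cycle: `cycle_id`, `t_start`, `t_end`,
#'   `S_CY`, `S_CT_left`, `S_SW_left`, `S_CT_right`, `S_SW_right`, `P_CT`,
#'   `P_SW`, `delay_Pon_Son`, `delay_Soff_Poff`, `n_pole_plants`.
#' @export
compute_phases <- function(cycles, ski_events, pole_events) {
  s_on <- list(
    left = sort(ski_events$time[ski_events$etype == "S_ON" & ski_events$side == "left"]),
    right = sort(ski_events$time[ski_events$etype == "S_ON" & ski_events$side == "right"])
  )
  s_off <- list(
    left = sort(ski_events$time[ski_events$etype == "S_OFF" & ski_events$side == "left"]),
    right = sort(ski_events$time[ski_events$etype == "S_OFF" & ski_events$side == "right"])
  )
  p_on <- sort(pole_events$time[pole_events$etype == "P_ON"])
  p_off <- sort(pole_events$time[pole_events$etype == "P_OFF"])

  # ski pushes with cycle ownership: the left plant opens its cycle; other
  # plants belong to the enclosing [t_start, t_end) interval
  pushes <- tibble::tibble(time = c(s_on$left, s_on$right))
  pushes$cycle <- vapply(pushes$time, function(tt) {
    hit <- which(abs(cycles$t_start - tt) < 1e-9)
    if (length(hit)) return(cycles$cycle_id[hit[1]])
    hit <- which(cycles$t_start <= tt & tt < cycles$t_end)
    if (length(hit)) cycles$cycle_id[hit[1]] else NA_integer_
  }, integer(1))
  # plants attach to their nearest push over ALL pushes (also those outside
  # the cycle table, whose plants are then dropped), capped at half a cycle
  max_gap <- stats::median(cycles$t_end - cycles$t_start) / 2
  plant_cycle <- plant_gap <- rep(NA_real_, length(p_on))
  if (nrow(pushes)) {
    for (i in seq_along(p_on)) {
      j <- which.min(abs(pushes$time - p_on[i]))
      if (abs(pushes$time[j] - p_on[i]) <= max_gap) {
        plant_cycle[i] <- pushes$cycle[j]
        plant_gap[i] <- abs(pushes$time[j] - p_on[i])
      }
    }
  }

  one <- function(k) {
    t0 <- cycles$t_start[k]; t1 <- cycles$t_end[k]
    res <- list(cycle_id = cycles$cycle_id[k], t_start = t0, t_end = t1, S_CY = t1 - t0)
    for (side in c("left", "right")) {
      on_k <- if (side == "left") t0 else {
        v <- s_on[[side]][s_on[[side]] >= t0 & s_on[[side]] < t1]
        if (length(v)) v[1] else NA_real_
      }
      off_k <- if (is.na(on_k)) NA_real_ else next_after(s_off[[side]], on_k)
      nxt <- if (is.na(off_k)) NA_real_ else next_after(s_on[[side]], off_k)
      res[[paste0("S_CT_", side)]] <- off_k - on_k
      res[[paste0("S_SW_", side)]] <- nxt - off_k
    }
    mine <- which(plant_cycle == cycles$cycle_id[k])
    plants <- p_on[mine]
    cts <- sws <- numeric(0)
    for (p in plants) {
      po <- next_after(p_off, p)
      if (!is.na(po)) {
        cts <- c(cts, po - p)
        np <- next_after(p_on, po)
        if (!is.na(np)) sws <- c(sws, np - po)
      }
    }
    res$P_CT <- if (length(cts)) mean(cts) else NA_real_
    res$P_SW <- if (length(sws)) mean(sws) else NA_real_
    res$delay_Pon_Son <- if (length(mine)) min(plant_gap[mine]) else NA_real_
    offs_in <- p_off[p_off >= t0 & p_off < t1]
    res$delay_Soff_Poff <- if (length(offs_in)) {
      so <- last_before(c(s_off$left, s_off$right), offs_in[1])
      offs_in[1] - so
    } else NA_real_
    res$n_pole_plants <- length(plants)
    tibble::as_tibble(res)
  }
  purrr::map_dfr(seq_len(nrow(cycles)), one)
}

#' Assemble cycles, phases and plant counts from an event series
#'
#' Convenience wrapper chaining [define_cycles()], [merge_pole_sides()] and
#' [compute_phases()].
#'
#' @param events An event tibble with per-side ski and pole events.
#' @param sync_window_s Pole-merge window, see [merge_pole_sides()].
#' @return The [compute_phases()] tibble.
#' @export
cycle_phases <- function(events, sync_window_s = 0.12) {
  cycles <- define_cycles(events)
  merged <- merge_pole_sides(events, sync_window_s)
  compute_phases(cycles, events, merged[merged$etype %in% c("P_ON", "P_OFF"), ])
}
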