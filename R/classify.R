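#' Decision-tree configuration for sub-technique classification
#'
#' @param sync_threshold_s Pole-ski synchrony threshold separating the
#'   synchronous (G4) from the offset (G2) single-poling techniques
#'   (default 0.10 s).
#' @param min_events_per_cycle Minimum number of events a cycle must contain
#'   to be classifiable (default 2).
#' @return A list of class `tree_config`.
#' @export
tree_config <- function(sync_threshold_s = 0.10, min_events_per_cycle = 2L) {
  if (sync_threshold_s <= 0) abort_invalid("`sync_threshold_s` must be > 0")
  structure(list(
    sync_threshold_s = sync_threshold_s,
    min_events_per_cycle = as.integer(min_events_per_cycle)
  ), class = "tree_config")
}

#' Classify skating sub-technique per cycle
#'
#' Decision tree over the cycle's temporal events: two merged pole plants in
#' the cycle means the skier poles with every leg push (G3); a single plant
#' is the symmetric, ski-synchronous technique (G4) when the pole-ski plant
#' delay is at most `sync_threshold_s`, and the offset technique (G2)
#' otherwise; cycles with no plant, or with the required events missing, fall
#' into the undetermined sink category (`NA`).
#'
#' @param records Phase table from [compute_phases()] / [cycle_phases()]
#'   (needs columns `n_pole_plants` and `delay_Pon_Son`).
#' @param cfg A [tree_config()].
#' @return `records` with a `subtech` character column (`"G2"`, `"G3"`,
#'   `"G4"` or `NA` for undetermined).
#' @export
classify_cycles <- function(records, cfg = tree_config()) {
  stopifnot(all(c("n_pole_plants", "delay_Pon_Son") %in% names(records)))
  lab <- rep(NA_character_, nrow(records))
  np <- records$n_pole_plants
  d <- records$delay_Pon_Son
  lab[np >= 2L] <- "G3"
  one <- which(np == 1L & !is.na(d))
  lab[one] <- ifelse(d[one] <= cfg$sync_threshold_s, "G4", "G2")
  records$subtech <- lab
  records
}

#' Classify a trial and score against ground truth
#'
#' Produces the per-cycle label sequence, the trial-level majority label
#' (ties and an undetermined majority give `NA`) and, when ground-truth
#' labels are supplied, the fraction of cycles labelled correctly. Cycles are
#' aligned to ground-truth cycles by nearest start time (within half the
#' median cycle duration); ground-truth cycles without an aligned detected
#' cycle count as incorrect.
#'
#' @param records Classified phase table from [classify_cycles()].
#' @param truth Optional ground-truth cycle table with columns `t_start` and
#'   `subtech` (e.g. `gt$cycles` from [schedule_events()]).
#' @param cfg A [tree_config()].
#' @return A list of class `trial_classification`: `labels` (tibble with
#'   `cycle_id`, `t_start`, `subtech`, and `ground_truth`/`correct` when
#'   truth is given), `majority`, and `accuracy`/`confusion` when truth is
#'   given.
#' @export
classify_trial <- function(records, truth = NULL, cfg = tree_config()) {
  if (!"subtech" %in% names(records)) records <- classify_cycles(records, cfg)
  if (nrow(records) < 1L) abort_invalid("need at least one cycle to classify")
  labels <- records[, c("cycle_id", "t_start", "subtech")]
  tab <- table(labels$subtech, useNA = "no")
  majority <- if (length(tab) == 0L) NA_character_ else {
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else NA_character_
  }
  out <- list(labels = labels, majority = majority)
  if (!is.null(truth)) {
    half_cycle <- stats::median(diff(sort(truth$t_start))) / 2
    j <- vapply(truth$t_start, function(t0) {
      d <- abs(labels$t_start - t0)
      if (length(d) && min(d) <= half_cycle) which.min(d) else NA_integer_
    }, integer(1))
    aligned <- tibble::tibble(
      t_start = truth$t_start,
      ground_truth = truth$subtech,
      subtech = ifelse(is.na(j), NA_character_, labels$subtech[j])
    )
    aligned$correct <- !is.na(aligned$subtech) & aligned$subtech == aligned$ground_truth
    out$aligned <- aligned
    out$accuracy <- mean(aligned$correct)
    out$confusion <- table(
      truth = aligned$ground_truth,
      detected = ifelse(is.na(aligned$subtech), "NaN", aligned$subtech)
    )
  }
  structure(out, class = "trial_classification")
}
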