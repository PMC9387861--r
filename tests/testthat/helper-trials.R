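# Shared synthetic trials, simulated once per test run and cached.

.trial_cache <- new.env(parent = emptyenv())

noiseless_spec <- function(subtech = "G3", n_cycles = 8L, seed = 3L, ...) {
  args <- list(
    subtech = subtech, n_cycles = n_cycles, seed = seed,
    noise_acc_sd = 0, noise_gyro_sd = 0, jitter_sd_s = 0,
    gyro_bias = 0, p_two_wheel = 0, marker_noise_sd_m = 0
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(trial_spec, args)
}

cached_trial <- function(key, spec) {
  if (is.null(.trial_cache[[key]])) .trial_cache[[key]] <- simulate_trial(spec)
  .trial_cache[[key]]
}

clean_trial <- function(subtech = "G3") {
  cached_trial(paste0("clean_", subtech), noiseless_spec(subtech))
}

noisy_trial <- function(subtech = "G3", seed = 11L) {
  cached_trial(
    paste0("noisy_", subtech, "_", seed),
    trial_spec(subtech, n_cycles = 12L, seed = seed)
  )
}

gt_events_of <- function(trial) {
  trial$ground_truth$events[!trial$ground_truth$events$pad, ]
}

# match per (etype, side) and return error vector in seconds
recovery_errors <- function(gt, detected, etype, side, max_gap = 0.55) {
  g <- gt[gt$etype == etype & gt$side == side, ]
  d <- detected[detected$etype == etype & detected$side == side, ]
  match_events(g, d, max_gap)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
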