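#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang %||% .data
NULL

#' Tidy a Kruskal-Wallis result
#'
#' @param x A `skate_kw` from [kruskal_wallis()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `n` and
#'   `method`.
#' @export
tidy.skate_kw <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$method <- "Kruskal-Wallis rank sum test"
  out
}

#' Tidy a DSCF post-hoc table
#'
#' @param x A `skate_dscf` from [dscf_posthoc()].
#' @param ... Unused.
#' @return A tibble with one row per group pair.
#' @export
tidy.skate_dscf <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$contrast <- paste(out$group1, "-", out$group2)
  out
}

#' One-row summary of a validation study
#'
#' @param x A `skate_validation` from [run_validation_study()].
#' @param ... Unused.
#' @return A one-row tibble: overall event attribution percentage, worst
#'   inner-cycle `sigma_mu` (ms and % of phase duration), per-cycle
#'   classification accuracy, and the batch dimensions.
#' @export
glance.skate_validation <- function(x, ...) {
  tibble::tibble(
    detection_pct = x$headline$detection_pct,
    worst_sigma_mu_ms = x$headline$worst_sigma_mu_ms,
    worst_sigma_mu_rel_pct = x$headline$worst_sigma_mu_rel_pct,
    classification_pct = x$headline$classification_pct,
    n_trials = 3L * x$n_per_tech, n_cycles = x$n_cycles, seed = x$seed
  )
}

#' Tidy the phase-level validation statistics
#'
#' @param x A `skate_validation`.
#' @param unit `"ms"` for absolute or `"pct"` for relative statistics.
#' @param ... Unused.
#' @return Tibble of inter-trial `b_mu`, `b_sigma`, `sigma_mu`,
#'   `sigma_sigma` per phase and gear.
#' @export
tidy.skate_validation <- function(x, unit = c("ms", "pct"), ...) {
  unit <- rlang::arg_match(unit)
  if (unit == "ms") x$phase_stats else x$phase_stats_rel
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf(
    "<trial_spec> %s, %d cycles @ %s Hz cycle rate, seed %d\n",
    x$subtech, x$n_cycles,
    ifelse(is.null(x$cycle_rate), "per-technique default", format(x$cycle_rate)),
    x$seed
  ))
  cat(sprintf(
    "  fs: imu %g / ref %g Hz; noise: acc %g m/s^2, gyro %g deg/s, bias %g deg/s\n",
    x$fs_imu, x$fs_ref, x$noise_acc_sd, x$noise_gyro_sd, x$gyro_bias
  ))
  cat(sprintf(
    "  event jitter %g ms, clock offset %g ms, two-wheel split p = %g\n",
    1000 * x$jitter_sd_s, 1000 * x$imu_offset_s, x$p_two_wheel
  ))
  invisible(x)
}

#' @export
print.ski_trial <- function(x, ...) {
  ev <- x$ground_truth$events
  cat(sprintf(
    "<ski_trial> %s: %d cycles, %d ground-truth events, %d IMU streams, %d marker tracks\n",
    x$spec$subtech, nrow(x$ground_truth$cycles), sum(!ev$pad),
    length(x$imu), length(x$markers)
  ))
  invisible(x)
}

#' @export
print.skate_validation <- function(x, ...) {
  h <- x$headline
  cat(sprintf(
    "<skate_validation> %d trials x %d cycles (seed %d)\n",
    3L * x$n_per_tech, x$n_cycles, x$seed
  ))
  cat(sprintf("  events attributed:        %.1f %%\n", h$detection_pct))
  cat(sprintf("  worst phase sigma_mu:     %.0f ms (%.1f %% of phase duration)\n",
              h$worst_sigma_mu_ms, h$worst_sigma_mu_rel_pct))
  cat(sprintf("  sub-technique per cycle:  %.1f %% correct\n", h$classification_pct))
  invisible(x)
}

#' @export
print.trial_classification <- function(x, ...) {
  cat(sprintf("<trial_classification> %d cycles, majority %s",
              nrow(x$labels), x$majority %||% "NaN"))
  if (!is.null(x$accuracy)) cat(sprintf(", accuracy %.1f %%", 100 * x$accuracy))
  cat("\n")
  invisible(x)
}
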