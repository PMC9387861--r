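#' Plot a synthetic trial's key channels with its ground-truth events
#'
#' Shows, for a time window, the channels each detector keys on (wrist yaw
#' acceleration and integrated yaw angle; ski vertical acceleration and roll
#' rate, left side) with ground-truth contact events overlaid, the standard
#' visual check that rendered signatures sit where the events are.
#'
#' @param object A `ski_trial` from [simulate_trial()].
#' @param t_lim Time window in seconds (default: first 5 cycles).
#' @param cfg A [detection_config()] used for the derived angle channel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ski_trial <- function(object, t_lim = NULL, cfg = detection_config(), ...) {
  gtc <- object$ground_truth$cycles
  if (is.null(t_lim)) t_lim <- c(gtc$t_start[1], gtc$t_end[min(5L, nrow(gtc))])
  chans <- list(
    `wrist L: yaw acc (m/s^2)` = imu_channel(object$imu$wrist_left, "acc", "yaw"),
    `wrist L: yaw angle (deg)` = wrist_yaw_angle(object$imu$wrist_left, cfg),
    `ski L: vertical acc (m/s^2)` = imu_channel(object$imu$ski_left, "acc", "yaw"),
    `ski L: roll rate (deg/s)` = imu_channel(object$imu$ski_left, "gyro", "roll")
  )
  df <- purrr::imap_dfr(chans, function(s, nm) {
    tibble::tibble(channel = nm, time = s$time, value = s$value)
  })
  df <- df[df$time >= t_lim[1] & df$time <= t_lim[2], ]
  ev <- object$ground_truth$events
  ev <- ev[!ev$pad & ev$side == "left" & ev$time >= t_lim[1] & ev$time <= t_lim[2], ]
  ev$channel_family <- ifelse(grepl("^P", ev$etype), "wrist", "ski")
  evdf <- tidyr::crossing(ev, channel = names(chans))
  evdf <- evdf[substr(evdf$channel, 1, 3) == substr(evdf$channel_family, 1, 3) |
                 (evdf$channel_family == "wrist" & grepl("^wrist", evdf$channel)) |
                 (evdf$channel_family == "ski" & grepl("^ski", evdf$channel)), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(
      data = evdf,
      ggplot2::aes(xintercept = .data$time, colour = .data$etype),
      linetype = "dashed", alpha = 0.7
    ) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "event") +
    ggplot2::theme_minimal()
}

#' Plot inter-trial phase precision of a validation study
#'
#' Bar chart of the inter-trial median precision (`sigma_mu`) per inner-cycle
#' phase and sub-technique, the study's central agreement figure.
#'
#' @param object A `skate_validation` from [run_validation_study()].
#' @param unit `"ms"` (absolute) or `"pct"` (relative to phase duration).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skate_validation <- function(object, unit = c("ms", "pct"), ...) {
  unit <- rlang::arg_match(unit)
  df <- if (unit == "ms") object$phase_stats else object$phase_stats_rel
  df <- df[df$phase %in% phase_names(), ]
  df$phase <- factor(df$phase, levels = phase_names())
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$sigma_mu, fill = .data$gear)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, fill = NULL,
      y = if (unit == "ms") "precision sigma_mu (ms)" else "precision sigma_mu (% of phase)"
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of per-trial event bias by sub-technique
#'
#' @param study A `skate_validation`.
#' @return A ggplot object.
#' @export
plot_event_bias <- function(study) {
  df <- study$per_trial_events
  df$etype <- factor(df$etype, levels = names(event_labels()), labels = event_labels())
  ggplot2::ggplot(df, ggplot2::aes(.data$subtech, .data$bias_ms, fill = .data$subtech)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~etype) +
    ggplot2::labs(x = NULL, y = "intra-trial bias (ms)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
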