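#' Match detected events to reference events
#'
#' Attributes each detected (IMU) event to the closest reference event:
#' candidate pairs within `max_gap_s` are taken greedily in order of
#' increasing absolute error, which realises the mutual-closeness rule (an
#' event proposing an already-better-matched partner loses and re-proposes
#' its next candidate). Reference events left unpaired are missed events for
#' the IMU method; detected events left unpaired are spurious.
#'
#' @param ref,imu Event tibbles (or bare numeric time vectors), typically
#'   restricted to one (etype, side).
#' @param max_gap_s Largest admissible |error|; the conventional choice is
#'   half the median cycle duration, beyond which an attribution would
#'   necessarily cross into another cycle.
#' @return A list of class `event_match`: `pairs` (tibble `ref_time`,
#'   `imu_time`, `error_s` with `error_s = ref_time - imu_time`, so positive
#'   errors mean the event was detected earlier on the IMU), `missed_ref`,
#'   `spurious_imu` (numeric vectors).
#' @examples
#' m <- match_events(c(1, 2), c(1.02, 1.98), max_gap_s = 0.5)
#' m$pairs$error_s # -0.02, +0.02
#' @export
match_events <- function(ref, imu, max_gap_s) {
  rt <- sort(if (is.data.frame(ref)) ref$time else as.numeric(ref))
  it <- sort(if (is.data.frame(imu)) imu$time else as.numeric(imu))
  pairs <- tibble::tibble(ref_time = numeric(0), imu_time = numeric(0), error_s = numeric(0))
  if (length(rt) && length(it)) {
    cand <- expand.grid(i = seq_along(rt), j = seq_along(it))
    cand$d <- abs(rt[cand$i] - it[cand$j])
    cand <- cand[cand$d <= max_gap_s, , drop = FALSE]
    cand <- cand[order(cand$d), , drop = FALSE]
    used_r <- logical(length(rt)); used_i <- logical(length(it))
    ki <- kj <- integer(0)
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!used_r[i] && !used_i[j]) {
        used_r[i] <- TRUE; used_i[j] <- TRUE
        ki <- c(ki, i); kj <- c(kj, j)
      }
    }
    ord <- order(rt[ki])
    ki <- ki[ord]; kj <- kj[ord]
    pairs <- tibble::tibble(
      ref_time = rt[ki], imu_time = it[kj], error_s = rt[ki] - it[kj]
    )
  }
  structure(list(
    pairs = pairs,
    missed_ref = setdiff(rt, pairs$ref_time),
    spurious_imu = setdiff(it, pairs$imu_time)
  ), class = "event_match")
}

#' Intra-trial bias and precision of timing errors
#'
#' Bias is the intra-trial mean error and precision the intra-trial sample
#' standard deviation (n - 1), both in milliseconds, keeping the convention
#' that positive errors mean earlier detection on the IMU. Trials with fewer
#' than two errors yield an undefined-statistic row (`NA`) and are excluded
#' from pooling.
#'
#' @param errors_s Numeric vector of per-event (or per-phase) errors in
#'   seconds.
#' @return A one-row tibble: `bias_ms`, `precision_ms`, `n`.
#' @examples
#' intra_trial_stats(c(-0.010, -0.020, -0.030)) # bias -20 ms, precision 10 ms
#' @export
intra_trial_stats <- function(errors_s) {
  errors_s <- errors_s[is.finite(errors_s)]
  if (length(errors_s) < 2L) {
    return(tibble::tibble(bias_ms = NA_real_, precision_ms = NA_real_, n = length(errors_s)))
  }
  tibble::tibble(
    bias_ms = mean(errors_s) * 1000,
    precision_ms = stats::sd(errors_s) * 1000,
    n = length(errors_s)
  )
}

iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Inter-trial summary of bias and precision
#'
#' The across-trial median and interquartile range (linear-interpolation,
#' type-7 quantiles) of the intra-trial bias and precision: `b_mu` (median
#' bias), `b_sigma` (IQR of the bias), `sigma_mu` (median precision),
#' `sigma_sigma` (IQR of the precision). Medians/IQRs are used because the
#' intra-trial statistics are typically not normally distributed across
#' trials.
#'
#' @param per_trial Tibble with columns `bias_ms` and `precision_ms`, one row
#'   per trial (`NA` rows are dropped).
#' @return A one-row tibble: `b_mu`, `b_sigma`, `sigma_mu`, `sigma_sigma`,
#'   `n_trials`.
#' @export
inter_trial_stats <- function(per_trial) {
  ok <- is.finite(per_trial$bias_ms) & is.finite(per_trial$precision_ms)
  b <- per_trial$bias_ms[ok]
  p <- per_trial$precision_ms[ok]
  if (!length(b)) {
    return(tibble::tibble(b_mu = NA_real_, b_sigma = NA_real_,
                          sigma_mu = NA_real_, sigma_sigma = NA_real_, n_trials = 0L))
  }
  tibble::tibble(
    b_mu = stats::median(b), b_sigma = iqr7(b),
    sigma_mu = stats::median(p), sigma_sigma = iqr7(p),
    n_trials = length(b)
  )
}

#' Relative phase errors in percent of the reference phase duration
#'
#' @param errors_s Per-occurrence phase errors (s).
#' @param durations_s Matching reference phase durations (s); occurrences
#'   with non-positive or missing duration are excluded.
#' @return Numeric vector of percentages (`100 * error / duration`).
#' @export
relative_phase_errors <- function(errors_s, durations_s) {
  ok <- is.finite(errors_s) & is.finite(durations_s) & durations_s > 0
  100 * errors_s[ok] / durations_s[ok]
}

#' Event detection rate
#'
#' @param n_ref Number of reference (or ground-truth) events.
#' @param n_matched Number of those attributed to a detected event
#'   (`n_matched <= n_ref`).
#' @return Percentage detected; `NA` when `n_ref` is 0.
#' @export
detection_rate <- function(n_ref, n_matched) {
  stopifnot(all(n_matched <= n_ref))
  ifelse(n_ref > 0, 100 * n_matched / n_ref, NA_real_)
}

#' Kruskal-Wallis rank test across groups
#'
#' Non-parametric one-way comparison of two or more groups, with the usual
#' tie correction and the chi-square approximation on k - 1 degrees of
#' freedom. With all values identical the statistic is 0 and p = 1.
#'
#' @param data Data frame with a value column and a grouping column, or a
#'   list of numeric vectors.
#' @param value,group Column names (tidy-eval) when `data` is a data frame.
#' @return A one-row tibble of class `skate_kw`: `statistic` (H), `df`,
#'   `p_value`, `n`.
#' @examples
#' kruskal_wallis(list(g1 = 1:3, g2 = 4:6, g3 = 7:9)) # H = 7.2, df = 2
#' @export
kruskal_wallis <- function(data, value = NULL, group = NULL) {
  parts <- as_group_list(data, {{ value }}, {{ group }})
  x <- unlist(parts, use.names = FALSE)
  g <- factor(rep(names(parts), lengths(parts)))
  if (length(x) < 3L) abort_insufficient("Kruskal-Wallis needs a total n of at least 3")
  if (max(x) == min(x)) {
    res <- tibble::tibble(statistic = 0, df = length(parts) - 1L, p_value = 1, n = length(x))
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- tibble::tibble(
      statistic = unname(kt$statistic), df = unname(kt$parameter),
      p_value = kt$p.value, n = length(x)
    )
  }
  class(res) <- c("skate_kw", class(res))
  res
}

as_group_list <- function(data, value, group) {
  if (is.data.frame(data)) {
    v <- dplyr::pull(data, {{ value }})
    g <- dplyr::pull(data, {{ group }})
    split(v, g, drop = TRUE)
  } else if (is.list(data)) {
    if (is.null(names(data))) names(data) <- paste0("g", seq_along(data))
    lapply(data, as.numeric)
  } else {
    abort_invalid("`data` must be a data frame or a list of numeric vectors")
  }
}

#' Dwass-Steel-Critchlow-Fligner all-pairs post-hoc test
#'
#' For each pair of groups, the two groups are re-ranked alone and compared
#' with a tie-corrected Wilcoxon rank-sum statistic, standardised and
#' referred to the Studentized range distribution with `k` groups (infinite
#' degrees of freedom); p-values are two-sided. The customary follow-up to a
#' significant Kruskal-Wallis omnibus test. Pairs in which both groups are
#' completely tied give statistic 0 and p = 1; empty groups are skipped.
#'
#' @inheritParams kruskal_wallis
#' @return A tibble of class `skate_dscf` with one row per pair: `group1`,
#'   `group2`, `n1`, `n2`, `statistic` (W), `p_value`.
#' @export
dscf_posthoc <- function(data, value = NULL, group = NULL) {
  parts <- as_group_list(data, {{ value }}, {{ group }})
  parts <- parts[lengths(parts) > 0L]
  k <- length(parts)
  if (k < 2L) abort_insufficient("need at least two non-empty groups")
  combs <- utils::combn(names(parts), 2L)
  rows <- apply(combs, 2L, function(nm) {
    x <- parts[[nm[1]]]; y <- parts[[nm[2]]]
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    r <- rank(c(x, y))
    Rj <- sum(r[seq.int(n1 + 1L, N)])
    expect <- n2 * (N + 1) / 2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / ((N) * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    W <- if (v <= 0) 0 else sqrt(2) * (Rj - expect) / sqrt(v)
    tibble::tibble(
      group1 = nm[1], group2 = nm[2], n1 = n1, n2 = n2,
      statistic = W,
      p_value = stats::ptukey(abs(W), nmeans = k, df = Inf, lower.tail = FALSE)
    )
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("skate_dscf", class(res))
  res
}
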