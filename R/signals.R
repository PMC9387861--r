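#' Construct a uniformly sampled signal
#'
#' A `uniform_signal` is a tibble with columns `time` (seconds, trial-relative)
#' and `value`, carrying the sampling rate, start time, label and units as
#' attributes. Sample `k` (1-based) has timestamp `t0 + (k - 1) / fs`.
#'
#' @param values Numeric vector of samples; must be finite and of length >= 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds. Default 0.
#' @param label Channel label, e.g. `"gyro_yaw"`.
#' @param units Unit string, e.g. `"m/s^2"`, `"deg/s"`, `"deg"`, `"m"`.
#'
#' @return A tibble of class `uniform_signal` with columns `time` and `value`.
#' @examples
#' s <- uniform_signal(sin(2 * pi * 1 * (0:255) / 256), fs = 256, units = "deg/s")
#' signal_fs(s)
#' @export
uniform_signal <- function(values, fs, t0 = 0, label = "", units = "") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort_invalid("`fs` must be a single positive number")
  }
  if (!is.numeric(values) || length(values) < 1L) {
    abort_invalid("`values` must be a numeric vector of length >= 1")
  }
  if (!all(is.finite(values))) {
    abort_invalid("`values` must be finite (non-finite samples rejected at construction)")
  }
  out <- tibble::tibble(
    time = t0 + (seq_along(values) - 1) / fs,
    value = as.numeric(values)
  )
  structure(out,
    fs = as.numeric(fs), t0 = as.numeric(t0),
    label = label, units = units,
    class = c("uniform_signal", class(out))
  )
}

#' @rdname uniform_signal
#' @param x A `uniform_signal`.
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) fs <- 1 / stats::median(diff(x$time))
  fs
}

#' @rdname uniform_signal
#' @export
signal_units <- function(x) attr(x, "units") %||% ""

# rebuild a uniform_signal from a template, replacing values/units
sig_like <- function(template, values, units = NULL, label = NULL) {
  uniform_signal(values,
    fs = signal_fs(template), t0 = template$time[1],
    label = label %||% (attr(template, "label") %||% ""),
    units = units %||% signal_units(template)
  )
}

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "skatephase_error_invalid_parameter")
}
abort_insufficient <- function(msg, class = "skatephase_error_insufficient_data", ...) {
  rlang::abort(msg, class = class, ...)
}

# steady-state single-pass IIR: past inputs/outputs seeded so a constant input
# produces its steady-state response from sample one
filter_ss <- function(b, a, x) {
  g <- sum(b) / sum(a)
  y <- signal::filter(b, a, x,
    init.x = rep(x[1], length(b) - 1),
    init.y = rep(g * x[1], length(a) - 1)
  )
  as.numeric(y)
}

#' Zero-phase Butterworth filter
#'
#' Applies an order-`order` Butterworth low- or high-pass filter
#' forward-backward (zero phase), so detected event times are not shifted by
#' the filter group delay. The stated cutoff applies per pass, giving -6 dB at
#' the cutoff for the cascade. Edges are handled by odd-reflection padding of
#' roughly three impulse-response lengths (trimmed after filtering), with
#' steady-state initial conditions, because trials start and end mid-motion.
#'
#' @param x A [uniform_signal()].
#' @param cutoff_hz Cutoff frequency in Hz; must satisfy `0 < cutoff_hz < fs/2`.
#' @param order Filter order per pass (default 2).
#' @param mode `"lowpass"` or `"highpass"`.
#'
#' @return A [uniform_signal()] with the same `t0`, `fs` and length.
#' @examples
#' s <- uniform_signal(sin(2 * pi * 0.8 * (0:2559) / 256), fs = 256)
#' hp <- butter_filter(s, 0.1, mode = "highpass")
#' @export
butter_filter <- function(x, cutoff_hz, order = 2L, mode = c("lowpass", "highpass")) {
  mode <- rlang::arg_match(mode)
  fs <- signal_fs(x)
  n <- nrow(x)
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort_invalid(sprintf(
      "`cutoff_hz` (%s) must lie strictly between 0 and the Nyquist frequency (%g Hz)",
      format(cutoff_hz), fs / 2
    ))
  }
  if (n < 3L * order + 1L) {
    abort_insufficient(sprintf(
      "series too short to filter: need at least %d samples, got %d", 3L * order + 1L, n
    ))
  }
  bf <- signal::butter(order, 2 * cutoff_hz / fs, type = if (mode == "lowpass") "low" else "high")
  v <- x$value
  # odd-reflection pad: ~3 impulse-response lengths, capped by series length
  npad <- min(n - 1L, max(3L * order, ceiling(3 * fs / cutoff_hz)))
  left <- 2 * v[1] - v[seq(npad + 1L, 2L)]
  right <- 2 * v[n] - v[seq(n - 1L, n - npad)]
  vp <- c(left, v, right)
  vp <- filter_ss(bf$b, bf$a, vp)
  vp <- rev(filter_ss(bf$b, bf$a, rev(vp)))
  sig_like(x, vp[seq(npad + 1L, npad + n)])
}

#' Cumulative trapezoidal integration of a rate signal
#'
#' Integrates a sampled rate (e.g. angular velocity in deg/s) into the
#' corresponding quantity (deg), starting at zero. Length, rate and start time
#' are preserved.
#'
#' @param x A [uniform_signal()] holding a rate.
#' @return A [uniform_signal()]; units `"deg/s"` (or `"deg.s-1"`) become `"deg"`.
#' @examples
#' r <- uniform_signal(rep(90, 256), fs = 256, units = "deg/s")
#' tail(integrate_signal(r)$value, 1) # ~90 deg after 1 s
#' @export
integrate_signal <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  v <- as.numeric(pracma::cumtrapz(x$time, x$value))
  u <- signal_units(x)
  u_out <- if (grepl("deg", u)) "deg" else if (nzchar(u)) paste0(u, ".s") else ""
  sig_like(x, v, units = u_out)
}

#' Find peaks by topographic prominence
#'
#' Returns all strict local extrema of the requested sign whose topographic
#' prominence is at least `min_prominence`. Prominence is the height of a peak
#' above the higher of its two flanking valleys, where each valley is the
#' minimum between the peak and the nearest strictly higher sample on that
#' side (bounded by the signal ends). Negative peaks are found on the negated
#' signal. Plateaus of equal-height samples collapse to their leftmost sample.
#'
#' @param x A [uniform_signal()].
#' @param min_prominence Minimum prominence (>= 0) to retain a peak.
#' @param sign `"positive"` (local maxima) or `"negative"` (local minima).
#'
#' @return A tibble of class `peak_list` with columns `index`, `time`, `value`
#'   (original signal value) and `prominence`, ordered by index; possibly empty.
#' @examples
#' s <- uniform_signal(c(0, 1, 2, 1, 0, 0.4, 0.2), fs = 1)
#' find_peaks(s, min_prominence = 1)
#' @export
find_peaks <- function(x, min_prominence = 0, sign = c("positive", "negative")) {
  sign <- rlang::arg_match(sign)
  if (!is.numeric(min_prominence) || min_prominence < 0) {
    abort_invalid("`min_prominence` must be >= 0")
  }
  v <- if (sign == "negative") -x$value else x$value
  pk <- peak_indices(v)
  prom <- peak_prominences(v, pk)
  keep <- prom >= min_prominence
  out <- tibble::tibble(
    index = pk[keep],
    time = x$time[pk[keep]],
    value = x$value[pk[keep]],
    prominence = prom[keep]
  )
  structure(out, sign = sign, class = c("peak_list", class(out)))
}

# leftmost-sample strict local maxima (plateaus collapse left; ends excluded)
peak_indices <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  run_start <- c(TRUE, diff(v) != 0)
  ridx <- which(run_start)
  rv <- v[ridx]
  m <- length(rv)
  if (m < 3L) return(integer(0))
  core <- 2:(m - 1L)
  is_pk <- rv[core] > rv[core - 1L] & rv[core] > rv[core + 1L]
  ridx[core][is_pk]
}

peak_prominences <- function(v, pk) {
  n <- length(v)
  vapply(pk, function(p) {
    h <- v[p]
    lhs <- which(v[seq_len(p - 1L)] > h)
    lstart <- if (length(lhs)) max(lhs) + 1L else 1L
    lbase <- min(v[lstart:(p - 1L)])
    rhs <- which(v[seq.int(p + 1L, n)] > h)
    rend <- if (length(rhs)) p + min(rhs) - 1L else n
    rbase <- min(v[seq.int(p + 1L, rend)])
    h - max(lbase, rbase)
  }, numeric(1))
}

#' Central-difference second derivative
#'
#' Computes `(x[k-1] - 2 x[k] + x[k+1]) * fs^2` on interior samples; the two
#' endpoint samples replicate their nearest interior value. Exact for
#' quadratics. For vertical marker positions in metres the result is in m/s^2.
#'
#' @param x A [uniform_signal()] with at least 3 samples.
#' @return A [uniform_signal()] of the same length.
#' @export
second_derivative <- function(x) {
  n <- nrow(x)
  if (n < 3L) abort_insufficient("second_derivative needs at least 3 samples")
  fs <- signal_fs(x)
  v <- x$value
  d2 <- c(NA_real_, (v[1:(n - 2L)] - 2 * v[2:(n - 1L)] + v[3:n]) * fs^2, NA_real_)
  d2[1] <- d2[2]
  d2[n] <- d2[n - 1L]
  u <- signal_units(x)
  sig_like(x, d2, units = if (u == "m") "m/s^2" else u)
}
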