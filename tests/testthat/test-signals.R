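test_that("zero-phase Butterworth rejects DC in highpass and passes it in lowpass", {
  s <- uniform_signal(rep(5, 2000), fs = 256)
  hp <- butter_filter(s, 0.1, mode = "highpass")
  expect_lt(max(abs(hp$value)), 1e-9)
  lp <- butter_filter(s, 2, mode = "lowpass")
  expect_lt(max(abs(lp$value - 5)), 1e-9)
  expect_identical(nrow(hp), nrow(s))
  expect_equal(hp$time, s$time)
})

test_that("forward-backward pass attenuates a sine at the cutoff to half amplitude", {
  fs <- 256
  t <- (0:(fs * 60 - 1)) / fs
  s <- uniform_signal(sin(2 * pi * 2 * t), fs = fs)
  lp <- butter_filter(s, 2, mode = "lowpass")
  mid <- lp$value[(10 * fs):(50 * fs)]
  amp <- (max(mid) - min(mid)) / 2
  expect_equal(amp, 0.5, tolerance = 0.02 / 0.5)
})

test_that("filtering is linear and introduces no group delay", {
  set.seed(1)
  fs <- 256
  t <- (0:2047) / fs
  x <- uniform_signal(sin(2 * pi * 1.3 * t) + 0.3 * sin(2 * pi * 4 * t), fs = fs)
  y <- uniform_signal(cos(2 * pi * 0.7 * t), fs = fs)
  mix <- uniform_signal(2 * x$value - 3 * y$value, fs = fs)
  lhs <- butter_filter(mix, 3, mode = "lowpass")$value
  rhs <- 2 * butter_filter(x, 3, mode = "lowpass")$value -
    3 * butter_filter(y, 3, mode = "lowpass")$value
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  # zero-phase: cross-correlation between band-limited input and output peaks at lag 0
  f <- butter_filter(x, 3, mode = "lowpass")$value
  lags <- -20:20
  cc <- vapply(lags, function(l) {
    idx <- 200:1800
    sum(x$value[idx] * f[idx + l])
  }, numeric(1))
  expect_identical(lags[which.max(cc)], 0L)
})

test_that("filter rejects invalid cutoffs and too-short series", {
  s <- uniform_signal(rnorm(100), fs = 100)
  expect_error(butter_filter(s, 50, mode = "lowpass"), class = "skatephase_error_invalid_parameter")
  expect_error(butter_filter(s, 0, mode = "lowpass"), class = "skatephase_error_invalid_parameter")
  short <- uniform_signal(rnorm(5), fs = 100)
  expect_error(butter_filter(short, 2, mode = "lowpass"),
    class = "skatephase_error_insufficient_data"
  )
})

test_that("trapezoidal integration matches closed forms and the analytic antiderivative", {
  fs <- 256
  z <- integrate_signal(uniform_signal(rep(0, 512), fs = fs, units = "deg/s"))
  expect_true(all(z$value == 0))
  expect_identical(signal_units(z), "deg")

  cst <- integrate_signal(uniform_signal(rep(90, fs + 1), fs = fs, units = "deg/s"))
  expect_equal(utils::tail(cst$value, 1), 90, tolerance = 90 / (2 * fs) / 90)

  A <- 1; f <- 2
  t <- (0:(4 * fs)) / fs
  rate <- uniform_signal(A * sin(2 * pi * f * t), fs = fs, units = "deg/s")
  ang <- integrate_signal(rate)
  truth <- A / (2 * pi * f) * (1 - cos(2 * pi * f * t))
  expect_lt(max(abs(ang$value - truth)), 1e-3)
})

test_that("find_peaks matches the exhaustive prominence oracle on a random walk", {
  set.seed(42)
  v <- cumsum(rnorm(200))
  s <- uniform_signal(v, fs = 100)
  for (sgn in c("positive", "negative")) {
    got <- find_peaks(s, min_prominence = 0.5, sign = sgn)
    want <- oracle_peaks(v, 0.5, sgn)
    expect_identical(got$index, want$index)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
  }
})

test_that("find_peaks honours trivial cases, plateaus and shift invariance", {
  mono <- uniform_signal(1:50, fs = 10)
  expect_identical(nrow(find_peaks(mono, 0)), 0L)

  tri <- uniform_signal(c(0, 1, 2, 1, 0), fs = 10)
  pk <- find_peaks(tri, min_prominence = 1)
  expect_identical(pk$index, 3L)
  expect_equal(pk$prominence, 2)

  plateau <- uniform_signal(c(0, 1, 1, 1, 0), fs = 10)
  expect_identical(find_peaks(plateau, 0)$index, 2L)

  set.seed(7)
  v <- cumsum(rnorm(150))
  a <- find_peaks(uniform_signal(v, fs = 10), 0.3)
  b <- find_peaks(uniform_signal(v + 17.5, fs = 10), 0.3)
  expect_identical(a$index, b$index)
  expect_equal(a$prominence, b$prominence)
})

test_that("second_derivative matches the stencil, is exact for quadratics, ignores trends", {
  fs <- 50
  t <- (0:99) / fs
  lin <- second_derivative(uniform_signal(3 * t + 1, fs = fs))
  expect_lt(max(abs(lin$value)), 1e-9)

  a <- 2.7
  quad <- second_derivative(uniform_signal(a * t^2, fs = fs))
  expect_equal(quad$value[2:99], rep(2 * a, 98), tolerance = 1e-6)

  set.seed(5)
  v <- rnorm(50)
  got <- second_derivative(uniform_signal(v, fs = fs))$value
  want <- vapply(2:49, function(k) (v[k - 1] - 2 * v[k] + v[k + 1]) * fs^2, numeric(1))
  expect_equal(got[2:49], want)
  expect_equal(got[1], got[2])
  expect_equal(got[50], got[49])

  trended <- second_derivative(uniform_signal(v + 5 * t + 2, fs = fs))$value
  expect_equal(trended[2:49], got[2:49], tolerance = 1e-8)

  expect_error(second_derivative(uniform_signal(c(1, 2), fs = 1)),
    class = "skatephase_error_insufficient_data"
  )
})

test_that("uniform_signal enforces its construction invariants", {
  expect_error(uniform_signal(c(1, NA), fs = 10), class = "skatephase_error_invalid_parameter")
  expect_error(uniform_signal(c(1, Inf), fs = 10), class = "skatephase_error_invalid_parameter")
  expect_error(uniform_signal(1:5, fs = 0), class = "skatephase_error_invalid_parameter")
  s <- uniform_signal(1:4, fs = 2, t0 = 1)
  expect_equal(s$time, c(1, 1.5, 2, 2.5))
})
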