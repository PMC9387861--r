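test_that("event matching attributes nearest neighbours with conservation", {
  m <- match_events(c(1.0, 2.0), c(1.02, 1.98), max_gap_s = 0.5)
  expect_equal(m$pairs$error_s, c(-0.02, 0.02))
  expect_identical(length(m$missed_ref), 0L)

  m2 <- match_events(c(1.0, 2.0), 1.02, max_gap_s = 0.5)
  expect_identical(nrow(m2$pairs), 1L)
  expect_equal(m2$missed_ref, 2.0)

  m3 <- match_events(numeric(0), c(1, 2, 3), max_gap_s = 0.5)
  expect_identical(nrow(m3$pairs), 0L)
  expect_equal(m3$spurious_imu, c(1, 2, 3))
})

test_that("matching equals the exhaustive assignment oracle on event-like sets", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(3:7, 1)
    ref <- cumsum(runif(n, 0.8, 1.4))
    imu <- ref + rnorm(n, 0, 0.03)
    imu <- sort(imu[runif(n) > 0.2])
    if (runif(1) > 0.5) imu <- sort(c(imu, runif(1, 0, max(ref))))
    gap <- 0.45
    got <- match_events(ref, imu, gap)
    want <- oracle_match(ref, imu, gap)
    expect_identical(nrow(got$pairs), nrow(want))
    expect_equal(got$pairs$ref_time, want$ref)
    expect_equal(got$pairs$imu_time, want$imu)
    # conservation identities
    expect_identical(nrow(got$pairs) + length(got$missed_ref), length(ref))
    expect_identical(nrow(got$pairs) + length(got$spurious_imu), length(imu))
  }
})

test_that("intra-trial bias and precision are the mean and n-1 SD in ms", {
  st <- intra_trial_stats(c(-0.010, -0.020, -0.030))
  expect_equal(st$bias_ms, -20)
  expect_equal(st$precision_ms, 10)

  expect_equal(intra_trial_stats(rep(0.004, 5))$precision_ms, 0)
  expect_true(is.na(intra_trial_stats(0.004)$bias_ms))
})

test_that("intra-trial statistics recover their sampling distribution", {
  set.seed(8)
  st <- intra_trial_stats(rnorm(1000, -0.022, 0.007))
  expect_equal(st$bias_ms, -22, tolerance = 0.7 / 22)
  expect_equal(st$precision_ms, 7, tolerance = 0.5 / 7)
})

test_that("inter-trial summaries use medians and type-7 IQRs", {
  per <- tibble::tibble(bias_ms = c(-10, -20, -30), precision_ms = c(5, 10, 15))
  st <- inter_trial_stats(per)
  expect_equal(st$b_mu, -20)
  expect_equal(st$sigma_mu, 10)

  single <- inter_trial_stats(tibble::tibble(bias_ms = 4, precision_ms = 6))
  expect_equal(single$b_sigma, 0)
  expect_equal(single$sigma_sigma, 0)

  set.seed(12)
  sim <- tibble::tibble(bias_ms = rnorm(200), precision_ms = rexp(200))
  st2 <- inter_trial_stats(sim)
  expect_equal(st2$b_sigma, oracle_iqr(sim$bias_ms))
  expect_equal(st2$sigma_sigma, oracle_iqr(sim$precision_ms))
  expect_equal(st2$b_mu, stats::median(sim$bias_ms))
})

test_that("relative errors are percentages of the reference duration", {
  expect_equal(relative_phase_errors(0.024, 1.2), 2.0)
  expect_equal(relative_phase_errors(0, 0.8), 0)
  set.seed(3)
  e <- rnorm(50, 0, 0.02)
  d <- runif(50, 0.5, 1.5)
  expect_equal(mean(relative_phase_errors(e, d)), mean(100 * e / d), tolerance = 1e-12)
  # non-positive durations are excluded
  expect_identical(length(relative_phase_errors(c(0.1, 0.1), c(1, 0))), 1L)
})

test_that("detection rate is matched over reference, undefined at zero", {
  expect_equal(detection_rate(25381, 25356), 99.90149, tolerance = 1e-6)
  expect_equal(detection_rate(10, 10), 100)
  expect_equal(detection_rate(10, 0), 0)
  expect_true(is.na(detection_rate(0, 0)))
  expect_error(detection_rate(5, 6))
})

test_that("Kruskal-Wallis reproduces the hand-ranked toy example exactly", {
  kw <- kruskal_wallis(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)
  expect_identical(as.integer(kw$df), 2L)

  same <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("Kruskal-Wallis matches the textbook formula and is rank-invariant", {
  set.seed(14)
  for (rep in 1:20) {
    groups <- lapply(1:3, function(i) round(rnorm(sample(4:9, 1), i * 0.3), 2))
    kw <- kruskal_wallis(groups)
    expect_equal(kw$statistic, oracle_kw(groups), tolerance = 1e-9)
    # strictly monotone transform of the pooled data leaves H unchanged
    kw2 <- kruskal_wallis(lapply(groups, function(g) exp(g / 2)))
    expect_equal(kw2$statistic, kw$statistic, tolerance = 1e-9)
  }
})

test_that("kruskal_wallis accepts a data frame with tidy-eval columns", {
  df <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                       g = rep(c("a", "b", "c"), each = 3))
  expect_equal(kruskal_wallis(df, v, g)$statistic, 7.2)
})

test_that("DSCF pairwise comparisons match a from-scratch rank computation", {
  expect_equal(dscf_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))$p_value, 1)
  expect_equal(dscf_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))$statistic, 0)

  set.seed(6)
  groups <- list(a = rnorm(12), b = rnorm(9, 0.4), c = rnorm(15, -0.2))
  ds <- dscf_posthoc(groups)
  expect_identical(nrow(ds), 3L)
  for (r in seq_len(nrow(ds))) {
    o <- oracle_dscf_pair(groups[[ds$group1[r]]], groups[[ds$group2[r]]], k = 3)
    expect_equal(ds$statistic[r], o$W, tolerance = 1e-9)
    expect_equal(ds$p_value[r], o$p, tolerance = 1e-9)
  }

  far <- list(a = rnorm(20), b = rnorm(20, 10), c = rnorm(20, 20))
  expect_true(all(dscf_posthoc(far)$p_value < 0.001))
})

test_that("an injected constant offset is recovered as inter-trial bias", {
  set.seed(19)
  delta <- 0.015
  jit <- 0.005
  per <- purrr::map_dfr(1:30, function(i) {
    ref <- cumsum(runif(50, 1.1, 1.4))
    imu <- ref + delta + rnorm(50, 0, jit)
    m <- match_events(ref, imu, 0.6)
    intra_trial_stats(m$pairs$error_s)
  })
  st <- inter_trial_stats(per)
  expect_equal(st$b_mu, -1000 * delta, tolerance = (2 / sqrt(30)) * jit * 1000 / (1000 * delta))
  expect_equal(st$sigma_mu, 1000 * jit, tolerance = 0.10)
})

test_that("precision recovers the jitter scale for one- and two-sided noise", {
  set.seed(23)
  s <- 0.008
  one_sided <- purrr::map_dfr(1:30, function(i) {
    ref <- cumsum(runif(50, 1.1, 1.4))
    intra_trial_stats(match_events(ref, ref + rnorm(50, 0, s), 0.6)$pairs$error_s)
  })
  expect_equal(inter_trial_stats(one_sided)$sigma_mu, 1000 * s, tolerance = 0.10)

  both_sided <- purrr::map_dfr(1:30, function(i) {
    base <- cumsum(runif(50, 1.1, 1.4))
    ref <- base + rnorm(50, 0, s)
    imu <- base + rnorm(50, 0, s)
    intra_trial_stats(match_events(ref, imu, 0.6)$pairs$error_s)
  })
  expect_equal(inter_trial_stats(both_sided)$sigma_mu, 1000 * s * sqrt(2), tolerance = 0.10)
})

test_that("phase occurrences tile reference cycles consistently", {
  tr <- clean_trial("G3")
  gt <- gt_events_of(tr)
  ph <- phase_occurrences(gt)
  scy <- ph[ph$phase == "S_CY", ]
  sct <- ph[ph$phase == "S_CT" & ph$side == "left", ]
  ssw <- ph[ph$phase == "S_SW" & ph$side == "left", ]
  n <- nrow(scy)
  expect_equal(
    sum(sct$duration[1:n]) + sum(ssw$duration[1:n]),
    sum(scy$duration),
    tolerance = 1e-9
  )
})

test_that("tidy methods expose the statistics as tibbles", {
  kw <- kruskal_wallis(list(a = 1:4, b = 5:8))
  td <- generics::tidy(kw)
  expect_true(all(c("statistic", "df", "p_value", "method") %in% names(td)))
  ds <- dscf_posthoc(list(a = rnorm(5), b = rnorm(5)))
  expect_true("contrast" %in% names(generics::tidy(ds)))
})
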