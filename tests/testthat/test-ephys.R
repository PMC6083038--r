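test_that("passive membrane formulas are exact with unit bookkeeping", {
  pm <- passive_membrane(Q = 0.4, dV = 10, Iss = 100, Ip = 2000)
  expect_identical(pm$Cm_pF, 40)         # 0.4 pC / 10 mV = 40 pF
  expect_identical(pm$Gm_nS, 10)         # 100 pA / 10 mV = 10 nS
  expect_identical(pm$Rs_MOhm, 5)        # 10 mV / 2000 pA = 5 MOhm
  # exact on rational inputs
  set.seed(4)
  for (i in 1:25) {
    Q <- sample(1:40, 1) / 8; dV <- sample(1:20, 1) / 2
    Iss <- sample(1:500, 1); Ip <- sample(1:4000, 1)
    pm <- passive_membrane(Q, dV, Iss, Ip)
    expect_identical(pm$Cm_pF, 1000 * Q / dV)
    expect_identical(pm$Gm_nS, Iss / dV)
    expect_identical(pm$Rs_MOhm, 1000 * dV / Ip)
  }
  expect_error(passive_membrane(1, 0, 1, 1), "dV")
  expect_error(passive_membrane(1, 1, 1, 0), "Ip")
})

test_that("series-resistance exclusion triggers above a 30% rise", {
  expect_false(rs_exclusion(c(10, 12)))        # +20%
  expect_true(rs_exclusion(c(10, 13.1)))       # +31%
  expect_false(rs_exclusion(c(8, 8, 8, 8)))    # constant
  expect_true(rs_exclusion(c(10, 11, 14, 9)))  # peak counts, not endpoint
  expect_error(rs_exclusion(5), "two")
  expect_error(rs_exclusion(c(10, -1)), "positive")
})

test_that("events are detected at injected times", {
  onsets <- seq(0.5, 9.5, by = 1)
  sim <- manual_mepsc_trace(onsets, rep(-20, 10))
  idx <- detect_events(sim$trace, threshold = -10)
  expect_length(idx, 10)
  expect_true(all(abs(idx - sim$peak_idx) <= 1))
  # flat trace
  expect_length(detect_events(current_trace(rep(0, 2000), 20000), -10), 0)
  # DC offsets do not matter
  shifted <- current_trace(sim$trace$samples - 137.5, 20000)
  expect_identical(detect_events(shifted, threshold = -10), idx)
})

test_that("rise time interpolates the 10% and 90% crossings", {
  # linear ramp 0 -> -20 pA over 1 ms, instant return
  fs <- 20000
  s <- rep(0, 400)
  ramp <- seq(0, -20, length.out = 21)   # 20 intervals = 1 ms
  s[100 + 0:20] <- ramp
  tr <- current_trace(s, fs)
  f <- event_features(tr, index = 120)
  expect_equal(f$peak_amplitude_pA, -20)
  expect_equal(f$rise_10_90_ms, 0.8, tolerance = 1e-9)
})

test_that("weighted decay is the amplitude-weighted bi-exponential constant", {
  fs <- 20000
  t_ms <- (0:1200) / fs * 1000
  # equal-amplitude decays tau1 = 2 ms, tau2 = 8 ms -> weighted 5 ms
  decay <- -10 * (0.5 * exp(-t_ms / 2) + 0.5 * exp(-t_ms / 8))
  s <- c(rep(0, 100), seq(0, -10, length.out = 7)[-7], decay, rep(0, 100))
  tr <- current_trace(s, fs)
  f <- event_features(tr, index = which.min(s), decay_ms = 55)
  expect_true(f$decay_biexponential)
  expect_equal(f$weighted_decay_ms, 5, tolerance = 0.05)
})

test_that("feature extraction is invariant to DC offset and time shift", {
  sim <- manual_mepsc_trace(c(0.5, 1.2), c(-15, -8))
  f0 <- event_features(sim$trace, sim$peak_idx[1])
  # DC offset
  f1 <- event_features(current_trace(sim$trace$samples + 42, 20000),
                       sim$peak_idx[1])
  expect_equal(f1$peak_amplitude_pA, f0$peak_amplitude_pA, tolerance = 1e-9)
  expect_equal(f1$rise_10_90_ms, f0$rise_10_90_ms, tolerance = 1e-9)
  # uniform time shift
  shift <- 400L
  f2 <- event_features(current_trace(c(rep(0, shift), sim$trace$samples),
                                     20000), sim$peak_idx[1] + shift)
  expect_equal(f2$peak_amplitude_pA, f0$peak_amplitude_pA, tolerance = 1e-9)
  expect_equal(f2$rise_10_90_ms, f0$rise_10_90_ms, tolerance = 1e-9)
  expect_equal(f2$weighted_decay_ms, f0$weighted_decay_ms, tolerance = 1e-6)
})

test_that("peaks of noiseless synthetic events are recovered within 5%", {
  onsets <- seq(0.3, 4.3, by = 0.5)
  amps <- rep(c(-20, -12, -6), length.out = length(onsets))
  sim <- manual_mepsc_trace(onsets, amps)
  ev <- extract_events(sim$trace, threshold = -4)
  expect_equal(nrow(ev), length(onsets))
  expect_lt(max(abs(ev$peak_amplitude_pA - amps) / abs(amps)), 0.05)
  # instantaneous frequency is the reciprocal inter-event interval
  expect_true(is.na(ev$instantaneous_frequency_Hz[1]))
  expect_equal(ev$instantaneous_frequency_Hz[-1], 1 / diff(ev$time_s))
})

test_that("frequency regression matches closed-form least squares", {
  # exact points on y = 2.7 + 4.6 x
  x <- c(0, 0.1, 0.2, 0.5, 1)
  rr <- suppressWarnings(frequency_rate_regression(x, 2.7 + 4.6 * x))
  expect_equal(rr$slope, 4.6, tolerance = 1e-12)
  expect_equal(rr$intercept, 2.7, tolerance = 1e-12)
  expect_equal(rr$r_squared, 1, tolerance = 1e-12)
  # closed-form normal equations on random data
  set.seed(19)
  for (i in 1:10) {
    xs <- runif(20, 0, 2); ys <- rnorm(20, 3 + 2 * xs)
    rr <- frequency_rate_regression(xs, ys)
    b <- cov(xs, ys) / var(xs)
    a <- mean(ys) - b * mean(xs)
    expect_equal(rr$slope, b, tolerance = 1e-10)
    expect_equal(rr$intercept, a, tolerance = 1e-10)
  }
  # confidence limits bracket the fit
  expect_true(all(rr$conf_limits$lower_5 <= rr$conf_limits$fit))
  expect_true(all(rr$conf_limits$upper_95 >= rr$conf_limits$fit))
  expect_error(frequency_rate_regression(c(1, 1, 1), c(1, 2, 3)),
               "identical")
  expect_error(frequency_rate_regression(c(1, 2), c(1, 2)), "3 points")
})

test_that("a seeded simulation recovers the generating slope", {
  set.seed(23)
  rates <- rep(c(0.05, 0.1, 0.2, 0.5, 1), each = 6)
  freqs <- 2.7 + 4.6 * rates + rnorm(length(rates), sd = 1)
  rr <- frequency_rate_regression(rates, freqs)
  expect_lt(abs(rr$slope - 4.6), 3 * rr$slope_se)
})
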