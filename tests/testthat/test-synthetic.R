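test_that("rendered tubes have the exact Gaussian cross-section", {
  # 50 um axial line in a 50 x 20 x 20 um volume (0.5 um isotropic voxels)
  w <- 3
  sp <- phantom_spec(c(100L, 40L, 40L), c(0.5, 0.5, 0.5),
                     list(curve_line(c(9.75, 9.75, 0.1), c(9.75, 9.75, 49.9),
                                     width_px = w, peak = 1)),
                     background = 0, noise_sd = 0, seed = 1)
  ph <- make_phantom(sp)
  expect_equal(ph$total_length, 49.8)
  # mid-plane profile vs analytic exp(-2 d^2 / w^2); the axis at 9.75 um
  # falls on voxel centre 19 (0-based) under the half-voxel convention
  plane <- ph$stack$intensities[50, , ]
  for (yi in c(10, 16, 20, 24)) for (xi in c(12, 20, 27)) {
    d2 <- (yi - 1 - 19)^2 + (xi - 1 - 19)^2
    expect_equal(plane[yi, xi], exp(-2 * d2 / w^2), tolerance = 1e-6)
  }
})

test_that("helix ground truth matches the analytic arc length", {
  cv <- curve_helix(center = c(15, 15, 2), radius_um = 10, pitch_um = 5,
                    turns = 2)
  expect_equal(curve_length(cv), 2 * sqrt((2 * pi * 10)^2 + 5^2))
  # dense polyline integration agrees to 0.1%
  poly_len <- sum(sqrt(rowSums(diff(curve_points(cv, 0.05))^2)))
  expect_lt(abs(poly_len - curve_length(cv)) / curve_length(cv), 1e-3)
  # bezier length is finite and consistent with its own polyline
  bz <- curve_bezier(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(5, 5, 5)))
  expect_equal(curve_length(bz),
               sum(sqrt(rowSums(diff(curve_points(bz, 0.05))^2))),
               tolerance = 1e-3)
})

test_that("generators are pure functions of spec and seed", {
  sp <- benchmark_phantom_spec(3, noise_sd = 0.1)
  expect_identical(make_phantom(sp)$stack$intensities,
                   make_phantom(sp)$stack$intensities)
  ms <- mixture_spec(c(0.5, 0.5), c(0, 5), c(1, 1), n = 1000, seed = 9)
  expect_identical(as.numeric(sample_mixture(ms)),
                   as.numeric(sample_mixture(ms)))
  expect_identical(synth_mepsc_trace(5, 10, seed = 2)$trace$samples,
                   synth_mepsc_trace(5, 10, seed = 2)$trace$samples)
})

test_that("curves outside the volume and invalid widths are rejected", {
  expect_error(phantom_spec(c(20L, 20L, 20L), c(0.5, 0.5, 0.5),
                            list(curve_line(c(0, 0, 0), c(50, 0, 0)))),
               "leaves the volume")
  expect_error(curve_line(c(0, 0, 0), c(1, 1, 1), width_px = 1), "2 px")
  expect_error(mixture_spec(c(0.6, 0.6), c(0, 1), c(1, 1), 10), "sum to 1")
})

test_that("mixture samples follow the stated fractions and moments", {
  # single component: CLT bound on the mean
  x <- sample_mixture(mixture_spec(1, 0, 1, n = 1e4, seed = 3))
  expect_lt(abs(mean(x)), 4 / sqrt(1e4))
  # multinomial component counts within 3 sigma
  spec <- mixture_spec(c(0.31, 0.41, 0.28), c(-5, -12, -22), c(2, 2, 2),
                       n = 5000, seed = 4)
  x <- sample_mixture(spec)
  counts <- tabulate(attr(x, "component"), 3)
  for (i in 1:3) {
    expd <- 5000 * spec$fractions[i]
    sd_i <- sqrt(5000 * spec$fractions[i] * (1 - spec$fractions[i]))
    expect_lt(abs(counts[i] - expd), 3 * sd_i)
  }
  # n = 0 gives an empty sample
  expect_length(sample_mixture(mixture_spec(1, 0, 1, n = 0, seed = 1)), 0)
})

test_that("synthetic mEPSC traces carry their ground truth", {
  # rate 0: pure noise, empty truth table
  sim0 <- synth_mepsc_trace(0, 2, seed = 5)
  expect_equal(nrow(sim0$events), 0)
  expect_lt(abs(sd(sim0$trace$samples) - 0.8), 0.05)
  # Poisson event count at rate 10 Hz for 100 s
  sim <- synth_mepsc_trace(10, 100, seed = 6)
  expect_lt(abs(nrow(sim$events) - 1000), 3 * sqrt(1000))
  # noiseless events are recovered end to end; amplitude is measured
  # against the local baseline, so judge it on events isolated from any
  # neighbour's decay
  simn <- synth_mepsc_trace(2, 10, noise_sd = 0, seed = 7)
  ev <- extract_events(simn$trace, threshold = -3)
  expect_equal(nrow(ev), nrow(simn$events))
  expect_lt(max(abs(ev$time_s - simn$events$peak_s)), 1.5e-4)
  gaps <- diff(c(-Inf, simn$events$peak_s, Inf))
  isolated <- gaps[-length(gaps)] > 0.06 & gaps[-1] > 0.06
  rel <- abs(ev$peak_amplitude_pA - simn$events$amplitude_pA) /
    abs(simn$events$amplitude_pA)
  expect_lt(max(rel[isolated]), 0.02)
})
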