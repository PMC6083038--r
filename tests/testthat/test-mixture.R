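test_that("Freedman-Diaconis binwidth follows the hinge convention", {
  b <- fd_binwidth(1:8)                  # hinges 2.5 / 6.5, IQR 4, n^(1/3) 2
  expect_equal(b$bin_width, 4)
  expect_equal(b$iqr, 4)
  # homogeneity: scaling the sample scales the width
  expect_equal(fd_binwidth(3.7 * (1:8))$bin_width, 3.7 * 4)
  # matches an independent hinge-and-formula oracle
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(sample(10:200, 1), sd = runif(1, 0.5, 20))
    expect_identical(fd_binwidth(x)$bin_width, fd_brute(x))
  }
  expect_error(fd_binwidth(rep(1, 10)), "IQR")
  expect_error(fd_binwidth(1:3), "at least 4")
})

test_that("histograms integrate to one over FD bins", {
  set.seed(2)
  x <- rnorm(500)
  h <- build_histogram(x)
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-12)
  expect_equal(sum(h$counts), 500)
})

test_that("gauss_sum is the area-parameterised Gaussian mixture", {
  # A = sqrt(pi/2), w = 1 gives unit peak height
  expect_equal(gauss_sum(0, 0, data.frame(A = sqrt(pi / 2), w = 1, xc = 0)), 1)
  # offset only
  expect_equal(gauss_sum(c(-3, 0, 11), 0.5, data.frame()[0, ]),
               rep(0.5, 3))
  # each component integrates to its area
  comp <- data.frame(A = 2.3, w = 1.7, xc = -4)
  q <- integrate(function(x) gauss_sum(x, 0, comp), -4 - 17, -4 + 17,
                 rel.tol = 1e-10)
  expect_equal(q$value, 2.3, tolerance = 1e-6)
  expect_error(gauss_sum(0, 0, data.frame(A = 1, w = -1, xc = 0)), "w")
})

test_that("an exact two-component histogram is recovered to 1e-4", {
  comps <- data.frame(A = c(0.4, 0.6), w = c(1.5, 2.5), xc = c(-8, -2))
  mids <- seq(-14, 4, by = 0.5)
  h <- structure(list(mids = mids,
                      density = gauss_sum(mids, 0, comps),
                      counts = rep(1, length(mids)),
                      breaks = c(mids - 0.25, max(mids) + 0.25),
                      bin_width = 0.5, n = 5000L),
                 class = "mix_histogram")
  fit <- fit_gauss_sum(h, 2)
  expect_true(fit$converged)
  expect_equal(fit$components$A, comps$A, tolerance = 1e-4)
  expect_equal(fit$components$w, comps$w, tolerance = 1e-4)
  expect_equal(fit$components$xc, comps$xc, tolerance = 1e-4)
  expect_lt(fit$chi_square, 1e-10)
})

test_that("a single-component fit centres on the sample mode", {
  x <- sample_mixture(mixture_spec(1, -9, 4, n = 4000, seed = 31))
  h <- build_histogram(x)
  fit <- fit_gauss_sum(h, 1)
  # the histogram mode itself carries ~1 bin of sampling noise
  mode_bin <- h$mids[which.max(h$density)]
  expect_lt(abs(fit$components$xc - mode_bin), 2 * h$bin_width)
})

test_that("degenerate histograms are flagged, not silently fitted", {
  mids <- seq(0, 10, by = 1)
  dens <- c(rep(0, 5), 12, rep(0, 5))    # all mass in one bin
  h <- structure(list(mids = mids, density = dens, counts = dens,
                      breaks = c(mids - 0.5, 10.5), bin_width = 1, n = 12L),
                 class = "mix_histogram")
  fit <- fit_gauss_sum(h, 1)
  expect_false(fit$converged)
})

test_that("model selection finds the generating component count", {
  # three well-separated components
  x <- sample_mixture(mixture_spec(c(0.31, 0.41, 0.28), c(-5, -12, -22),
                                   c(2, 2, 2), n = 5000, seed = 77))
  fit <- select_model(build_histogram(x))
  expect_equal(fit$k, 3L)
  fr <- component_fractions(fit)[order(fit$components$xc)]
  expect_lt(max(abs(fr - c(0.28, 0.41, 0.31))), 0.05)
  expect_lt(max(abs(sort(fit$components$xc) - c(-22, -12, -5))),
            0.5 * fit$bins$bin_width + 1e-9)
  # the fourth-component probe is reported even though rejected
  expect_equal(nrow(fit$trail), 4L)
  expect_false(fit$trail$accepted[4])
  # warm-started chi-square trail is non-increasing
  expect_true(all(diff(fit$trail$chi_square) <= 1e-8))
  # single-Gaussian data selects k = 1
  x1 <- sample_mixture(mixture_spec(1, 3, 2, n = 5000, seed = 78))
  expect_equal(select_model(build_histogram(x1))$k, 1L)
})

test_that("selected fits never contain a sub-1% component", {
  for (s in 1:5) {
    x <- sample_mixture(mixture_spec(c(0.31, 0.41, 0.28), c(-5, -12, -22),
                                     c(2, 2, 2), n = 3000, seed = 100 + s))
    fit <- select_model(build_histogram(x))
    expect_gte(min(component_fractions(fit)), 0.01)
  }
})

test_that("component fractions are areas over total area", {
  fit <- list(components = data.frame(A = c(2, 3, 5), w = 1, xc = 1:3))
  expect_equal(component_fractions(fit), c(0.2, 0.3, 0.5))
  expect_equal(sum(component_fractions(fit)), 1, tolerance = 1e-9)
  expect_equal(component_fractions(list(components = data.frame(
    A = 7, w = 1, xc = 0))), 1)
})

test_that("size cutoffs sit at the density crossing points", {
  # equal area, equal width: crossing at the midpoint
  fit <- list(components = data.frame(A = c(1, 1), w = c(2, 2), xc = c(0, 4)))
  expect_equal(size_cutoffs(fit), 2, tolerance = 1e-9)
  # general case matches a brute-force grid search for the sign change
  fit2 <- list(components = data.frame(A = c(0.5, 0.3, 0.2),
                                       w = c(1.2, 2.1, 3.3),
                                       xc = c(1, 6, 14)))
  cuts <- size_cutoffs(fit2)
  expect_equal(length(cuts), 2L)
  expect_true(all(diff(cuts) > 0))
  dens <- function(i, x) fit2$components$A[i] /
    (fit2$components$w[i] * sqrt(pi / 2)) *
    exp(-2 * (x - fit2$components$xc[i])^2 / fit2$components$w[i]^2)
  for (i in 1:2) {
    grid <- seq(fit2$components$xc[i], fit2$components$xc[i + 1], 1e-4)
    dd <- dens(i, grid) - dens(i + 1, grid)
    brute <- grid[which(dd[-1] * dd[-length(dd)] <= 0)[1]]
    expect_lt(abs(cuts[i] - brute), 1e-3)
  }
  expect_error(size_cutoffs(list(components = data.frame(
    A = c(1, 1), w = c(1, 1), xc = c(2, 2)))), "identical")
  # no crossing between the centres: midpoint with a warning
  fit3 <- list(components = data.frame(A = c(1, 1e6), w = c(1, 30),
                                       xc = c(0, 4)))
  expect_warning(mid <- size_cutoffs(fit3), "midpoint")
  expect_equal(mid, 2)
})

test_that("size classification is the cutoff partition", {
  cls <- classify_sizes(c(1, 5, 9), c(3, 7))
  expect_equal(as.character(cls$labels), c("small", "medium", "large"))
  expect_equal(unname(cls$proportions), rep(1 / 3, 3))
  # negative amplitudes classified by magnitude
  clm <- classify_sizes(c(-1, -5, -9), c(3, 7), magnitude = TRUE)
  expect_equal(as.character(clm$labels), c("small", "medium", "large"))
  # empty stratum reports NA, not zero
  cs <- classify_sizes(c(1, 5, 9), c(3, 7),
                       by = factor(c("soma", "soma", "soma"),
                                   levels = c("soma", "dendrite")))
  expect_true(all(is.na(cs$proportions["dendrite", ])))
  expect_equal(sum(cs$proportions["soma", ]), 1)
  # counts agree with an exhaustive comparison loop
  set.seed(12)
  v <- runif(300, 0, 12)
  cl <- classify_sizes(v, c(3, 7))
  expect_equal(unname(as.numeric(cl$counts)),
               c(sum(v < 3), sum(v >= 3 & v < 7), sum(v >= 7)))
})

test_that("classification is stable under re-fitting the same histogram", {
  x <- sample_mixture(mixture_spec(c(0.31, 0.41, 0.28), c(-5, -12, -22),
                                   c(2, 2, 2), n = 4000, seed = 55))
  h <- build_histogram(abs(x))
  f1 <- select_model(h); f2 <- select_model(h)
  c1 <- size_cutoffs(f1); c2 <- size_cutoffs(f2)
  expect_identical(c1, c2)
  expect_identical(classify_sizes(abs(x), c1)$labels,
                   classify_sizes(abs(x), c2)$labels)
})
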