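test_that("Gaussian smoothing has the expected impulse and identity behaviour", {
  v <- array(0, c(21, 21, 21)); v[11, 11, 11] <- 1
  G <- smooth_volume(v, 1.5)
  # impulse response: separable kernel, peak at the impulse, mass conserved
  expect_equal(which.max(G), which.max(v))
  expect_equal(sum(G), 1, tolerance = 1e-12)
  k <- dnorm(seq(-6, 6), sd = 1.5); k <- k / sum(k)
  expect_equal(G[11, 11, 5:17], k * max(k)^2, tolerance = 1e-12)
  # constant volume is a fixed point
  Gc <- smooth_volume(array(3.2, c(8, 9, 10)), 2)
  expect_equal(range(Gc), c(3.2, 3.2), tolerance = 1e-12)
  expect_error(smooth_volume(v, 0), "> 0")
})

test_that("separable smoothing agrees with direct dense convolution", {
  set.seed(8)
  v <- array(runif(12^3), c(12, 12, 12))
  sigma <- 1.2
  G <- smooth_volume(v, sigma)
  # brute force: full 3D kernel applied voxel by voxel with the same
  # edge-repeating reflection
  r <- ceiling(3.5 * sigma)
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  dense <- array(0, dim(v))
  for (z in 1:12) for (y in 1:12) for (x in 1:12) {
    acc <- 0
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r)
      acc <- acc + k1[dz + r + 1] * k1[dy + r + 1] * k1[dx + r + 1] *
        v[refl(z + dz, 12), refl(y + dy, 12), refl(x + dx, 12)]
    dense[z, y, x] <- acc
  }
  expect_lt(max(abs(G - dense)), 1e-8)
})

test_that("Hessian eigen-system matches closed forms and stays orthonormal", {
  ph <- analytic_tube(width_px = 2, peak = 1)
  G <- smooth_volume(ph$stack, 2)
  eig <- hessian_eigen(G, tube_axis_px)
  lam <- tube_lambda_closed_form(2, 2)
  # lambda2 ~ lambda3 ~ closed form, lambda1 ~ 0
  expect_lt(max(abs(eig$values[2:3] - lam) / abs(lam)), 0.05)
  expect_lt(abs(eig$values[1]) / abs(eig$values[3]), 0.05)
  # minor eigenvector along the tube (z axis)
  ang <- acos(min(1, abs(sum(eig$vectors[, 1] * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 5)
  # orthonormal eigenvectors satisfying H v = lambda v
  expect_lt(max(abs(crossprod(eig$vectors) - diag(3))), 1e-6)
  for (j in 1:3)
    expect_lt(max(abs(eig$H %*% eig$vectors[, j] -
                        eig$values[j] * eig$vectors[, j])), 1e-6)
  expect_error(hessian_eigen(G, c(1, 1, 1)), class = "axonmap_boundary_error")
})

test_that("quadratic volumes give exact isotropic Hessians", {
  # bowl a(x^2 + y^2 + z^2): all eigenvalues 2a (finite differences are
  # exact on quadratics)
  a <- 0.3
  n <- 13L
  idx <- seq_len(n) - 7
  v <- array(0, c(n, n, n))
  for (z in 1:n) for (y in 1:n) v[z, y, ] <- a * (idx^2 + idx[y]^2 + idx[z]^2)
  eig <- hessian_eigen(v, c(6, 6, 6), window = 9)
  expect_equal(eig$values, rep(2 * a, 3), tolerance = 1e-10)
})

test_that("random quadratic forms recover H and the polynomial eigenvalues", {
  set.seed(9)
  n <- 13L
  idx <- seq_len(n) - 7
  for (rep in 1:10) {
    H <- matrix(rnorm(9, sd = 0.2), 3); H <- (H + t(H)) / 2
    v <- array(0, c(n, n, n))
    for (z in 1:n) for (y in 1:n) {
      p <- cbind(idx, idx[y], idx[z])
      v[z, y, ] <- 0.5 * rowSums((p %*% H) * p)
    }
    eig <- hessian_eigen(v, c(6, 6, 6))
    expect_equal(eig$H, H, tolerance = 1e-9)
    # characteristic-polynomial oracle: det(H - lambda I) = 0
    cp <- c(-det(H),
            H[1, 1] * H[2, 2] + H[1, 1] * H[3, 3] + H[2, 2] * H[3, 3] -
              H[1, 2]^2 - H[1, 3]^2 - H[2, 3]^2,
            -(H[1, 1] + H[2, 2] + H[3, 3]), 1)
    roots <- sort(Re(polyroot(cp)))
    expect_equal(sort(eig$values), roots, tolerance = 1e-9)
  }
})

test_that("the minor eigenvector tracks the tube axis across scales", {
  ph <- analytic_tube(width_px = 2, peak = 1)
  for (sigma in c(2, 3, 4, 5)) {
    G <- smooth_volume(ph$stack, sigma)
    eig <- hessian_eigen(G, tube_axis_px)
    ang <- acos(min(1, abs(sum(eig$vectors[, 1] * c(0, 0, 1))))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("tubularity separates tubes, blobs and background", {
  pars <- tracer_params(sigma = 2)
  ideal <- structure(list(values = c(0, -1, -1), vectors = diag(3)),
                     class = "hessian_eigen")
  blob <- structure(list(values = c(-1, -1, -1), vectors = diag(3)),
                    class = "hessian_eigen")
  expect_true(is_tubular(ideal, pars))
  expect_false(is_tubular(blob, pars))
  # on the rendered analytic tube: axis is tubular, background is not
  ph <- analytic_tube(width_px = 2, peak = 1)
  G <- smooth_volume(ph$stack, 2)
  expect_true(is_tubular(hessian_eigen(G, tube_axis_px), pars))
  expect_false(is_tubular(hessian_eigen(G, c(8, 8, 24)), pars))
})

test_that("medial correction re-centres points on the tube axis", {
  ph <- analytic_tube(width_px = 3, peak = 1)
  G <- smooth_volume(ph$stack, 2)
  # 2 px lateral offset pulled back to within 0.5 px of the axis
  p <- medial_correct(G, c(26, 24, 24), c(0, 0, 1))
  expect_lt(sqrt(sum((p[1:2] - 24)^2)), 0.5)
  expect_equal(p[3], 24)                 # stays in the normal plane
  # a point already on the axis barely moves
  p0 <- medial_correct(G, c(24, 24, 24), c(0, 0, 1))
  expect_lt(sqrt(sum((p0[1:2] - 24)^2)), 0.25)
  # constant volume: tie broken to the centre (input point)
  pc <- medial_correct(array(1, c(16, 16, 16)), c(8, 8, 8), c(0, 0, 1))
  expect_equal(pc, c(8, 8, 8), tolerance = 1e-9)
  expect_error(medial_correct(G, c(200, 200, 200), c(0, 0, 1)),
               class = "axonmap_boundary_error")
})
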