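# Shared fixtures, all generated in code.

# analytic tube along z on a voxel-centred axis (x = y = 9.8 um -> px 24)
# in an isotropic 48^3 volume; no background, no noise
analytic_tube <- function(width_px = 2, peak = 1) {
  make_phantom(phantom_spec(
    c(48L, 48L, 48L), c(0.4, 0.4, 0.4),
    list(curve_line(c(9.8, 9.8, 0.2), c(9.8, 9.8, 19.0),
                    width_px = width_px, peak = peak)),
    background = 0, noise_sd = 0, seed = 1L))
}

tube_axis_px <- c(24, 24, 24)

# closed-form lambda2 = lambda3 on the axis of the analytic tube after
# Gaussian smoothing: the tube's radial Gaussian has variance w^2/4 per
# lateral axis; smoothing adds sigma^2 and scales the peak per axis
tube_lambda_closed_form <- function(width_px, sigma, peak = 1) {
  s0sq <- width_px^2 / 4
  s2 <- s0sq + sigma^2
  -(peak * s0sq / s2) / s2
}

# brute-force Euclidean distance transform (independent oracle)
edt_brute <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg)))
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((fg[i, 1] - bg[, 1])^2 + (fg[i, 2] - bg[, 2])^2))
  out
}

# independent FD binwidth oracle: sorted halves, hinge medians, formula
fd_brute <- function(x) {
  x <- sort(x)
  n <- length(x)
  lower <- x[1:ceiling(n / 2)]
  upper <- x[(floor(n / 2) + 1):n]
  med <- function(v) {
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  2 * (med(upper) - med(lower)) / n^(1 / 3)
}

# deterministic synthetic mEPSC trace: difference-of-exponentials events at
# given onsets (independent of the package generator)
manual_mepsc_trace <- function(onsets_s, amps_pA, fs = 20000,
                               duration_s = max(onsets_s) + 0.1,
                               rise_ms = 0.3, d1_ms = 2, d2_ms = 8,
                               split = 0.5, noise_sd = 0) {
  n <- round(duration_s * fs)
  s <- if (noise_sd > 0) rnorm(n, sd = noise_sd) else numeric(n)
  t_ms <- (0:round(0.06 * fs)) / fs * 1000
  shape <- split * exp(-t_ms / d1_ms) + (1 - split) * exp(-t_ms / d2_ms) -
    exp(-t_ms / rise_ms)
  shape <- shape / max(shape)
  peak_off <- which.max(shape) - 1L
  for (i in seq_along(onsets_s)) {
    i0 <- round(onsets_s[i] * fs) + 1L
    idx <- i0 + seq_along(shape) - 1L
    s[idx] <- s[idx] + amps_pA[i] * shape
  }
  list(trace = current_trace(s, fs),
       peak_idx = round(onsets_s * fs) + 1L + peak_off)
}
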