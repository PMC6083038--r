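# Accuracy metrics for traces against phantom ground truth, and seeded
# benchmark drivers shared by the test suite and the reproducibility script.
# Distances are measured in (anisotropy-corrected) voxel units: both traces
# and centerlines are mapped to pixel space before comparison.

# minimum distance from each row of `pts` to the polyline `poly` (both n x 3)
min_dist_to_polyline <- function(pts, poly) {
  if (nrow(poly) == 1L)
    return(sqrt(rowSums(sweep(pts, 2L, poly[1, ])^2)))
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(poly) - 1L)) {
    p0 <- poly[i, ]; v <- poly[i + 1L, ] - p0
    L2 <- sum(v^2)
    dx <- sweep(pts, 2L, p0)
    t <- if (L2 > 0) pmin(pmax((dx %*% v) / L2, 0), 1) else 0
    d2 <- rowSums((dx - outer(as.numeric(t), v))^2)
    best <- pmin(best, d2)
  }
  sqrt(best)
}

to_px <- function(pts_um, voxel_size) {
  sweep(pts_um, 2L, rev(voxel_size), `/`) - 0.5
}

#' Tracing accuracy against phantom ground truth
#'
#' Compares a set of traces with a phantom's analytic centerlines in voxel
#' units. Coverage is the fraction of ground-truth arc length lying within
#' `tol_voxels` of some trace; the orthogonal deviation is the mean distance
#' from trace nodes to the nearest true centerline.
#'
#' @param traces list of [axon_trace()] objects.
#' @param phantom a [make_phantom()] result.
#' @param tol_voxels coverage tolerance in voxels (default 2).
#' @return A list: `coverage` (0-1), `mean_deviation_voxels`,
#'   `traced_length_um`, `truth_length_um`.
#' @export
trace_accuracy <- function(traces, phantom, tol_voxels = 2) {
  vox <- phantom$stack$voxel_size
  truth_px <- lapply(phantom$centerlines, to_px, voxel_size = vox)
  truth_all <- do.call(rbind, truth_px)
  if (!length(traces)) {
    return(list(coverage = 0, mean_deviation_voxels = NA_real_,
                traced_length_um = 0,
                truth_length_um = phantom$total_length))
  }
  trace_px <- lapply(traces, function(tr) to_px(tr$points, vox))
  # coverage: ground-truth samples (uniform in arc length) near any trace
  best <- rep(Inf, nrow(truth_all))
  for (tp in trace_px)
    best <- pmin(best, min_dist_to_polyline(truth_all, tp))
  coverage <- mean(best <= tol_voxels)
  # deviation: trace nodes to the nearest true centerline
  nodes <- do.call(rbind, trace_px)
  dev <- rep(Inf, nrow(nodes))
  for (tp in truth_px) dev <- pmin(dev, min_dist_to_polyline(nodes, tp))
  list(coverage = coverage,
       mean_deviation_voxels = mean(dev),
       traced_length_um = sum(vapply(traces, trace_length, numeric(1))),
       truth_length_um = phantom$total_length)
}

# -- benchmark drivers ----------------------------------------------------

#' Standard tracing phantoms
#'
#' A seeded family of single-tube phantoms (alternating straight oblique
#' lines and helices) in a 72 x 72 x 72 voxel anisotropic volume
#' (0.5 x 0.4 x 0.4 um voxels), tube width 3 px, peak 0.9 over a 0.05
#' background. These are the study conditions used by the validation suite.
#'
#' @param i phantom index (also seeds the noise).
#' @param noise_sd additive Gaussian noise SD (0 = noise free; 0.17 gives
#'   peak SNR ~ 5).
#' @param shape volume dimensions `(nz, ny, nx)`.
#' @return A [phantom_spec()].
#' @export
benchmark_phantom_spec <- function(i, noise_sd = 0, shape = c(72L, 72L, 72L)) {
  vox <- c(0.5, 0.4, 0.4)
  extent <- rev(shape) * rev(vox)            # (x, y, z) um
  mid <- extent / 2
  if (i %% 2L == 1L) {
    # oblique line, direction varying with i, kept clear of the faces
    ang <- (i * 37) %% 360 * pi / 180
    dir <- c(cos(ang), sin(ang) * 0.6, 0.45 + 0.1 * ((i %% 3) - 1))
    dir <- dir / sqrt(sum(dir^2))
    half <- 0.42 * min(extent)
    cv <- curve_line(mid - half * dir, mid + half * dir)
  } else {
    cv <- curve_helix(center = c(mid[1], mid[2], 0.22 * extent[3]),
                      radius_um = 0.26 * min(extent[1:2]),
                      pitch_um = 0.28 * extent[3], turns = 2,
                      phase = i * pi / 5)
  }
  phantom_spec(shape, vox, list(cv), background = 0.05,
               noise_sd = noise_sd, seed = 1000L + i)
}

#' Tracing parameters used for the benchmark phantoms
#'
#' Chosen for 3 px wide tubes: smoothing at 2 px preserves the tube
#' cross-section. The seed-stage intensity band is the method's one
#' interactive step and depends on the image: its lower edge sits at the
#' ceiling of the projected background, `background + 3.5 * noise_sd`
#' (a maximum projection over many planes lifts the background floor to
#' roughly the upper tail of the per-voxel noise), with a floor of 0.2 for
#' clean images. Marches terminate below twice the effective background
#' level; with noise the detector's zero clip inflates that level from
#' `b` to `E[max(b + noise, 0)] = b * pnorm(b / s) + s * dnorm(b / s)`.
#'
#' @param noise_sd the additive noise level of the stack being traced.
#' @param background the stack's background level.
#' @return A list with elements `seed` (a [seed_params()]) and `tracer`
#'   (a [tracer_params()]).
#' @export
benchmark_trace_params <- function(noise_sd = 0, background = 0.05) {
  lower <- max(0.2, background + 3.5 * noise_sd)
  bg_eff <- if (noise_sd > 0)
    background * stats::pnorm(background / noise_sd) +
      noise_sd * stats::dnorm(background / noise_sd)
  else background
  list(seed = seed_params(lower, 1, window_n = 5L),
       tracer = tracer_params(sigma = 2, step_size = 1,
                              min_intensity = 2 * bg_eff, max_steps = 600L))
}

#' Run the phantom-tracing benchmark
#'
#' Renders `n` standard phantoms, traces each end to end and measures
#' accuracy against the analytic centerlines.
#'
#' @param n number of phantoms.
#' @param noise_sd additive Gaussian noise SD.
#' @param tol_voxels coverage tolerance in voxels.
#' @param seed_offset added to the phantom index for replicate families.
#' @return A `data.frame` with one row per phantom: `coverage`,
#'   `mean_deviation_voxels`, `traced_length_um`, `truth_length_um`,
#'   `density`, `true_density`.
#' @export
phantom_benchmark <- function(n = 10L, noise_sd = 0, tol_voxels = 2,
                              seed_offset = 0L) {
  pars <- benchmark_trace_params(noise_sd)
  rows <- lapply(seq_len(n), function(i) {
    ph <- make_phantom(benchmark_phantom_spec(i + seed_offset, noise_sd))
    traces <- trace_all(ph$stack, pars$seed, pars$tracer)
    acc <- trace_accuracy(traces, ph, tol_voxels = tol_voxels)
    data.frame(coverage = acc$coverage,
               mean_deviation_voxels = acc$mean_deviation_voxels,
               traced_length_um = acc$traced_length_um,
               truth_length_um = acc$truth_length_um,
               density = axon_density(traces, ph$stack),
               true_density = ph$total_length / stack_volume_um3(ph$stack))
  })
  do.call(rbind, rows)
}

#' Run the mixture-recovery benchmark
#'
#' Draws seeded replicates from a three-component Gaussian mixture
#' (fractions 0.31 / 0.41 / 0.28, centres -5 / -12 / -22, widths 2 — well
#' separated small/medium/large populations on an inward-current scale),
#' fits 1-4 components with [select_model()] and scores the recovery.
#'
#' @param n_rep number of replicates.
#' @param n samples per replicate.
#' @param seed base RNG seed.
#' @return A `data.frame` with one row per replicate: `k_selected`,
#'   `center_error_bins` (median |centre error| in bin widths),
#'   `fraction_error` (max |fraction error|), `chi2_nonincreasing`.
#' @export
mixture_benchmark <- function(n_rep = 100L, n = 5000L, seed = 1L) {
  fractions <- c(0.31, 0.41, 0.28)
  centers <- c(-5, -12, -22)
  widths <- c(2, 2, 2)
  rows <- lapply(seq_len(n_rep), function(r) {
    spec <- mixture_spec(fractions, centers, widths, n = n,
                         seed = seed * 10000L + r)
    x <- sample_mixture(spec)
    h <- build_histogram(x)
    fit <- select_model(h)
    trail <- fit$trail$chi_square
    noninc <- all(diff(trail) <= 1e-8 * trail[-length(trail)] + 1e-12)
    if (fit$k == 3L) {
      perm_err <- abs(sort(fit$components$xc) - sort(centers))
      frac_fit <- component_fractions(fit)[order(fit$components$xc)]
      frac_err <- max(abs(frac_fit - fractions[order(centers)]))
      cen_err <- median(perm_err) / h$bin_width
    } else {
      cen_err <- NA_real_
      frac_err <- NA_real_
    }
    data.frame(k_selected = fit$k, center_error_bins = cen_err,
               fraction_error = frac_err, chi2_nonincreasing = noninc)
  })
  do.call(rbind, rows)
}

#' Run the mEPSC event-pipeline benchmark
#'
#' Synthesises a seeded 10 Hz / 100 s trace with the default amplitude
#' mixture and kinetics, detects events at -4 pA and matches detections to
#' the ground truth within 1 ms.
#'
#' @param rate,duration generator rate (Hz) and duration (s).
#' @param threshold detection threshold in pA.
#' @param seed RNG seed.
#' @return A list: `n_true`, `n_detected`, `median_amp_error` (relative),
#'   `measured_rate_hz`, `events` (feature table), `truth`.
#' @export
mepsc_benchmark <- function(rate = 10, duration = 100, threshold = -4,
                            seed = 1L) {
  sim <- synth_mepsc_trace(rate, duration, seed = seed)
  ev <- extract_events(sim$trace, threshold = threshold,
                       peak_smooth_ms = 0.2)
  truth <- sim$events
  amp_err <- rep(NA_real_, nrow(ev))
  if (nrow(ev) && nrow(truth)) {
    for (i in seq_len(nrow(ev))) {
      j <- which.min(abs(truth$peak_s - ev$time_s[i]))
      if (abs(truth$peak_s[j] - ev$time_s[i]) <= 1e-3)
        amp_err[i] <- abs(ev$peak_amplitude_pA[i] - truth$amplitude_pA[j]) /
          abs(truth$amplitude_pA[j])
    }
  }
  list(n_true = nrow(truth), n_detected = nrow(ev),
       median_amp_error = median(amp_err, na.rm = TRUE),
       measured_rate_hz = nrow(ev) / duration,
       events = ev, truth = truth)
}
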