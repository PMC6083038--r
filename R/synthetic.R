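# Ground-truthed generators: tubular image phantoms for the tracer,
# Gaussian-mixture samples for the histogram decomposition, and synthetic
# mEPSC traces for the event pipeline. All generators are pure functions of
# their spec: the same spec and seed reproduce identical output.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# -- parametric curves ----------------------------------------------------

#' Tube curve primitives for image phantoms
#'
#' Parametric 3D centerlines, each carrying the tube's Gaussian
#' cross-section width (pixels) and peak intensity. Coordinates are
#' physical (um).
#'
#' @param from,to line endpoints, `(x, y, z)` um.
#' @param width_px tube width `w` in pixels (the rendered radial profile is
#'   `exp(-2 d^2 / w^2)`); at least 2 px so the tube is resolvable.
#' @param peak peak intensity on the centerline, in `(0, 1]`.
#' @return A `phantom_curve` object.
#' @export
curve_line <- function(from, to, width_px = 3, peak = 0.9) {
  new_curve("line", list(from = as.numeric(from), to = as.numeric(to)),
            width_px, peak)
}

#' @rdname curve_line
#' @param center helix axis centre `(x, y, z)` um; the helix axis is z.
#' @param radius_um,pitch_um,turns helix radius, pitch (axial advance per
#'   turn) and number of turns.
#' @param phase starting angle in radians.
#' @export
curve_helix <- function(center, radius_um, pitch_um, turns, phase = 0,
                        width_px = 3, peak = 0.9) {
  new_curve("helix", list(center = as.numeric(center), radius = radius_um,
                          pitch = pitch_um, turns = turns, phase = phase),
            width_px, peak)
}

#' @rdname curve_line
#' @param control 4 x 3 matrix of cubic Bezier control points, um.
#' @export
curve_bezier <- function(control, width_px = 3, peak = 0.9) {
  control <- as.matrix(control)
  stopifnot(nrow(control) == 4L, ncol(control) == 3L)
  new_curve("bezier", list(control = control), width_px, peak)
}

new_curve <- function(type, geom, width_px, peak) {
  if (width_px < 2) stop_user("tube width must be at least 2 px")
  if (peak <= 0 || peak > 1) stop_user("'peak' must be in (0, 1]")
  structure(c(list(type = type, width_px = width_px, peak = peak), geom),
            class = "phantom_curve")
}

# dense polyline (um) along a curve; spacing is approximate arc spacing
curve_points <- function(curve, spacing_um = 0.2) {
  switch(curve$type,
    line = {
      len <- sqrt(sum((curve$to - curve$from)^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(len / spacing_um) + 1L))
      outer(1 - t, curve$from) + outer(t, curve$to)
    },
    helix = {
      total <- 2 * pi * curve$turns
      arc <- curve$turns * sqrt((2 * pi * curve$radius)^2 + curve$pitch^2)
      t <- seq(0, total, length.out = max(2L, ceiling(arc / spacing_um) + 1L))
      cbind(curve$center[1] + curve$radius * cos(t + curve$phase),
            curve$center[2] + curve$radius * sin(t + curve$phase),
            curve$center[3] + curve$pitch * t / (2 * pi))
    },
    bezier = {
      t <- seq(0, 1, length.out = 2048L)
      b <- cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
      b %*% curve$control
    },
    stop_user("unknown curve type: ", curve$type))
}

#' Arc length of a phantom curve
#'
#' Closed form for lines (`|to - from|`) and helices
#' (`turns * sqrt((2 pi R)^2 + pitch^2)`); numeric polyline integration at
#' 0.05 um resolution (accurate to well under 0.1%) for Bezier curves.
#'
#' @param curve a `phantom_curve`.
#' @return Length in um.
#' @export
curve_length <- function(curve) {
  switch(curve$type,
    line = sqrt(sum((curve$to - curve$from)^2)),
    helix = curve$turns * sqrt((2 * pi * curve$radius)^2 + curve$pitch^2),
    bezier = sum(sqrt(rowSums(diff(curve_points(curve, 0.05))^2))))
}

# -- phantom rendering ----------------------------------------------------

#' Phantom volume specification
#'
#' Describes a synthetic confocal stack containing tubular structures with
#' known centerlines: the radial intensity profile of each tube is
#' `peak * exp(-2 d^2 / w^2)` with `d` the distance to the centerline in
#' pixel units, the same Gaussian form used by the mixture fitting, so the
#' Hessian eigenvalues on a tube axis have a closed form. Overlapping tubes
#' blend by maximum. Optional Gaussian read noise and Poisson shot noise are
#' applied after rendering; intensities are clipped to `[0, 1]`
#' (detector range).
#'
#' @param shape volume dimensions `(nz, ny, nx)` in voxels.
#' @param voxel_size `(dz, dy, dx)` in um; the default reflects confocal
#'   acquisition (0.5 um optical sections, 0.4 um lateral).
#' @param curves list of [curve_line()] / [curve_helix()] / [curve_bezier()]
#'   objects; all centerlines must lie inside the volume.
#' @param background background intensity level.
#' @param noise_sd additive Gaussian noise SD (0 = none).
#' @param poisson_scale photons per intensity unit for Poisson shot noise
#'   (0 = none).
#' @param seed RNG seed; a fixed spec and seed give byte-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_size = c(0.5, 0.4, 0.4), curves,
                         background = 0.05, noise_sd = 0, poisson_scale = 0,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L))
  if (inherits(curves, "phantom_curve")) curves <- list(curves)
  if (!length(curves)) stop_user("'curves' must contain at least one curve")
  extent <- rev(shape) * rev(voxel_size)     # (x, y, z) um
  for (cv in curves) {
    pts <- curve_points(cv, spacing_um = 1)
    if (any(pts < 0) || any(sweep(pts, 2L, extent) > 0))
      stop_user("curve leaves the volume: extents are ",
                paste(signif(extent, 4), collapse = " x "), " um (x, y, z)")
  }
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 curves = curves, background = background,
                 noise_sd = noise_sd, poisson_scale = poisson_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# render one curve into `vol` (max blending); px coordinates are continuous
# 0-based voxel indices
render_curve <- function(vol, curve, voxel_size) {
  d <- dim(vol)                               # (nz, ny, nx)
  vox <- rev(voxel_size)                      # (dx, dy, dz)
  pts_um <- curve_points(curve, spacing_um = 0.5 * min(voxel_size))
  pts <- sweep(pts_um, 2L, vox, `/`) - 0.5    # now in pixel space
  w <- curve$width_px
  rcut <- 3 * w
  dims <- rev(d)                              # (nx, ny, nz)
  for (i in seq_len(nrow(pts) - 1L)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
    lo <- pmax(floor(pmin(p0, p1) - rcut), 0)
    hi <- pmin(ceiling(pmax(p0, p1) + rcut), dims - 1)
    if (any(hi < lo)) next
    g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    v <- p1 - p0
    L2 <- sum(v^2)
    px <- g$x - p0[1]; py <- g$y - p0[2]; pz <- g$z - p0[3]
    t <- if (L2 > 0) pmin(pmax((px * v[1] + py * v[2] + pz * v[3]) / L2, 0), 1)
         else 0
    d2 <- (px - t * v[1])^2 + (py - t * v[2])^2 + (pz - t * v[3])^2
    val <- curve$peak * exp(-2 * d2 / w^2)
    idx <- cbind(g$z + 1L, g$y + 1L, g$x + 1L)
    cur <- vol[idx]
    upd <- val > cur
    if (any(upd)) vol[idx[upd, , drop = FALSE]] <- val[upd]
  }
  vol
}

#' Render a tubular image phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom`: `stack` (a [confocal_stack()]),
#'   `centerlines` (list of dense polylines in um), `lengths` (analytic arc
#'   lengths, um) and `total_length` (um).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    vol <- array(0, spec$shape)
    for (cv in spec$curves) vol <- render_curve(vol, cv, spec$voxel_size)
    vol <- vol + spec$background
    if (spec$poisson_scale > 0)
      vol <- array(rpois(length(vol), vol * spec$poisson_scale) /
                     spec$poisson_scale, dim(vol))
    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), sd = spec$noise_sd), dim(vol))
    vol <- pmin(pmax(vol, 0), 1)
    dim(vol) <- spec$shape
    stack <- confocal_stack(vol, spec$voxel_size, name = "phantom")
    lengths <- vapply(spec$curves, curve_length, numeric(1))
    structure(list(stack = stack,
                   centerlines = lapply(spec$curves, curve_points,
                                        spacing_um = 0.1),
                   lengths = lengths,
                   total_length = sum(lengths)),
              class = "phantom")
  })
}

# -- mixture samples ------------------------------------------------------

#' Gaussian-mixture sample specification
#'
#' Emulates populations of small, medium and large synapses (or quantal
#' amplitudes): each component has a population fraction, a centre and a
#' width `w` in the same convention as [gauss_sum()] (the component's
#' standard deviation is `w / 2`).
#'
#' @param fractions component fractions, summing to 1.
#' @param centers component centres.
#' @param widths component widths `w` (> 0).
#' @param n number of samples.
#' @param seed RNG seed.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(fractions, centers, widths, n, seed = 1L) {
  fractions <- as.numeric(fractions)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_user("component fractions must sum to 1")
  if (any(fractions < 0)) stop_user("fractions must be non-negative")
  if (any(widths <= 0)) stop_user("widths must be > 0")
  stopifnot(length(centers) == length(fractions),
            length(widths) == length(fractions))
  structure(list(fractions = fractions, centers = as.numeric(centers),
                 widths = as.numeric(widths), n = as.integer(n),
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Draw samples from a Gaussian mixture
#'
#' @param spec a [mixture_spec()].
#' @return Numeric vector of `n` draws with an attribute `component` giving
#'   each draw's generating component.
#' @export
sample_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  with_seed(spec$seed, draw_mixture(spec))
}

# draws using the current RNG state (for callers that manage the seed)
draw_mixture <- function(spec) {
  n <- spec$n
  if (n == 0L) {
    out <- numeric(0)
    attr(out, "component") <- integer(0)
    return(out)
  }
  comp <- sample.int(length(spec$fractions), n, replace = TRUE,
                     prob = spec$fractions)
  out <- rnorm(n, mean = spec$centers[comp], sd = spec$widths[comp] / 2)
  attr(out, "component") <- comp
  out
}

# -- synthetic mEPSC traces ----------------------------------------------

#' Synthesise a miniature-EPSC current trace
#'
#' Events occur at Poisson times; each event is a difference-of-exponentials
#' waveform (one rising, two decaying exponentials) normalised to unit peak
#' and scaled by an amplitude drawn from a Gaussian mixture; Gaussian
#' current noise is added. Inward events are negative.
#'
#' @param rate mean event rate in Hz (>= 0).
#' @param duration trace duration in s.
#' @param amplitude_spec a [mixture_spec()] of signed peak amplitudes in pA
#'   (its `n` and `seed` fields are ignored; draws use this function's RNG
#'   stream).
#' @param kinetics list with `rise_ms`, `decay1_ms`, `decay2_ms` and
#'   `split` (fraction of the decay carried by the fast component). The
#'   defaults (0.3 / 2 / 8 ms, split 0.5) give the 5 ms weighted decay
#'   typical of these synapses.
#' @param noise_sd Gaussian current-noise SD in pA.
#' @param sampling_rate sampling rate in Hz (default 20 kHz).
#' @param seed RNG seed.
#' @return A list: `trace` (a [current_trace()]) and `events` (ground-truth
#'   `data.frame` with `onset_s`, `peak_s`, `amplitude_pA`).
#' @export
synth_mepsc_trace <- function(rate, duration,
                              amplitude_spec = mixture_spec(
                                c(0.23, 0.50, 0.27), c(-6, -10, -16),
                                c(2, 3, 4), n = 1L),
                              kinetics = list(rise_ms = 0.3, decay1_ms = 2,
                                              decay2_ms = 8, split = 0.5),
                              noise_sd = 0.8, sampling_rate = 20000,
                              seed = 1L) {
  if (rate < 0) stop_user("'rate' must be >= 0")
  fs <- sampling_rate
  n <- as.integer(round(duration * fs))
  with_seed(seed, {
    samples <- if (noise_sd > 0) rnorm(n, sd = noise_sd) else numeric(n)
    pad <- 6 * kinetics$decay2_ms / 1000 + 5 * kinetics$rise_ms / 1000
    n_ev <- rpois(1L, rate * max(0, duration - pad))
    truth <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                        amplitude_pA = numeric(0))
    if (n_ev > 0) {
      t_ms <- (0:ceiling(pad * fs)) / fs * 1000
      shape <- kinetics$split * exp(-t_ms / kinetics$decay1_ms) +
        (1 - kinetics$split) * exp(-t_ms / kinetics$decay2_ms) -
        exp(-t_ms / kinetics$rise_ms)
      shape <- shape / max(shape)
      onsets <- sort(round(runif(n_ev, 0, duration - pad) * fs)) + 1L
      amp_spec <- amplitude_spec
      amp_spec$n <- n_ev
      amps <- as.numeric(draw_mixture(amp_spec))
      for (e in seq_len(n_ev)) {
        idx <- onsets[e] + seq_along(shape) - 1L
        samples[idx] <- samples[idx] + amps[e] * shape
      }
      truth <- data.frame(
        onset_s = (onsets - 1L) / fs,
        peak_s = (onsets - 1L + which.max(shape) - 1L) / fs,
        amplitude_pA = amps)
    }
    list(trace = current_trace(samples, fs), events = truth)
  })
}
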