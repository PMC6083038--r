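# Stage two of the tracer: recursive 3D vectorial tracking. The smoothed
# volume's local Hessian identifies tubular structure; the eigenvector of
# the smallest-magnitude eigenvalue points along the axon; a medial
# correction in the plane normal to the march keeps nodes on the centerline.
#
# All geometry here is in continuous 0-based voxel (pixel) coordinates in
# (x, y, z) order; conversion to um happens only when a trace is emitted.

#' Vectorial-tracking parameters
#'
#' @param sigma Gaussian smoothing scale in pixels. The default of 5 px
#'   suits noisy confocal data; smaller scales preserve thin, closely
#'   apposed axons at the cost of noise sensitivity.
#' @param hessian_window cubic neighbourhood edge in pixels used for the
#'   local Hessian and the medial search disc; 9 px captures an axon's full
#'   cross-section plus surrounding background.
#' @param step_size march step in pixels (default 1; small steps keep the
#'   medial correction's search disc local).
#' @param tubularity_ratio_min minimum `min(|l2|,|l3|)/max(|l2|,|l3|)` for a
#'   point to count as tubular (operationalises `l2 ~ l3`).
#' @param tubularity_flatness_max maximum `|l1|/|l3|` (operationalises
#'   `l1 ~ 0` against `l3 << 0`).
#' @param min_intensity smoothed-intensity floor below which a march
#'   terminates. `NULL` means "decided by the caller": [trace_all()]
#'   substitutes the seed stage's `lower_threshold`, [trace_from_seed()]
#'   substitutes 0 (no intensity termination).
#' @param max_steps maximum march steps per direction.
#' @param min_nodes traces with fewer nodes than this are discarded by
#'   [trace_all()] as spurious (default 3).
#' @return An object of class `tracer_params`.
#' @export
tracer_params <- function(sigma = 5, hessian_window = 9L, step_size = 1,
                          tubularity_ratio_min = 0.5,
                          tubularity_flatness_max = 0.25,
                          min_intensity = NULL, max_steps = 2000L,
                          min_nodes = 3L) {
  if (!is.numeric(sigma) || sigma <= 0) stop_user("'sigma' must be > 0")
  hessian_window <- as.integer(hessian_window)
  if (is.na(hessian_window) || hessian_window < 3L || hessian_window %% 2L == 0L)
    stop_user("'hessian_window' must be an odd integer >= 3")
  if (!is.numeric(step_size) || step_size <= 0)
    stop_user("'step_size' must be > 0")
  if (max_steps < 1L) stop_user("'max_steps' must be >= 1")
  structure(list(sigma = sigma, hessian_window = hessian_window,
                 step_size = step_size,
                 tubularity_ratio_min = tubularity_ratio_min,
                 tubularity_flatness_max = tubularity_flatness_max,
                 min_intensity = min_intensity,
                 max_steps = as.integer(max_steps),
                 min_nodes = as.integer(min_nodes)),
            class = "tracer_params")
}

# reflective (edge-repeating) index mapping for out-of-range indices
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  repeat {
    under <- i < 1L
    over <- i > n
    if (!any(under) && !any(over)) return(i)
    i[under] <- 1L - i[under]
    i[over] <- 2L * n + 1L - i[over]
  }
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# convolve a 3D array with a 1D kernel along one axis, reflective boundaries
convolve_axis <- function(vol, kernel, axis) {
  n <- dim(vol)[axis]
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(vol))
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- reflect_idx(seq_len(n) + off, n)
    shifted <- switch(axis,
                      vol[idx, , , drop = FALSE],
                      vol[, idx, , drop = FALSE],
                      vol[, , idx, drop = FALSE])
    out <- out + kernel[j] * shifted
  }
  out
}

#' Gaussian smoothing of an image volume
#'
#' Convolves the stack with an isotropic-in-pixels Gaussian kernel
#' (separable, reflective boundary handling). Smoothing makes the sampled
#' intensity field differentiable in practice, which the Hessian analysis
#' requires; the kernel is normalised so total intensity is conserved away
#' from boundaries.
#'
#' @param stack a [confocal_stack()] or a plain 3D array.
#' @param sigma kernel scale in pixels, > 0.
#' @return A 3D array of the same shape as the input grid.
#' @export
smooth_volume <- function(stack, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_user("'sigma' must be a single value > 0")
  vol <- if (inherits(stack, "confocal_stack")) stack$intensities else stack
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop_user("'stack' must be a confocal_stack or a 3D array")
  k <- gauss_kernel_1d(sigma)
  for (axis in 1:3) vol <- convolve_axis(vol, k, axis)
  vol
}

# trilinear interpolation of a (z, y, x) array at n x 3 (x, y, z) 0-based
# continuous positions; positions are clamped to the valid cell range
trilinear <- function(vol, pts) {
  d <- dim(vol)                       # (nz, ny, nx)
  pts <- matrix(pts, ncol = 3L)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  x0 <- pmin(pmax(floor(pts[, 1]), 0), nx - 2L)
  y0 <- pmin(pmax(floor(pts[, 2]), 0), ny - 2L)
  z0 <- pmin(pmax(floor(pts[, 3]), 0), nz - 2L)
  fx <- pts[, 1] - x0; fy <- pts[, 2] - y0; fz <- pts[, 3] - z0
  val <- numeric(nrow(pts))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) fx else 1 - fx) * (if (cy) fy else 1 - fy) *
      (if (cz) fz else 1 - fz)
    val <- val + w * vol[cbind(z0 + cz + 1, y0 + cy + 1, x0 + cx + 1)]
  }
  val
}

# stack dims in (x, y, z) order for a (z, y, x) array
dims_xyz <- function(vol) rev(dim(vol))

in_margin <- function(point, dims, margin) {
  all(point >= margin) && all(point <= dims - 1 - margin)
}

#' Local Hessian eigen-system of a smoothed volume
#'
#' Estimates the symmetric 3x3 matrix of second-order partial derivatives of
#' the smoothed intensity field at a (possibly fractional) voxel position,
#' using 4th-order-accurate central finite-difference stencils sampled from
#' the surrounding window, and returns its eigenvalues sorted by ascending
#' magnitude together with the matching orthonormal eigenvectors. On a
#' bright tube the two large-magnitude eigenvalues are negative and
#' cross-sectional, while the smallest-magnitude eigenvalue's eigenvector
#' points along the tube.
#'
#' @param G smoothed 3D array (from [smooth_volume()]) or a
#'   [confocal_stack()] whose intensities are already smooth.
#' @param point numeric `(x, y, z)` 0-based voxel position, at least
#'   `window / 2` voxels from every face.
#' @param window neighbourhood edge in pixels (default 9).
#' @return A list of class `hessian_eigen` with `values` (ascending `|l|`),
#'   `vectors` (matching columns, `(x, y, z)` components), and the Hessian
#'   matrix `H` in units of intensity per pixel^2.
#' @export
hessian_eigen <- function(G, point, window = 9L) {
  vol <- if (inherits(G, "confocal_stack")) G$intensities else G
  point <- as.numeric(point)
  dims <- dims_xyz(vol)
  margin <- floor(window / 2)
  if (!in_margin(point, dims, margin))
    stop_boundary("point is closer than window/2 = ", margin,
                  " voxels to a volume face")
  # 4th-order stencils: f'' ~ (-1 16 -30 16 -1)/12, f' ~ (1 -8 8 -1)/12
  c2 <- c(-1, 16, -30, 16, -1) / 12
  d1 <- c(1, -8, 8, -1) / 12
  off2 <- -2:2
  off1 <- c(-2L, -1L, 1L, 2L)
  ax <- diag(3)
  pts <- point                        # row 1: centre
  for (a in 1:3) for (k in off2[off2 != 0])
    pts <- rbind(pts, point + k * ax[a, ])
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (pr in pairs) for (i in off1) for (j in off1)
    pts <- rbind(pts, point + i * ax[pr[1], ] + j * ax[pr[2], ])
  g <- trilinear(vol, pts)
  H <- matrix(0, 3, 3)
  centre <- g[1]
  row <- 1L
  for (a in 1:3) {
    vals <- c(g[row + 1L], g[row + 2L], centre, g[row + 3L], g[row + 4L])
    H[a, a] <- sum(c2 * vals)
    row <- row + 4L
  }
  for (pr in pairs) {
    acc <- 0
    for (i in seq_along(off1)) for (j in seq_along(off1)) {
      row <- row + 1L
      acc <- acc + d1[i] * d1[j] * g[row]
    }
    H[pr[1], pr[2]] <- H[pr[2], pr[1]] <- acc
  }
  es <- eigen(H, symmetric = TRUE)
  ord <- order(abs(es$values))
  structure(list(values = es$values[ord],
                 vectors = es$vectors[, ord, drop = FALSE],
                 H = H, point = point),
            class = "hessian_eigen")
}

#' Tubularity test on a Hessian eigen-system
#'
#' A point lies on a bright tubular structure when `l2 ~ l3 << 0` and
#' `l1 ~ 0` (eigenvalues sorted by ascending magnitude). The approximate
#' relations are operationalised with two scale-free ratios: flatness
#' `|l1| / |l3| <= tubularity_flatness_max` and cross-sectional isotropy
#' `min(|l2|, |l3|) / max(|l2|, |l3|) >= tubularity_ratio_min`.
#'
#' @param eig a [hessian_eigen()] result.
#' @param params a [tracer_params()].
#' @return `TRUE` iff the point qualifies as tubular.
#' @export
is_tubular <- function(eig, params) {
  l <- eig$values
  if (!(l[2] < 0 && l[3] < 0)) return(FALSE)
  a2 <- abs(l[2]); a3 <- abs(l[3])
  if (a3 == 0) return(FALSE)
  abs(l[1]) / a3 <= params$tubularity_flatness_max &&
    min(a2, a3) / max(a2, a3) >= params$tubularity_ratio_min
}

unit <- function(v) v / sqrt(sum(v^2))

# orthonormal basis (u, v) of the plane normal to a unit direction d
normal_plane_basis <- function(d) {
  e <- diag(3)[, which.min(abs(d))]
  u <- unit(pracma_cross(d, e))
  v <- pracma_cross(d, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Medial-axis correction of a tracking node
#'
#' Samples the smoothed volume on a discrete disc in the plane through
#' `point` normal to `direction` and moves the node to the in-plane position
#' of maximal interpolated intensity. Because the volume is
#' Gaussian-smoothed, that maximum sits on the axon's centerline, so the
#' correction keeps the march on the medial axis. Ties (e.g. in a constant
#' volume) resolve to the most central candidate.
#'
#' @param G smoothed 3D array or [confocal_stack()].
#' @param point `(x, y, z)` 0-based voxel position.
#' @param direction unit `(x, y, z)` vector along the local axon axis.
#' @param radius search-disc radius in pixels (default: half the 9-px
#'   Hessian window).
#' @param spacing disc sampling pitch in pixels; the discrete maximum is
#'   refined to sub-pixel precision by a separable parabolic fit through its
#'   in-plane neighbours.
#' @return Corrected `(x, y, z)` position.
#' @export
medial_correct <- function(G, point, direction, radius = 4.5, spacing = 0.5) {
  vol <- if (inherits(G, "confocal_stack")) G$intensities else G
  point <- as.numeric(point)
  direction <- unit(as.numeric(direction))
  basis <- normal_plane_basis(direction)
  grid1 <- seq(-radius, radius, by = spacing)
  grid <- expand.grid(s = grid1, t = grid1)
  grid <- grid[grid$s^2 + grid$t^2 <= radius^2 + 1e-9, ]
  grid <- grid[order(grid$s^2 + grid$t^2), ]        # centre first: tie-break
  plane_pt <- function(s, t)
    cbind(point[1] + s * basis$u[1] + t * basis$v[1],
          point[2] + s * basis$u[2] + t * basis$v[2],
          point[3] + s * basis$u[3] + t * basis$v[3])
  pts <- plane_pt(grid$s, grid$t)
  dims <- dims_xyz(vol)
  ok <- pts[, 1] >= 0 & pts[, 1] <= dims[1] - 1 &
    pts[, 2] >= 0 & pts[, 2] <= dims[2] - 1 &
    pts[, 3] >= 0 & pts[, 3] <= dims[3] - 1
  if (!any(ok))
    stop_boundary("medial search disc lies fully outside the volume")
  vals <- rep(-Inf, nrow(pts))
  vals[ok] <- trilinear(vol, pts[ok, , drop = FALSE])
  best <- which.max(vals)
  s0 <- grid$s[best]; t0 <- grid$t[best]
  # parabolic sub-pixel refinement along each in-plane axis
  refine <- function(o, vm, vc, vp) {
    if (!all(is.finite(c(vm, vc, vp)))) return(o)
    den <- vm - 2 * vc + vp
    if (den >= 0) return(o)                          # not a local peak
    o + 0.5 * spacing * (vm - vp) / den
  }
  nb <- plane_pt(c(s0 - spacing, s0 + spacing, s0, s0),
                 c(t0, t0, t0 - spacing, t0 + spacing))
  nb_ok <- nb[, 1] >= 0 & nb[, 1] <= dims[1] - 1 &
    nb[, 2] >= 0 & nb[, 2] <= dims[2] - 1 &
    nb[, 3] >= 0 & nb[, 3] <= dims[3] - 1
  nv <- rep(NA_real_, 4L)
  if (any(nb_ok)) nv[nb_ok] <- trilinear(vol, nb[nb_ok, , drop = FALSE])
  s1 <- refine(s0, nv[1], vals[best], nv[2])
  t1 <- refine(t0, nv[3], vals[best], nv[4])
  if (s1^2 + t1^2 > radius^2) { s1 <- s0; t1 <- t0 }
  drop(plane_pt(s1, t1))
}

# -- tracking ------------------------------------------------------------

# march from `start` along `dir0`; returns list(points = matrix of (x,y,z)
# pixel nodes excluding the start, reason, claimed = matrix of voxel indices
# claimed during this march)
march <- function(G, start, dir0, params, claim, id, own_recent) {
  dims <- dims_xyz(G)
  margin <- floor(params$hessian_window / 2)
  pts <- matrix(numeric(0), 0, 3)
  claimed <- matrix(integer(0), 0, 3)
  p <- start
  d <- dir0
  reason <- "max_steps"
  recent <- own_recent                 # last few voxels of the growing path
  for (step in seq_len(params$max_steps)) {
    pn <- p + params$step_size * d
    if (!in_margin(pn, dims, margin)) { reason <- "boundary"; break }
    pn <- tryCatch(
      medial_correct(G, pn, d, radius = params$hessian_window / 2),
      axonmap_boundary_error = function(e) NULL)
    if (is.null(pn) || !in_margin(pn, dims, margin)) {
      reason <- "boundary"; break
    }
    if (trilinear(G, pn) < params$min_intensity) {
      reason <- "intensity"; break
    }
    eig <- tryCatch(hessian_eigen(G, pn, params$hessian_window),
                    axonmap_boundary_error = function(e) NULL)
    if (is.null(eig)) { reason <- "boundary"; break }
    if (!is_tubular(eig, params)) { reason <- "tubularity"; break }
    v <- as.integer(round(pn)) + 1L    # 1-based (x, y, z) voxel index
    key <- claim[v[3], v[2], v[1]]
    visited_own <- any(recent[, 1] == v[1] & recent[, 2] == v[2] &
                         recent[, 3] == v[3])
    if (key != 0L && !(key == id && visited_own)) {
      reason <- "claimed"; break
    }
    if (key == id && !visited_own) { reason <- "loop"; break }
    if (key == 0L) {
      claim[v[3], v[2], v[1]] <- id
      claimed <- rbind(claimed, v)
    }
    recent <- rbind(recent, v)
    if (nrow(recent) > 3L) recent <- recent[-1L, , drop = FALSE]
    pts <- rbind(pts, pn)
    dn <- eig$vectors[, 1]
    if (sum(dn * d) < 0) dn <- -dn
    p <- pn
    d <- unit(dn)
  }
  list(points = pts, reason = reason, claimed = claimed)
}

px_to_um <- function(pts_px, stack) {
  v <- vox_xyz(stack)
  sweep(pts_px + 0.5, 2L, v, `*`)
}

um_to_px <- function(pts_um, stack) {
  v <- vox_xyz(stack)
  sweep(pts_um, 2L, v, `/`) - 0.5
}

# drop rows identical to their predecessor
dedupe_rows <- function(m) {
  if (nrow(m) < 2L) return(m)
  keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
  m[keep, , drop = FALSE]
}

#' Trace a single axon from a seed
#'
#' Marches bidirectionally from the seed: at each node the local Hessian
#' eigen-system is computed on the smoothed volume, the node must qualify as
#' tubular, the march advances `step_size` pixels along the minor
#' eigenvector (sign chosen to avoid reversal), and the node is re-centred
#' with [medial_correct()]. A march terminates on tubularity failure,
#' smoothed intensity below `min_intensity`, volume boundary, a voxel
#' already claimed by another trace, or `max_steps`.
#'
#' @param stack a [confocal_stack()].
#' @param seed a one-row data frame (or list/vector) with 0-based voxel
#'   indices `x`, `y`, `z`, e.g. one row of [select_seeds()] output.
#' @param params a [tracer_params()]; a `NULL` `min_intensity` falls back
#'   to 0 here.
#' @param G optional precomputed smoothed volume (recomputed when `NULL`).
#' @param claim optional integer (z, y, x) array of voxel ownership shared
#'   across traces; `id` is this trace's label in it.
#' @param id integer trace id used in `claim`.
#' @return An [axon_trace()] in um with a `termination` attribute naming
#'   the two marches' stopping reasons, or `NULL` when the seed itself fails
#'   the tubularity test (an empty trace, not an error).
#' @export
trace_from_seed <- function(stack, seed, params = tracer_params(),
                            G = NULL, claim = NULL, id = 1L) {
  stopifnot(inherits(stack, "confocal_stack"))
  assert_traceable(stack)
  if (is.data.frame(seed)) seed <- as.list(seed[1, ])
  if (is.atomic(seed)) seed <- list(x = seed[1], y = seed[2], z = seed[3])
  p0 <- as.numeric(c(seed$x, seed$y, seed$z))
  if (length(p0) != 3L || any(!is.finite(p0)))
    stop_user("'seed' must provide x, y, z voxel indices")
  dims <- dims_xyz(stack$intensities)
  if (any(p0 < 0) || any(p0 > dims - 1)) stop_user("seed out of stack bounds")
  if (is.null(G)) G <- smooth_volume(stack, params$sigma)
  if (is.null(params$min_intensity)) params$min_intensity <- 0
  if (is.null(claim)) claim <- new_claim(stack)
  margin <- floor(params$hessian_window / 2)
  if (!in_margin(p0, dims_xyz(G), margin)) return(NULL)
  eig0 <- hessian_eigen(G, p0, params$hessian_window)
  if (!is_tubular(eig0, params)) return(NULL)
  v0 <- as.integer(round(p0)) + 1L
  own0 <- matrix(v0, 1L, 3L)
  claimed0 <- matrix(integer(0), 0, 3)
  if (claim[v0[3], v0[2], v0[1]] == 0L) {
    claim[v0[3], v0[2], v0[1]] <- id
    claimed0 <- own0
  }
  d0 <- unit(eig0$vectors[, 1])
  fwd <- march(G, p0, d0, params, claim, id, own0)
  bwd <- march(G, p0, -d0, params, claim, id, own0)
  pts_px <- dedupe_rows(rbind(bwd$points[rev(seq_len(nrow(bwd$points))), ,
                                         drop = FALSE],
                              matrix(p0, 1L, 3L), fwd$points))
  tr <- axon_trace(px_to_um(pts_px, stack),
                   seed_index = if (!is.null(seed$index)) seed$index else id)
  attr(tr, "termination") <- c(backward = bwd$reason, forward = fwd$reason)
  attr(tr, "claimed") <- rbind(claimed0, fwd$claimed, bwd$claimed)
  attr(tr, "points_px") <- pts_px
  tr
}

# fresh claim array (an environment-free big.matrix substitute is not
# needed: arrays are modified in place via local functions below)
new_claim <- function(stack) array(0L, dim(stack))

# dilate claimed voxels by one voxel (26-neighbourhood), writing `id` into
# free cells only; returns the updated claim array
claim_dilate <- function(claim, voxels, id) {
  if (!nrow(voxels)) return(claim)
  d <- dim(claim)                      # (nz, ny, nx)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    x <- pmin(pmax(voxels[, 1] + dx, 1L), d[3])
    y <- pmin(pmax(voxels[, 2] + dy, 1L), d[2])
    z <- pmin(pmax(voxels[, 3] + dz, 1L), d[1])
    idx <- cbind(z, y, x)
    free <- claim[idx] == 0L
    if (any(free)) claim[idx[free, , drop = FALSE]] <- id
  }
  claim
}

#' Trace every axon in a stack
#'
#' Generates seeds with [select_seeds()], smooths the volume once, and
#' traces from each seed in descending distance-score order. Voxels claimed
#' by earlier traces (dilated by one voxel) suppress seeds and marches of
#' later, redundant traces, so each axon is traced once. Traces shorter than
#' `min_nodes` nodes are discarded.
#'
#' @param stack a [confocal_stack()].
#' @param seed_params a [seed_params()].
#' @param params a [tracer_params()]; a `NULL` `min_intensity` defaults to
#'   the seed stage's `lower_threshold` for consistency between stages.
#' @param verbose emit a per-run summary via `message()`.
#' @return A list of [axon_trace()] objects (possibly empty), with an
#'   attribute `termination` tabulating stopping reasons.
#' @export
trace_all <- function(stack, seed_params, params = tracer_params(),
                      verbose = FALSE) {
  stopifnot(inherits(stack, "confocal_stack"))
  seeds <- select_seeds(stack, seed_params)
  if (!nrow(seeds)) return(list())
  if (is.null(params$min_intensity))
    params$min_intensity <- seed_params$lower_threshold
  G <- smooth_volume(stack, params$sigma)
  claim <- new_claim(stack)
  traces <- list()
  reasons <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(seeds))) {
    v <- as.integer(c(seeds$x[i], seeds$y[i], seeds$z[i])) + 1L
    if (claim[v[3], v[2], v[1]] != 0L) { skipped <- skipped + 1L; next }
    id <- length(traces) + 1L
    seed <- c(as.list(seeds[i, ]), index = i)
    tr <- trace_from_seed(stack, seed, params, G = G, claim = claim, id = id)
    if (is.null(tr)) next
    claimed <- attr(tr, "claimed")
    if (nrow(tr$points) < params$min_nodes) {
      if (nrow(claimed)) claim[claimed[, c(3, 2, 1), drop = FALSE]] <- 0L
      next
    }
    claim <- claim_dilate(claim, claimed, id)
    reasons <- c(reasons, attr(tr, "termination"))
    attr(tr, "claimed") <- NULL
    traces[[id]] <- tr
  }
  traces <- traces[!vapply(traces, is.null, logical(1))]
  if (verbose)
    message(sprintf("trace_all: %d seeds, %d suppressed, %d traces emitted",
                    nrow(seeds), skipped, length(traces)))
  attr(traces, "termination") <- table(reasons)
  traces
}

#' Axonal density of a set of traces
#'
#' Total traced centerline length divided by the stack's physical volume,
#' the standard summary for projection-density mapping.
#'
#' @param traces list of [axon_trace()] objects (may be empty).
#' @param stack the [confocal_stack()] the traces came from.
#' @return Density in um of axon per um^3 of tissue.
#' @export
axon_density <- function(traces, stack) {
  vol <- stack_volume_um3(stack)
  if (vol <= 0) stop_user("stack has zero physical volume")
  if (!length(traces)) return(0)
  sum(vapply(traces, trace_length, numeric(1))) / vol
}
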