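# Seed-point generation: the first, semi-interactive stage of the tracer.
# Five steps: maximum-intensity projection, user-thresholded binarization,
# Euclidean distance transform, windowed local maxima of the distance map,
# and per-(x, y) selection of the brightest z plane.

#' Seed-generation parameters
#'
#' Setting the two intensity thresholds is the only interactive step of the
#' tracing pipeline: the band should bracket axonal fluorescence, with the
#' upper cut removing saturated structures (somata, debris). The window size
#' controls seed spacing; 5 px gives dense coverage of tortuous, tightly
#' packed axonal segments.
#'
#' @param lower_threshold lowest intensity considered foreground.
#' @param upper_threshold highest intensity considered foreground; must
#'   exceed `lower_threshold`.
#' @param window_n odd local-maximum window edge in pixels (default 5).
#' @return An object of class `seed_params`.
#' @export
seed_params <- function(lower_threshold, upper_threshold, window_n = 5L) {
  if (!is.numeric(lower_threshold) || !is.numeric(upper_threshold) ||
      lower_threshold >= upper_threshold)
    stop_user("thresholds must satisfy lower_threshold < upper_threshold")
  window_n <- as.integer(window_n)
  if (is.na(window_n) || window_n < 3L || window_n %% 2L == 0L)
    stop_user("'window_n' must be an odd integer >= 3")
  structure(list(lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold,
                 window_n = window_n),
            class = "seed_params")
}

#' Maximum-intensity projection onto the x-y plane
#'
#' @param stack a [confocal_stack()].
#' @return `(ny, nx)` matrix: `out[y, x] = max over z of intensities[z, y, x]`.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "confocal_stack"))
  d <- dim(stack)
  v <- stack$intensities
  out <- v[1L, , , drop = TRUE]
  if (d[1] > 1L) for (z in 2:d[1]) out <- pmax(out, v[z, , ])
  matrix(out, d[2], d[3])
}

#' Band-pass binarization of a projection image
#'
#' A pixel is foreground iff `lower_threshold <= value <= upper_threshold`.
#'
#' @param image 2D numeric matrix.
#' @param params a [seed_params()] (or anything with the two thresholds).
#' @return Logical matrix of the same shape.
#' @export
binarize_band <- function(image, params) {
  if (params$lower_threshold >= params$upper_threshold)
    stop_user("thresholds must satisfy lower_threshold < upper_threshold")
  image >= params$lower_threshold & image <= params$upper_threshold
}

#' Euclidean distance transform of a binary mask
#'
#' Scores each foreground pixel by its exact Euclidean distance (in pixels)
#' to the nearest background pixel; background pixels score 0. Foreground
#' pixels touching background orthogonally score 1, and pixels on an
#' object's medial axis attain the highest local values, which is what the
#' seed stage exploits.
#'
#' @param mask logical matrix with at least one background (`FALSE`) pixel.
#' @return Numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  if (!is.matrix(mask)) stop_user("'mask' must be a matrix")
  mask <- mask != 0
  if (all(mask))
    stop_user("distance transform undefined: mask has no background pixel")
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
  matrix(EBImage::imageData(d), nrow(mask), ncol(mask))
}

# local maxima of `score` over foreground within a centred n x n window.
# Plateaus count as maxima (the medial axis of a uniform-width tube is an
# exact plateau of the distance map, so strict maxima would only mark its
# ends); tied candidates are thinned greedily so that no two seeds share a
# window: candidates in descending score (then (y, x)) order, each accepted
# unless an accepted seed already lies within its window.
window_maxima <- function(score, mask, window_n) {
  r <- (window_n - 1L) %/% 2L
  ny <- nrow(score); nx <- ncol(score)
  pad <- matrix(-Inf, ny + 2L * r, nx + 2L * r)
  pad[r + seq_len(ny), r + seq_len(nx)] <- score
  neigh_max <- matrix(-Inf, ny, nx)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    neigh_max <- pmax(neigh_max,
                      pad[r + dy + seq_len(ny), r + dx + seq_len(nx)])
  }
  cand <- which(mask & score >= neigh_max & score >= 1, arr.ind = TRUE)
  if (!nrow(cand)) return(cand)
  v <- score[cand]
  ord <- order(-v, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  taken <- matrix(FALSE, ny, nx)     # pixels within a window of a seed
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1]; x <- cand[i, 2]
    if (taken[y, x]) next
    keep[i] <- TRUE
    taken[max(1L, y - r):min(ny, y + r), max(1L, x - r):min(nx, x + r)] <- TRUE
  }
  cand[keep, , drop = FALSE]
}

#' Generate tracing seeds from a confocal stack
#'
#' Runs the five seed-selection steps: (1) maximum-intensity projection
#' along z, (2) band-pass binarization with the user thresholds, (3)
#' Euclidean distance transform of the foreground, (4) local maxima of the
#' distance map within `window_n` x `window_n` pixel windows to fix the
#' `(x, y)` seed coordinates, (5) for each `(x, y)`, the z index of the
#' brightest voxel in that column.
#'
#' @param stack a [confocal_stack()].
#' @param params a [seed_params()].
#' @return A `data.frame` with 0-based voxel indices `x`, `y`, `z`, the 3D
#'   `intensity` at the seed and its `distance` score (pixels), ordered by
#'   decreasing distance score. Empty (with a warning) when no pixel falls
#'   inside the intensity band.
#' @export
select_seeds <- function(stack, params) {
  stopifnot(inherits(stack, "confocal_stack"))
  assert_traceable(stack)
  mip <- max_intensity_projection(stack)
  mask <- binarize_band(mip, params)
  empty <- data.frame(x = integer(), y = integer(), z = integer(),
                      intensity = numeric(), distance = numeric())
  if (!any(mask)) {
    warning("no foreground pixels inside the intensity band; no seeds generated")
    return(empty)
  }
  dmap <- distance_transform(mask)
  hits <- window_maxima(dmap, mask, params$window_n)
  if (!nrow(hits)) {
    warning("no local maxima found in the distance map; no seeds generated")
    return(empty)
  }
  v <- stack$intensities
  z <- integer(nrow(hits)); intensity <- numeric(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    prof <- v[, hits[i, 1], hits[i, 2]]
    # ties (an axon running straight down the column) resolve to the middle
    # of the brightest plateau, not its end
    cand <- which(prof == max(prof))
    z[i] <- cand[ceiling(length(cand) / 2)]
    intensity[i] <- prof[z[i]]
  }
  out <- data.frame(x = hits[, 2] - 1L, y = hits[, 1] - 1L, z = z - 1L,
                    intensity = intensity,
                    distance = dmap[hits])
  out <- out[order(-out$distance, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}
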