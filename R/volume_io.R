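#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rnorm rpois runif sd lm predict coef dnorm
#'   uniroot quantile setNames runmed complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# condition helpers ------------------------------------------------------

stop_user <- function(...) {
  stop(structure(class = c("axonmap_user_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_boundary <- function(...) {
  stop(structure(class = c("axonmap_boundary_error", "axonmap_user_error",
                           "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# ConfocalStack ----------------------------------------------------------

#' Calibrated confocal image volume
#'
#' A `confocal_stack` holds a 3D grid of non-negative fluorescence
#' intensities together with its voxel calibration. The grid is stored in
#' `(z, y, x)` axis order (planes, rows, columns), matching the acquisition
#' geometry of a confocal z-series, and is typically anisotropic: optical
#' sections are around 0.5-0.6 um thick while the lateral resolution is
#' around 0.4 um.
#'
#' Voxel indices are 0-based throughout the package and a voxel's physical
#' position is taken at its centre, `(index + 0.5) * voxel_size`.
#'
#' @param intensities 3D numeric array, indexed `[z, y, x]`, finite and
#'   non-negative.
#' @param voxel_size numeric length-3 vector `(dz, dy, dx)` in um, all > 0.
#' @param name free-text identifier.
#' @return An object of class `confocal_stack`.
#' @export
confocal_stack <- function(intensities, voxel_size, name = "") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop_user("'intensities' must be a 3D array indexed (z, y, x)")
  if (!all(is.finite(intensities)))
    stop_user("stack intensities must all be finite")
  if (any(intensities < 0))
    stop_user("stack intensities must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || !all(is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop_user("'voxel_size' must be three strictly positive values (dz, dy, dx) in um")
  structure(list(intensities = intensities, voxel_size = voxel_size,
                 name = as.character(name)[1]),
            class = "confocal_stack")
}

#' @export
dim.confocal_stack <- function(x) dim(x$intensities)

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<confocal_stack '%s': %d x %d x %d voxels (z,y,x), voxel %.3g x %.3g x %.3g um>\n",
              x$name, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# voxel size in (x, y, z) order, the order of point coordinates
vox_xyz <- function(stack) rev(stack$voxel_size)

#' Physical volume of a stack in cubic micrometres
#'
#' @param stack a [confocal_stack()].
#' @return Volume in um^3 (`prod(dim) * prod(voxel_size)`).
#' @export
stack_volume_um3 <- function(stack) {
  stopifnot(inherits(stack, "confocal_stack"))
  prod(dim(stack)) * prod(stack$voxel_size)
}

# check the stack is usable for tracing (at least 2 planes per axis)
assert_traceable <- function(stack) {
  if (any(dim(stack) < 2L))
    stop_user("tracing requires at least 2 planes along every axis")
  invisible(stack)
}

#' Read a grayscale TIFF volume
#'
#' Reads a single- or multi-page grayscale TIFF into a [confocal_stack()].
#' Page order maps to z. Intensities are returned on the `[0, 1]` scale
#' used by the `tiff` package.
#'
#' @param path path to a TIFF file.
#' @param voxel_size voxel calibration `(dz, dy, dx)` in um.
#' @param name stack name; defaults to the file name.
#' @return A [confocal_stack()] of shape `(pages, rows, columns)`.
#' @export
read_stack <- function(path, voxel_size, name = basename(path)) {
  if (!file.exists(path)) stop_user("cannot read TIFF: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stop_user("TIFF contains no images: ", path)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop_user("multi-channel (RGB) TIFF: extract a single channel before reading")
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), logical(1))))
    stop_user("TIFF pages differ in shape: ", path)
  vol <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  confocal_stack(vol, voxel_size, name = name)
}

#' Write a stack to a 32-bit grayscale TIFF
#'
#' Intensities must lie in `[0, 1]`. Storage is quantised to 32 bits, so a
#' write/read round trip reproduces the grid to better than 1e-9.
#'
#' @param stack a [confocal_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "confocal_stack"))
  v <- stack$intensities
  if (min(v) < 0 || max(v) > 1)
    stop_user("write_stack() stores intensities on the [0, 1] scale; rescale first")
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

# AxonTrace --------------------------------------------------------------

#' Traced axon centerline
#'
#' An ordered 3D polyline in physical (um) coordinates representing one
#' traced axon segment.
#'
#' @param points numeric matrix with columns `(x, y, z)` in um, at least one
#'   row, consecutive rows distinct.
#' @param seed_index index of the seed that produced the trace (or `NA`).
#' @param radii optional per-node radii in um.
#' @return An object of class `axon_trace`.
#' @export
axon_trace <- function(points, seed_index = NA_integer_, radii = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 1L || ncol(points) != 3L)
    stop_user("'points' must be an n x 3 matrix of (x, y, z) positions in um")
  if (!all(is.finite(points))) stop_user("trace points must be finite")
  colnames(points) <- c("x", "y", "z")
  if (nrow(points) > 1L) {
    steps <- diff(points)
    if (any(rowSums(steps^2) == 0))
      stop_user("consecutive trace points must be distinct")
  }
  if (!is.null(radii)) {
    radii <- as.numeric(radii)
    if (length(radii) != nrow(points) || any(!is.finite(radii)) || any(radii < 0))
      stop_user("'radii' must be one finite non-negative value per point")
  }
  structure(list(points = points, seed_index = seed_index, radii = radii),
            class = "axon_trace")
}

#' Polyline length of a trace
#'
#' @param trace an [axon_trace()].
#' @return Total length in um (0 for a single-point trace).
#' @export
trace_length <- function(trace) {
  stopifnot(inherits(trace, "axon_trace"))
  p <- trace$points
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' @export
print.axon_trace <- function(x, ...) {
  cat(sprintf("<axon_trace: %d nodes, %.2f um, seed %s>\n",
              nrow(x$points), trace_length(x), format(x$seed_index)))
  invisible(x)
}

# SWC --------------------------------------------------------------------

#' Write a trace as an SWC file
#'
#' Emits the standard 7-column SWC morphology format (node id, structure
#' type, x, y, z, radius, parent id). A trace is a simple path: node `i` has
#' parent `i - 1` and the root has parent `-1`. Structure type 2 (axon) is
#' used. Coordinates are written with sub-1e-6 um precision.
#'
#' @param trace an [axon_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trace, path) {
  stopifnot(inherits(trace, "axon_trace"))
  p <- trace$points
  n <- nrow(p)
  radii <- if (is.null(trace$radii)) rep(1, n) else trace$radii
  lines <- c("# SWC axon trace (axonmap)",
             sprintf("%d 2 %.7f %.7f %.7f %.7f %d",
                     seq_len(n), p[, 1], p[, 2], p[, 3], radii,
                     c(-1L, seq_len(n - 1L))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simple-path SWC file
#'
#' Parses a whitespace-separated SWC file (`#` comments ignored). The node
#' set must form a single unbranched path; a parent id that refers to no
#' node is a parse error.
#'
#' @param path SWC file path.
#' @return An [axon_trace()] with the file's radii attached.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop_user("cannot read SWC: no such file: ", path)
  tab <- tryCatch(
    read.table(path, comment.char = "#", col.names = c("id", "type", "x", "y",
                                                       "z", "radius", "parent")),
    error = function(e) stop_user("malformed SWC file: ", conditionMessage(e)))
  if (!nrow(tab)) stop_user("SWC file contains no nodes: ", path)
  if (anyDuplicated(tab$id)) stop_user("SWC parse error: duplicated node ids")
  bad <- !(tab$parent %in% c(-1L, tab$id))
  if (any(bad))
    stop_user("SWC parse error: dangling parent id(s): ",
              paste(unique(tab$parent[bad]), collapse = ", "))
  tab <- tab[order(tab$id), ]
  if (sum(tab$parent == -1L) != 1L)
    stop_user("SWC parse error: expected exactly one root node")
  if (!all(tab$parent == c(-1L, tab$id[-nrow(tab)])))
    stop_user("SWC file is not a simple path (branching or reordered nodes)")
  axon_trace(as.matrix(tab[, c("x", "y", "z")]), radii = tab$radius)
}
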