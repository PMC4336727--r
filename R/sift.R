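#' Dense sampling grid specification
#'
#' Descriptors are computed on a regular grid rather than at detected
#' keypoints. Defaults follow the field protocol for paddy-rice canopy
#' imagery: grid spacing 15 px and four circular support radii of 4, 6, 8
#' and 10 px, giving four 128-dimensional descriptors per grid point.
#'
#' @param spacing Grid spacing M in pixels (>= 1).
#' @param radii Strictly increasing integer support radii (all >= 1).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(spacing = 15, radii = c(4, 6, 8, 10)) {
  spacing <- as.integer(spacing)
  radii <- as.integer(radii)
  if (is.na(spacing) || spacing < 1) abort("`spacing` must be >= 1")
  if (length(radii) < 1 || any(radii < 1) || is.unsorted(radii, strictly = TRUE))
    abort("`radii` must be strictly increasing integers >= 1")
  structure(list(spacing = spacing, radii = radii), class = "grid_spec")
}

#' Regular grid points over an image
#'
#' Points sit at `(i * spacing, j * spacing)` for integers `i, j >= 1` with
#' the coordinate strictly inside the image (0-based pixel coordinates), in
#' row-major order (y outer, x inner). The grid origin at `(spacing,
#' spacing)` keeps full support for small radii near the border.
#'
#' @param width,height Image dimensions in pixels.
#' @param spacing Grid spacing in pixels.
#' @return Tibble with integer columns `x`, `y` (possibly zero rows).
#' @export
make_grid <- function(width, height, spacing) {
  stopifnot(width >= 1, height >= 1, spacing >= 1)
  xs <- seq.int(spacing, by = spacing,
                length.out = max(0, floor((width - 1) / spacing)))
  ys <- seq.int(spacing, by = spacing,
                length.out = max(0, floor((height - 1) / spacing)))
  if (length(xs) == 0 || length(ys) == 0)
    return(tibble::tibble(x = integer(), y = integer()))
  tibble::tibble(
    x = as.integer(rep(xs, times = length(ys))),
    y = as.integer(rep(ys, each = length(xs)))
  )
}

#' Dominant gradient orientation at a point
#'
#' 36-bin histogram of gradient orientations over the circular support of the
#' given radius, with magnitudes Gaussian-weighted (sigma = radius / 2);
#' gradients by central differences with zero padding beyond the image. The
#' returned angle is the left edge of the peak bin (ties broken toward the
#' lowest bin); a zero-gradient support returns 0 by convention.
#'
#' @param lum Luminance matrix (H x W).
#' @param x,y 0-based pixel coordinates of the center.
#' @param radius Support radius in pixels (>= 1).
#' @return Angle in `[0, 2*pi)`.
#' @export
dominant_orientation <- function(lum, x, y, radius) {
  stopifnot(is.matrix(lum), radius >= 1)
  .dominant_orientation_cpp(lum, as.integer(x), as.integer(y), as.integer(radius))
}

#' SIFT descriptor at a point
#'
#' A square of side `4 * radius` centered on the point and rotated by
#' `orientation` is divided 4 x 4 into 16 spatial patches; each patch
#' accumulates an 8-bin hard histogram of gradient magnitudes by orientation
#' relative to the rotated frame. The 16 x 8 = 128 values are concatenated
#' patch-major (row-major over patches), bin-minor, then L2-normalized,
#' clipped at 0.2 and re-normalized. A zero-gradient support yields the zero
#' vector.
#'
#' @inheritParams dominant_orientation
#' @param orientation Rotation of the descriptor frame, radians.
#' @return Numeric vector of length 128.
#' @export
sift_descriptor <- function(lum, x, y, radius, orientation = 0) {
  stopifnot(is.matrix(lum))
  if (radius < 1) abort("`radius` must be >= 1")
  .sift_descriptor_cpp(lum, as.integer(x), as.integer(y), as.integer(radius),
                       as.numeric(orientation))
}

#' Dense multi-scale SIFT over an image
#'
#' Computes, for every grid point of [make_grid()] and every support radius,
#' one SIFT descriptor oriented to that point's per-scale dominant
#' orientation.
#'
#' @param lum Luminance matrix (H x W) or a [canopy_image()].
#' @param grid A [grid_spec()].
#' @return A `descriptor_set`: list with `points` (tibble `x`, `y`),
#'   `radii`, `descriptors` (matrix `(n_points * n_radii) x 128`, rows
#'   point-major then radius), `orientations`, and `grid`.
#' @export
dense_multiscale_sift <- function(lum, grid = grid_spec()) {
  if (inherits(lum, "canopy_image")) lum <- lum$luminance
  stopifnot(is.matrix(lum), inherits(grid, "grid_spec"))
  pts <- make_grid(ncol(lum), nrow(lum), grid$spacing)
  if (nrow(pts) == 0) {
    return(new_descriptor_set(pts, grid,
                              matrix(0, 0, 128), numeric(0)))
  }
  res <- .dense_sift_cpp(lum, pts$x, pts$y, grid$radii)
  new_descriptor_set(pts, grid, res$descriptors, res$orientations)
}

new_descriptor_set <- function(points, grid, descriptors, orientations) {
  structure(
    list(points = points, radii = grid$radii, grid = grid,
         descriptors = descriptors, orientations = orientations),
    class = "descriptor_set"
  )
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf(
    "<descriptor_set> %d points x %d radii = %d descriptors (spacing %d, radii %s)\n",
    nrow(x$points), length(x$radii), nrow(x$descriptors),
    x$grid$spacing, paste(x$radii, collapse = ",")
  ))
  invisible(x)
}

#' Tidy a descriptor set
#'
#' One row per descriptor with its grid point, support radius, dominant
#' orientation and descriptor norm (0 for flat supports, else ~1).
#'
#' @param x A `descriptor_set`.
#' @param ... Unused.
#' @export
tidy.descriptor_set <- function(x, ...) {
  nr <- length(x$radii)
  tibble::tibble(
    x = rep(x$points$x, each = nr),
    y = rep(x$points$y, each = nr),
    radius = rep(x$radii, times = nrow(x$points)),
    orientation = as.numeric(x$orientations),
    norm = sqrt(rowSums(x$descriptors^2))
  )
}
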