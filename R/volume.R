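#' 3D scalar volume with voxel spacing
#'
#' The basic image container of the package: a 3D numeric array plus a
#' per-axis voxel size in millimetres and a free-form frame tag
#' (conventionally `"fixed"` or `"moving"`). Voxel coordinates in the public
#' API are always 0-based, so voxel index 0 sits at the first grid node and
#' index `shape - 1` at the last; this makes the node-centred normalized
#' mapping (index 0 <-> -1, index N-1 <-> +1) exact at grid corners.
#'
#' @param data 3D numeric array of intensities. Must be free of NaN/Inf.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#'   A scalar is recycled to the three axes. Default 0.4 mm isotropic, the
#'   photoacoustic-mammography reconstruction convention this package
#'   targets.
#' @param frame_tag identifier string, e.g. `"fixed"` or `"moving"`.
#' @return An object of class `pa_volume`.
#' @export
pa_volume <- function(data, spacing = 0.4, frame_tag = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  storage.mode(data) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  }
  shp <- dim(data)
  if (any(shp < 2L)) {
    stop("every axis needs at least 2 voxels (normalization needs two endpoints)",
         call. = FALSE)
  }
  nbad <- sum(!is.finite(data))
  if (nbad > 0L) {
    stop(sprintf("volume contains %d non-finite voxel(s)", nbad), call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, shape = shp,
         frame_tag = as.character(frame_tag)[1L]),
    class = "pa_volume"
  )
}

#' @export
print.pa_volume <- function(x, ...) {
  cat(sprintf("<pa_volume '%s'> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$frame_tag, x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.pa_volume <- function(x) x$shape

is_pa_volume <- function(x) inherits(x, "pa_volume")

as_coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("coordinates must be N x 3", call. = FALSE)
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must be N x 3", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

check_degenerate_axes <- function(volume) {
  if (any(volume$shape < 2L)) {
    stop("degenerate axis of length < 2: normalized mapping undefined",
         call. = FALSE)
  }
}

#' Convert 0-based voxel indices to normalized coordinates
#'
#' Default (`isotropic = FALSE`) is the per-axis node-centred convention:
#' `x_norm = 2 * idx / (shape_a - 1) - 1`, so index 0 maps to -1 and index
#' `shape_a - 1` to +1 on every axis (exact at grid corners, anisotropic
#' in mm when the grid is). With `isotropic = TRUE` all axes share the
#' longest axis' scale about the volume centre, so the cube is isometric
#' but shorter axes do not reach +-1. Indices may be fractional and may
#' lie outside the grid (the map is linear everywhere).
#'
#' @param volume a [pa_volume].
#' @param idx N x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @param isotropic use a single scale for all axes.
#' @return N x 3 matrix of coordinates in the `[-1, 1]^3` cube convention.
#' @export
voxel_to_normalized <- function(volume, idx, isotropic = FALSE) {
  stopifnot(is_pa_volume(volume))
  check_degenerate_axes(volume)
  idx <- as_coord_matrix(idx)
  half <- norm_half_extent(volume, isotropic)
  sweep(sweep(idx, 2L, (volume$shape - 1) / 2, "-"), 2L, half, "/")
}

#' Convert normalized coordinates to 0-based voxel indices
#'
#' Inverse of [voxel_to_normalized()].
#' @inheritParams voxel_to_normalized
#' @param coords N x 3 matrix of normalized coordinates.
#' @return N x 3 matrix of (possibly fractional) 0-based voxel indices.
#' @export
normalized_to_voxel <- function(volume, coords, isotropic = FALSE) {
  stopifnot(is_pa_volume(volume))
  check_degenerate_axes(volume)
  coords <- as_coord_matrix(coords)
  half <- norm_half_extent(volume, isotropic)
  sweep(sweep(coords, 2L, half, "*"), 2L, (volume$shape - 1) / 2, "+")
}

norm_half_extent <- function(volume, isotropic) {
  if (isotropic) rep(max(volume$shape - 1) / 2, 3L)
  else (volume$shape - 1) / 2
}

#' Convert 0-based voxel indices to millimetres
#'
#' World position is `idx * spacing`; the grid origin (voxel 0,0,0) is the
#' world origin.
#' @inheritParams voxel_to_normalized
#' @return N x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(volume, idx) {
  stopifnot(is_pa_volume(volume))
  idx <- as_coord_matrix(idx)
  sweep(idx, 2L, volume$spacing, "*")
}

#' Convert millimetres to 0-based voxel indices
#' @inheritParams voxel_to_normalized
#' @param mm N x 3 matrix of mm coordinates.
#' @export
mm_to_voxel <- function(volume, mm) {
  stopifnot(is_pa_volume(volume))
  mm <- as_coord_matrix(mm)
  sweep(mm, 2L, volume$spacing, "/")
}

#' @rdname voxel_to_mm
#' @param coords N x 3 normalized coordinates.
#' @export
normalized_to_mm <- function(volume, coords) {
  voxel_to_mm(volume, normalized_to_voxel(volume, coords))
}

#' @rdname mm_to_voxel
#' @export
mm_to_normalized <- function(volume, mm) {
  voxel_to_normalized(volume, mm_to_voxel(volume, mm))
}

# Trilinear interpolation at fractional 0-based voxel coordinates.
# Returns list(value, [grad]) where grad is d(value)/d(voxel coordinate),
# zero outside the domain. `outside` is decided in normalized coordinates by
# the caller; here vox is assumed already computed and `outside` passed in.
trilinear_vox <- function(data, vox, outside, fill = 0, want_grad = FALSE) {
  n <- dim(data)
  N <- nrow(vox)
  val <- rep(as.numeric(fill), N)
  grad <- if (want_grad) matrix(0, N, 3L) else NULL
  inside <- !outside
  if (any(inside)) {
    v <- vox[inside, , drop = FALSE]
    i0 <- floor(v)
    # clamp so that points exactly on the far face use the last cell
    i0[, 1] <- pmin(pmax(i0[, 1], 0), n[1] - 2)
    i0[, 2] <- pmin(pmax(i0[, 2], 0), n[2] - 2)
    i0[, 3] <- pmin(pmax(i0[, 3], 0), n[3] - 2)
    f <- v - i0
    f1 <- f[, 1]; f2 <- f[, 2]; f3 <- f[, 3]
    g1 <- 1 - f1; g2 <- 1 - f2; g3 <- 1 - f3
    # linear index of corner (i0 + di, ...) in column-major order, 1-based
    base <- 1 + i0[, 1] + n[1] * (i0[, 2] + n[2] * i0[, 3])
    o1 <- 1; o2 <- n[1]; o3 <- n[1] * n[2]
    c000 <- data[base]
    c100 <- data[base + o1]
    c010 <- data[base + o2]
    c110 <- data[base + o1 + o2]
    c001 <- data[base + o3]
    c101 <- data[base + o1 + o3]
    c011 <- data[base + o2 + o3]
    c111 <- data[base + o1 + o2 + o3]
    val[inside] <-
      c000 * g1 * g2 * g3 + c100 * f1 * g2 * g3 +
      c010 * g1 * f2 * g3 + c110 * f1 * f2 * g3 +
      c001 * g1 * g2 * f3 + c101 * f1 * g2 * f3 +
      c011 * g1 * f2 * f3 + c111 * f1 * f2 * f3
    if (want_grad) {
      grad[inside, 1] <-
        (c100 - c000) * g2 * g3 + (c110 - c010) * f2 * g3 +
        (c101 - c001) * g2 * f3 + (c111 - c011) * f2 * f3
      grad[inside, 2] <-
        (c010 - c000) * g1 * g3 + (c110 - c100) * f1 * g3 +
        (c011 - c001) * g1 * f3 + (c111 - c101) * f1 * f3
      grad[inside, 3] <-
        (c001 - c000) * g1 * g2 + (c101 - c100) * f1 * g2 +
        (c011 - c010) * g1 * f2 + (c111 - c110) * f1 * f2
    }
  }
  if (want_grad) list(value = val, grad = grad) else list(value = val)
}

#' Sample intensities at normalized coordinates by trilinear interpolation
#'
#' Coordinates outside the `[-1, 1]^3` cube return `fill_value` (default 0,
#' the dark-background convention for photoacoustic data).
#'
#' @inheritParams voxel_to_normalized
#' @param coords N x 3 normalized coordinates (finite).
#' @param fill_value scalar returned for out-of-domain coordinates.
#' @return numeric vector of N interpolated intensities.
#' @export
sample_intensity <- function(volume, coords, fill_value = 0) {
  stopifnot(is_pa_volume(volume))
  coords <- as_coord_matrix(coords)
  if (any(!is.finite(coords))) {
    stop("non-finite coordinates passed to sample_intensity", call. = FALSE)
  }
  tol <- 1e-12
  outside <- rowSums(abs(coords) > 1 + tol) > 0
  vox <- normalized_to_voxel(volume, coords)
  trilinear_vox(volume$data, vox, outside, fill = fill_value)$value
}

# internal: sample + gradient with respect to NORMALIZED coordinates
sample_intensity_grad <- function(volume, coords, fill_value = 0) {
  coords <- as_coord_matrix(coords)
  tol <- 1e-12
  outside <- rowSums(abs(coords) > 1 + tol) > 0
  vox <- normalized_to_voxel(volume, coords)
  r <- trilinear_vox(volume$data, vox, outside, fill = fill_value,
                     want_grad = TRUE)
  # chain rule: d vox / d norm = (shape - 1) / 2 per axis
  r$grad <- sweep(r$grad, 2L, (volume$shape - 1) / 2, "*")
  r
}
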