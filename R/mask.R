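#' Vessel-mask parameters
#'
#' Parameters of the coarse vessel sampling mask built on the fixed image:
#' multiscale Frangi filtering followed by adaptive thresholding against a
#' threshold map that decays exponentially with depth (deep vessels receive
#' less light fluence, so a laxer threshold keeps them in the mask).
#'
#' @param sigmas Frangi scale list in voxels (default 2, 3, 4).
#' @param t_surface threshold at zero depth (in vesselness units).
#' @param t_deep asymptotic threshold at infinite depth.
#' @param tau exponential decay constant of the threshold map, in mm.
#' @param depth_axis axis index pointing into tissue.
#' @return a `mask_params` list.
#' @export
mask_params <- function(sigmas = c(2, 3, 4), t_surface = 0.5, t_deep = 0.05,
                        tau = 10, depth_axis = 3L) {
  if (!(t_deep >= 0 && t_deep <= t_surface && t_surface <= 1)) {
    stop("need 0 <= t_deep <= t_surface <= 1", call. = FALSE)
  }
  if (tau <= 0) stop("`tau` must be > 0 (mm)", call. = FALSE)
  depth_axis <- as.integer(depth_axis)
  if (!depth_axis %in% 1:3) stop("`depth_axis` must be 1, 2 or 3",
                                 call. = FALSE)
  structure(list(sigmas = as.numeric(sigmas), t_surface = t_surface,
                 t_deep = t_deep, tau = tau, depth_axis = depth_axis),
            class = "mask_params")
}

#' Per-voxel imaging depth in millimetres
#'
#' Depth is the distance along `depth_axis` from the entry face of the grid
#' (the index-0 plane) to each voxel. A flat entry plane is assumed; a
#' segmented tissue surface can be substituted by passing `surface_offset`,
#' a matrix of per-column entry depths in mm subtracted from the flat map.
#'
#' @param volume a [pa_volume].
#' @param depth_axis axis index (1-3).
#' @param surface_offset optional matrix (shaped like the two non-depth
#'   axes) of entry-surface depths in mm.
#' @return array of depths in mm, shaped like the volume (floored at 0 when
#'   a surface offset is used).
#' @export
depth_map <- function(volume, depth_axis = 3L, surface_offset = NULL) {
  stopifnot(is_pa_volume(volume))
  depth_axis <- as.integer(depth_axis)
  if (!depth_axis %in% 1:3) stop("`depth_axis` must be 1, 2 or 3",
                                 call. = FALSE)
  d1 <- (seq_len(volume$shape[depth_axis]) - 1) * volume$spacing[depth_axis]
  depth <- array(d1[slice.index(array(0, volume$shape), depth_axis)],
                 dim = volume$shape)
  if (!is.null(surface_offset)) {
    other <- setdiff(1:3, depth_axis)
    if (!identical(dim(surface_offset), volume$shape[other])) {
      stop("`surface_offset` must be shaped like the non-depth axes",
           call. = FALSE)
    }
    idx <- slice.index(depth, other[1]) +
      volume$shape[other[1]] * (slice.index(depth, other[2]) - 1L)
    depth <- pmax(depth - array(surface_offset[idx], dim = dim(depth)), 0)
  }
  depth
}

#' Coarse vessel sampling mask on the fixed image
#'
#' Multiscale Frangi response thresholded against
#' `T(x) = t_deep + (t_surface - t_deep) * exp(-depth(x) / tau)`.
#'
#' @param fixed a [pa_volume] (the fixed image).
#' @param params a [mask_params].
#' @param surface_offset optional entry-surface map, see [depth_map()].
#' @return a [pa_volume] whose data is a 0/1 mask.
#' @export
vessel_mask <- function(fixed, params = mask_params(),
                        surface_offset = NULL) {
  stopifnot(is_pa_volume(fixed), inherits(params, "mask_params"))
  v <- frangi_vesselness(fixed, vesselness_params(sigmas = params$sigmas))
  thr <- mask_threshold_map(fixed, params, surface_offset)
  m <- (v$data > thr) * 1
  if (sum(m) == 0) {
    stop(paste("vessel mask is empty: no voxel exceeds the threshold map;",
               "lower t_surface/t_deep or check the input contrast"),
         call. = FALSE)
  }
  pa_volume(m, spacing = fixed$spacing,
            frame_tag = paste0(fixed$frame_tag, ":mask"))
}

# the exponentially decaying threshold map T(x)
mask_threshold_map <- function(volume, params, surface_offset = NULL) {
  depth <- depth_map(volume, params$depth_axis, surface_offset)
  params$t_deep + (params$t_surface - params$t_deep) * exp(-depth / params$tau)
}
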