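# Separable Gaussian / derivative filtering and multiscale Frangi
# vesselness. Second derivatives are realised as exact discrete central
# differences of the Gaussian-smoothed signal (kernel = difference stencil
# convolved with the sampled Gaussian), so the Hessian agrees to machine
# precision with finite differences of the smoothed volume and is exact on
# polynomial test images.

gaussian_kernel_1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# derivative-order 0, 1, 2 kernels for correlation (no flip); the
# first/second difference stencils are exact on linear/quadratic signals
deriv_kernel_1d <- function(sigma, order, truncate = 4) {
  g <- gaussian_kernel_1d(sigma, truncate)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- c(-0.5, 0, 0.5)          # correlation stencil: (f[i+1]-f[i-1])/2
  } else if (order == 2L) {
    k <- c(1, -2, 1)
  } else stop("unsupported derivative order")
  # discrete convolution of stencil with the smoothing kernel
  n <- length(g) + length(k) - 1L
  out <- numeric(n)
  for (i in seq_along(k)) {
    out[i:(i + length(g) - 1L)] <- out[i:(i + length(g) - 1L)] + k[i] * g
  }
  out
}

# reflect (edge-duplicating) index fold onto 0..n-1
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  period <- 2L * n
  i <- i %% period
  i[i < 0] <- i[i < 0] + period
  over <- i >= n
  i[over] <- period - 1L - i[over]
  i
}

# dense n x n correlation operator with reflect boundary handling
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  C <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    j <- reflect_index(seq_len(n) - 1L + off, n) + 1L
    C[cbind(seq_len(n), j)] <- C[cbind(seq_len(n), j)] + kernel[k]
  }
  C
}

# correlate a 3D array with a 1D kernel along one axis (reflect boundary)
correlate_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  C <- conv_matrix(d[axis], kernel)
  if (axis == 1L) {
    out <- C %*% matrix(arr, nrow = d[1])
    return(array(out, dim = d))
  }
  perm <- if (axis == 2L) c(2L, 1L, 3L) else c(3L, 1L, 2L)
  a <- aperm(arr, perm)
  out <- C %*% matrix(a, nrow = d[axis])
  a <- array(out, dim = d[perm])
  aperm(a, order(perm))
}

# Gaussian smoothing of a 3D array (separable, reflect boundary)
gaussian_smooth_3d <- function(arr, sigma, truncate = 4) {
  g <- gaussian_kernel_1d(sigma, truncate)
  correlate_axis(correlate_axis(correlate_axis(arr, g, 1L), g, 2L), g, 3L)
}

#' Vesselness filter parameters
#'
#' @param sigmas Gaussian scales in voxels, in the order applied. The
#'   default is the multiscale list used for vessel masks.
#' @param frangi_a plate-vs-line sensitivity (classic Frangi alpha).
#' @param frangi_b blob sensitivity (classic Frangi beta).
#' @param frangi_c structureness sensitivity; the default `"auto"` uses half
#'   the maximum Hessian Frobenius norm at each scale.
#' @param bright_on_dark if `TRUE` (the photoacoustic case) the response is
#'   zeroed where the two principal eigenvalues are not both negative.
#' @return a `vesselness_params` list.
#' @export
vesselness_params <- function(sigmas = c(2, 3, 4), frangi_a = 0.5,
                              frangi_b = 0.5, frangi_c = "auto",
                              bright_on_dark = TRUE) {
  sigmas <- as.numeric(sigmas)
  if (length(sigmas) < 1L || any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stop("`sigmas` must be positive scales (voxels)", call. = FALSE)
  }
  if (!is.numeric(frangi_a) || frangi_a <= 0 ||
      !is.numeric(frangi_b) || frangi_b <= 0) {
    stop("`frangi_a` and `frangi_b` must be > 0", call. = FALSE)
  }
  if (!identical(frangi_c, "auto") &&
      (!is.numeric(frangi_c) || frangi_c <= 0)) {
    stop("`frangi_c` must be > 0 or \"auto\"", call. = FALSE)
  }
  structure(list(sigmas = sigmas, frangi_a = frangi_a, frangi_b = frangi_b,
                 frangi_c = frangi_c, bright_on_dark = isTRUE(bright_on_dark)),
            class = "vesselness_params")
}

# sort three eigenvalue grids by |lambda| with vectorised compare-swaps
sort_by_abs3 <- function(l1, l2, l3) {
  swp <- abs(l1) > abs(l2)
  tmp <- l1[swp]; l1[swp] <- l2[swp]; l2[swp] <- tmp
  swp <- abs(l2) > abs(l3)
  tmp <- l2[swp]; l2[swp] <- l3[swp]; l3[swp] <- tmp
  swp <- abs(l1) > abs(l2)
  tmp <- l1[swp]; l1[swp] <- l2[swp]; l2[swp] <- tmp
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Gamma-normalized Hessian eigenvalues at one scale
#'
#' The Hessian is computed by Gaussian smoothing at scale `sigma` followed
#' by exact central second differences, multiplied by the scale
#' normalization factor `sigma^2` so responses are comparable across scales.
#' Eigenvalues are returned sorted per voxel by absolute value,
#' `|lambda1| <= |lambda2| <= |lambda3|`.
#'
#' @param volume a [pa_volume].
#' @param sigma Gaussian scale in voxels (> 0).
#' @return list of three arrays `lambda1`, `lambda2`, `lambda3` (each the
#'   shape of the volume) plus `frobenius`, the Hessian Frobenius norm.
#' @export
hessian_eigenvalues <- function(volume, sigma) {
  stopifnot(is_pa_volume(volume))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a positive scale in voxels", call. = FALSE)
  }
  H <- hessian_components(volume$data, sigma)
  eig <- symmetric_eigenvalues_3x3(H)
  s <- sort_by_abs3(eig$l1, eig$l2, eig$l3)
  frob <- sqrt(H$xx^2 + H$yy^2 + H$zz^2 + 2 * (H$xy^2 + H$xz^2 + H$yz^2))
  list(lambda1 = s$l1, lambda2 = s$l2, lambda3 = s$l3, frobenius = frob)
}

hessian_components <- function(data, sigma, truncate = 4) {
  g0 <- deriv_kernel_1d(sigma, 0L, truncate)
  g1 <- deriv_kernel_1d(sigma, 1L, truncate)
  g2 <- deriv_kernel_1d(sigma, 2L, truncate)
  gamma <- sigma^2
  d2 <- function(ka, kb, kc) {
    gamma * correlate_axis(correlate_axis(correlate_axis(data, ka, 1L),
                                          kb, 2L), kc, 3L)
  }
  list(
    xx = d2(g2, g0, g0), yy = d2(g0, g2, g0), zz = d2(g0, g0, g2),
    xy = d2(g1, g1, g0), xz = d2(g1, g0, g1), yz = d2(g0, g1, g1)
  )
}

# closed-form eigenvalues of symmetric 3x3 matrices, vectorised over voxels
symmetric_eigenvalues_3x3 <- function(H) {
  a <- H$xx; b <- H$yy; c <- H$zz; d <- H$xy; f <- H$xz; e <- H$yz
  tr <- a + b + c
  q <- tr / 3
  p1 <- d^2 + f^2 + e^2
  A <- a - q; B <- b - q; C <- c - q
  p2 <- A^2 + B^2 + C^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  # r = det(M - qI) / (2 p^3), clamped into [-1, 1]
  detB <- A * (B * C - e^2) - d * (d * C - e * f) + f * (d * e - B * f)
  safe <- p > .Machine$double.eps * (abs(q) + 1)
  r <- numeric(length(a))
  r[safe] <- detB[safe] / (2 * p[safe]^3)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- tr - l1 - l3
  dim(l1) <- dim(l2) <- dim(l3) <- dim(a)
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Multiscale Frangi vesselness
#'
#' Classic bright-tube vesselness: per scale,
#' `V = (1 - exp(-Ra^2 / (2 a^2))) * exp(-Rb^2 / (2 b^2)) *
#'     (1 - exp(-S^2 / (2 c^2)))`
#' with `Ra = |l2|/|l3|`, `Rb = |l1|/sqrt(|l2 l3|)` and `S` the Hessian
#' Frobenius norm; the response is forced to zero where `l2 > 0` or
#' `l3 > 0` (bright structures on dark background) and where `l3 = 0`. The
#' multiscale output is the voxelwise maximum over scales.
#'
#' @param volume a [pa_volume].
#' @param params a [vesselness_params].
#' @return a [pa_volume] of vesselness values in `[0, 1]`.
#' @export
frangi_vesselness <- function(volume, params = vesselness_params()) {
  stopifnot(is_pa_volume(volume), inherits(params, "vesselness_params"))
  out <- array(0, dim = volume$shape)
  for (sigma in params$sigmas) {
    out <- pmax(out, frangi_single_scale(volume, sigma, params))
  }
  pa_volume(out, spacing = volume$spacing,
            frame_tag = paste0(volume$frame_tag, ":vesselness"))
}

frangi_single_scale <- function(volume, sigma, params) {
  eig <- hessian_eigenvalues(volume, sigma)
  l1 <- eig$lambda1; l2 <- eig$lambda2; l3 <- eig$lambda3
  S <- eig$frobenius
  # a structureless (constant) volume yields S at floating-point noise
  # level ~ eps * intensity * sigma^2; treat that as exactly no structure
  s_tol <- 1e-8 * max(1, max(abs(volume$data))) * max(1, sigma^2)
  if (max(S) <= s_tol) return(array(0, dim = volume$shape))
  c_val <- if (identical(params$frangi_c, "auto")) {
    max(S) / 2
  } else params$frangi_c
  a2 <- abs(l2); a3 <- abs(l3)
  eps <- .Machine$double.xmin
  Ra2 <- (a2 / pmax(a3, eps))^2
  Rb2 <- l1^2 / pmax(a2 * a3, eps)
  V <- (1 - exp(-Ra2 / (2 * params$frangi_a^2))) *
    exp(-Rb2 / (2 * params$frangi_b^2)) *
    (1 - exp(-S^2 / (2 * c_val^2)))
  V[a3 == 0] <- 0
  if (params$bright_on_dark) V[l2 > 0 | l3 > 0] <- 0
  V
}

#' Adaptive intensity modulation parameters
#'
#' Defines the depth-percentile gain-equalization used to compensate the
#' depth-dependent loss of light fluence: a per-depth gain profile is taken
#' as a high percentile of the nonzero vesselness in each depth slab,
#' smoothed along depth, floored, and divided out. The strategy is
#' pluggable via the `strategy` field (a function `(vesselness_array,
#' params) -> array`), with the percentile equalizer as the default.
#'
#' @param depth_axis axis index (1-3) pointing into tissue.
#' @param profile_percentile percentile (0-100, exclusive) of the
#'   significant vesselness in each depth slab defining the gain profile.
#' @param profile_smoothing Gaussian smoothing scale of the profile along
#'   depth, in voxels.
#' @param epsilon floor of the gain profile, capping the maximum boost at
#'   `1/epsilon`; prevents noise in vessel-free slabs from being amplified
#'   into saturation.
#' @param signal_floor fraction of the global vesselness maximum below
#'   which slab values are treated as background when estimating the
#'   profile (the filter halo and noise responses must not set the gain).
#' @param strategy optional replacement modulation function.
#' @return a `modulation_params` list.
#' @export
modulation_params <- function(depth_axis = 3L, profile_percentile = 99,
                              profile_smoothing = 5, epsilon = 0.05,
                              signal_floor = 0.02, strategy = NULL) {
  if (profile_percentile <= 0 || profile_percentile >= 100) {
    stop("`profile_percentile` must be in (0, 100)", call. = FALSE)
  }
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  if (signal_floor < 0 || signal_floor >= 1) {
    stop("`signal_floor` must be in [0, 1)", call. = FALSE)
  }
  depth_axis <- as.integer(depth_axis)
  if (!depth_axis %in% 1:3) stop("`depth_axis` must be 1, 2 or 3",
                                 call. = FALSE)
  structure(list(depth_axis = depth_axis,
                 profile_percentile = profile_percentile,
                 profile_smoothing = profile_smoothing,
                 epsilon = epsilon, signal_floor = signal_floor,
                 strategy = strategy),
            class = "modulation_params")
}

#' Adaptive intensity modulation of a vesselness volume
#'
#' Divides out a smoothed per-depth gain profile so that vessels attenuated
#' by depth-dependent light fluence regain contrast; output is clipped to
#' `[0, 1]` and, within any fixed depth slab, is a monotone nondecreasing
#' function of the input.
#'
#' @param vesselness a [pa_volume] with values in `[0, 1]`.
#' @param params a [modulation_params].
#' @return a [pa_volume] of modulated vesselness in `[0, 1]`.
#' @export
adaptive_intensity_modulation <- function(vesselness,
                                          params = modulation_params()) {
  stopifnot(is_pa_volume(vesselness), inherits(params, "modulation_params"))
  if (!is.null(params$strategy)) {
    out <- params$strategy(vesselness$data, params)
    return(pa_volume(out, spacing = vesselness$spacing,
                     frame_tag = vesselness$frame_tag))
  }
  v <- vesselness$data
  ax <- params$depth_axis
  nd <- dim(v)[ax]
  floor_abs <- params$signal_floor * max(v)
  slabs <- split(seq_along(v), slice.index(v, ax))
  g_raw <- vapply(seq_len(nd), function(d) {
    vals <- v[slabs[[d]]]
    nz <- vals[vals > max(floor_abs, 1e-12)]
    if (length(nz) == 0L) NA_real_
    else stats::quantile(nz, params$profile_percentile / 100, names = FALSE)
  }, numeric(1))
  if (all(is.na(g_raw))) {
    warning("no nonzero vesselness in any depth slab; returning input unchanged")
    return(vesselness)
  }
  # nearest-neighbour fill of empty slabs, then smooth along depth
  filled <- g_raw
  idx_ok <- which(!is.na(g_raw))
  for (d in which(is.na(g_raw))) {
    filled[d] <- g_raw[idx_ok[which.min(abs(idx_ok - d))]]
  }
  if (params$profile_smoothing > 0) {
    k <- gaussian_kernel_1d(params$profile_smoothing)
    C <- conv_matrix(nd, k)
    filled <- as.numeric(C %*% filled)
  }
  g <- pmax(filled, params$epsilon)
  gain <- array((1 / g)[slice.index(v, ax)], dim = dim(v))
  out <- pmin(pmax(v * gain, 0), 1)
  pa_volume(out, spacing = vesselness$spacing,
            frame_tag = paste0(vesselness$frame_tag, ":modulated"))
}

# convenience: multiscale vesselness + modulation in one call
enhance_volume <- function(volume, vparams = vesselness_params(),
                           mparams = modulation_params()) {
  adaptive_intensity_modulation(frangi_vesselness(volume, vparams), mparams)
}
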