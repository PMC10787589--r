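# Quantitative registration assessment: PSNR, global NCC, Dice overlap of
# vessel masks, and landmark target registration error (TRE), before and
# after co-registration.

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(R^2 / MSE)` with `R` the maximum intensity of the
#' reference volume (so the measure is asymmetric when the two maxima
#' differ); identical volumes give `Inf`.
#'
#' @param reference,test [pa_volume]s on the same grid shape.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, test) {
  stopifnot(is_pa_volume(reference), is_pa_volume(test))
  if (!identical(reference$shape, test$shape)) {
    stop("volumes must share a grid shape", call. = FALSE)
  }
  mse <- mean((reference$data - test$data)^2)
  if (mse == 0) return(Inf)
  R <- max(reference$data)
  10 * log10(R^2 / mse)
}

#' Global normalized cross correlation
#'
#' NCC over all voxels (one patch spanning the whole volume); constant
#' volumes give 0 with a warning.
#'
#' @param a,b [pa_volume]s on the same grid shape.
#' @return value in `[-1, 1]`.
#' @export
ncc_global <- function(a, b) {
  stopifnot(is_pa_volume(a), is_pa_volume(b))
  if (!identical(a$shape, b$shape)) {
    stop("volumes must share a grid shape", call. = FALSE)
  }
  r <- local_ncc(matrix(a$data, nrow = 1), matrix(b$data, nrow = 1),
                 want_grad = FALSE)
  if (r$ncc[1] == 0 && (stats::var(as.numeric(a$data)) < 1e-24 ||
                        stats::var(as.numeric(b$data)) < 1e-24)) {
    warning("constant volume in ncc_global; returning 0")
  }
  r$ncc[1]
}

#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2 |A n B| / (|A| + |B|)`; two empty masks are defined as
#' perfectly overlapping (1, with a warning).
#'
#' @param mask_a,mask_b binary [pa_volume]s (values 0/1) on the same grid.
#' @return value in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(is_pa_volume(mask_a), is_pa_volume(mask_b))
  if (!identical(mask_a$shape, mask_b$shape)) {
    stop("masks must share a grid shape", call. = FALSE)
  }
  av <- mask_a$data; bv <- mask_b$data
  if (!all(av %in% c(0, 1)) || !all(bv %in% c(0, 1))) {
    stop("dice requires binary (0/1) masks", call. = FALSE)
  }
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(av * bv) / (na + nb)
}

#' Landmark target registration error
#'
#' Euclidean distances in millimetres between corresponding points matched
#' by name. Both sets are converted to mm through their volumes' spacing;
#' the standard deviation is the population SD of the per-point distances.
#'
#' @param points_a a [landmark_set] (e.g. fixed landmarks mapped into the
#'   moving frame).
#' @param points_b a [landmark_set] of corresponding ground-truth points.
#' @param volume_a,volume_b the volumes defining each set's geometry
#'   (`volume_b` defaults to `volume_a`).
#' @return list with `mean_mm`, `sd_mm` and the named per-point
#'   `distances_mm`.
#' @export
tre <- function(points_a, points_b, volume_a, volume_b = volume_a) {
  stopifnot(inherits(points_a, "landmark_set"),
            inherits(points_b, "landmark_set"))
  miss_a <- setdiff(points_b$names, points_a$names)
  miss_b <- setdiff(points_a$names, points_b$names)
  if (length(miss_a) || length(miss_b)) {
    stop(sprintf("landmark name mismatch; unmatched: %s",
                 paste(unique(c(miss_a, miss_b)), collapse = ", ")),
         call. = FALSE)
  }
  a_mm <- convert_landmarks(points_a, volume_a, "mm")
  b_mm <- convert_landmarks(points_b, volume_b, "mm")
  ord <- match(a_mm$names, b_mm$names)
  d <- sqrt(rowSums((a_mm$points - b_mm$points[ord, , drop = FALSE])^2))
  names(d) <- a_mm$names
  n <- length(d)
  list(mean_mm = mean(d),
       sd_mm = sqrt(sum((d - mean(d))^2) / n),
       distances_mm = d)
}

#' Evaluation parameters
#'
#' @param sigmas Frangi scales used to build the vesselness images on
#'   which PSNR/NCC are computed and the masks for Dice.
#' @param mask_params a [mask_params] for the Dice vessel masks.
#' @param modulation_params a [modulation_params].
#' @param use_raw_intensities if `TRUE`, PSNR/NCC are computed on the raw
#'   volumes instead of modulated vesselness.
#' @return an `evaluation_params` list.
#' @export
evaluation_params <- function(sigmas = c(2, 3, 4),
                              mask_params = vesselreg::mask_params(),
                              modulation_params = vesselreg::modulation_params(),
                              use_raw_intensities = FALSE) {
  structure(list(sigmas = as.numeric(sigmas), mask_params = mask_params,
                 modulation_params = modulation_params,
                 use_raw_intensities = isTRUE(use_raw_intensities)),
            class = "evaluation_params")
}

#' Evaluate a registration before or after co-registration
#'
#' Assembles the four metrics for one pair: PSNR and NCC between the fixed
#' and (warped) moving modulated-vesselness volumes (or raw volumes on
#' request), Dice between their vessel masks, and landmark TRE. With
#' `model = NULL` the identity transform is used and the phase is
#' `"before"`; with a trained model the moving volume is warped and fixed
#' landmarks are mapped through the network (`"after"`).
#'
#' @param fixed,moving [pa_volume]s.
#' @param model a `displacement_model` or `NULL` (identity / before).
#' @param landmarks_fixed,landmarks_moving corresponding [landmark_set]s
#'   (optional; TRE reported as NA when absent).
#' @param params an [evaluation_params].
#' @param pair_id identifier copied into the report.
#' @return a one-row tibble (`metrics_report`): psnr_db, ncc, dsc,
#'   tre_mean_mm, tre_sd_mm, phase, pair_id.
#' @export
evaluate_pair <- function(fixed, moving, model = NULL,
                          landmarks_fixed = NULL, landmarks_moving = NULL,
                          params = evaluation_params(), pair_id = "pair") {
  stopifnot(is_pa_volume(fixed), is_pa_volume(moving))
  phase <- if (is.null(model)) "before" else "after"
  # fill out-of-domain regions of the warped volume with the moving
  # image's background estimate rather than hard 0: an image with a
  # nonzero baseline (e.g. a global intensity offset) would otherwise gain
  # artificial intensity cliffs at the domain boundary that corrupt the
  # vesselness-based metrics
  bg <- stats::quantile(moving$data, 0.01, names = FALSE)
  mov_eval <- if (is.null(model)) moving else
    warp_volume(model, moving, fixed, fill_value = bg)
  vp <- vesselness_params(sigmas = params$sigmas)
  if (params$use_raw_intensities) {
    img_f <- fixed
    img_m <- mov_eval
  } else {
    img_f <- adaptive_intensity_modulation(frangi_vesselness(fixed, vp),
                                           params$modulation_params)
    img_m <- adaptive_intensity_modulation(frangi_vesselness(mov_eval, vp),
                                           params$modulation_params)
  }
  mask_f <- vessel_mask(fixed, params$mask_params)
  # an all-background warped volume has an empty mask: Dice 0, not an error
  mask_m <- tryCatch(vessel_mask(mov_eval, params$mask_params),
                     error = function(e) {
                       pa_volume(array(0, dim = mov_eval$shape),
                                 spacing = mov_eval$spacing,
                                 frame_tag = "empty-mask")
                     })
  tre_mean <- NA_real_; tre_sd <- NA_real_
  if (!is.null(landmarks_fixed) && !is.null(landmarks_moving)) {
    mapped <- if (is.null(model)) {
      convert_landmarks(landmarks_fixed, fixed, "normalized")
    } else {
      transform_landmarks(model, landmarks_fixed, fixed)
    }
    vol_a <- if (is.null(model)) fixed else moving
    t_ <- tre(mapped, landmarks_moving, volume_a = vol_a, volume_b = moving)
    tre_mean <- t_$mean_mm
    tre_sd <- t_$sd_mm
  }
  tibble::tibble(
    pair_id = pair_id,
    phase = phase,
    psnr_db = psnr(img_f, img_m),
    ncc = ncc_global(img_f, img_m),
    dsc = dice(mask_f, mask_m),
    tre_mean_mm = tre_mean,
    tre_sd_mm = tre_sd
  )
}
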