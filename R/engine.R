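# The optimization loop: mask-guided patch sampling, coarse-to-fine
# vesselness similarity via local NCC, Jacobian-determinant regularization,
# Adam, and application of the trained field to volumes and landmarks.

#' Registration configuration
#'
#' Defaults reproduce the published configuration: coarse-to-fine scale
#' schedule sigma = {12, 9, 5, 3, 2} with 4000 iterations each (20,000
#' epochs total, one epoch = one sampled batch + one optimizer step),
#' loss `L_data + alpha * L_reg` with `alpha = 0.95`, 200 patch centers of
#' 5^3 lattice points (25,000 coordinates per epoch), patch side
#' `patch_side_factor * sigma_c / 100` in normalized units, Adam with
#' learning rate 5e-5, and a 6 x 300 sine network with omega = 30.
#'
#' @param sigma_schedule ordered Frangi scales (voxels), coarse to fine.
#' @param iters_per_scale optimizer iterations per scale stage.
#' @param alpha regularization weight in `[0, 1]`.
#' @param batch_centers patch centers sampled from the mask per epoch.
#' @param patch_edge_points lattice points per patch side (>= 2).
#' @param patch_side_factor patch side = `factor * sigma_c / 100`
#'   normalized units.
#' @param learning_rate Adam step size.
#' @param seed integer; one global RNG seed governs weight initialization
#'   and coordinate sampling.
#' @param arch a [network_arch].
#' @param mask_params a [mask_params].
#' @param vesselness_params a [vesselness_params]; its `sigmas` are ignored
#'   during optimization (the schedule supplies the per-stage scale) but
#'   its Frangi constants are used.
#' @param modulation_params a [modulation_params].
#' @param reg_on_centers if `TRUE` (default) the Jacobian regularizer is
#'   evaluated on the patch centers only, not on all lattice points.
#' @param sigma_unit `"voxel"` (default) or `"mm"`; mm scales are divided
#'   by the fixed image spacing before filtering.
#' @return a `registration_config` list.
#' @export
registration_config <- function(sigma_schedule = c(12, 9, 5, 3, 2),
                                iters_per_scale = 4000L,
                                alpha = 0.95,
                                batch_centers = 200L,
                                patch_edge_points = 5L,
                                patch_side_factor = 2.5,
                                learning_rate = 5e-5,
                                seed = 1L,
                                arch = network_arch(),
                                mask_params = vesselreg::mask_params(),
                                vesselness_params = vesselreg::vesselness_params(),
                                modulation_params = vesselreg::modulation_params(),
                                reg_on_centers = TRUE,
                                sigma_unit = c("voxel", "mm")) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (batch_centers < 1L) stop("`batch_centers` must be >= 1", call. = FALSE)
  if (patch_edge_points < 2L) stop("`patch_edge_points` must be >= 2",
                                   call. = FALSE)
  structure(list(
    sigma_schedule = as.numeric(sigma_schedule),
    iters_per_scale = as.integer(iters_per_scale),
    alpha = alpha,
    batch_centers = as.integer(batch_centers),
    patch_edge_points = as.integer(patch_edge_points),
    patch_side_factor = patch_side_factor,
    learning_rate = learning_rate,
    seed = as.integer(seed),
    arch = arch,
    mask_params = mask_params,
    vesselness_params = vesselness_params,
    modulation_params = modulation_params,
    reg_on_centers = isTRUE(reg_on_centers),
    sigma_unit = match.arg(sigma_unit)
  ), class = "registration_config")
}

#' Desk-scale registration configuration
#'
#' A reduced configuration for ~96^3 phantoms on one CPU: scale schedule
#' {6, 4, 2} in millimetres (15/10/5 voxels at 0.4 mm) x 300 iterations, a
#' 3 x 48 sine network (omega kept at 30), 80 patch centers and Adam
#' learning rate 3e-4. Severe (tens of mm) misalignments need more
#' capacity and budget: pass e.g. `sigma_schedule = c(12, 9, 5, 3, 2)`,
#' `iters_per_scale = 500`, `batch_centers = 100` and a 3 x 64
#' architecture.
#'
#' Two desk-scale choices compensate for the small grid. First, the scale
#' schedule is interpreted in mm: the coarse-to-fine strategy only has a
#' capture range when the coarsest smoothing is comparable to the initial
#' misalignment (at full scale the coarsest kernel is ~5 mm against
#' 6-11 mm repositioning displacements); {6,4,2} voxels would be
#' {2.4,1.6,0.8} mm, and the similarity landscape is then measurably flat
#' around the identity for typical 8 mm displacements. Second, the patch
#' side factor is raised to 10 because the patch side is defined in
#' normalized units: on several-hundred-voxel grids the default factor 2.5
#' yields a physical patch of tens of voxels, whereas on 96^3 it would
#' shrink below typical initial displacements. See the methods vignette;
#' all values can be overridden.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [registration_config()].
#' @return a `registration_config`.
#' @export
reduced_config <- function(seed = 1L, ...) {
  defaults <- list(
    sigma_schedule = c(6, 4, 2),
    iters_per_scale = 300L,
    batch_centers = 80L,
    patch_side_factor = 10,
    learning_rate = 3e-4,
    sigma_unit = "mm",
    arch = network_arch(n_hidden_layers = 3L, units_per_layer = 48L,
                        seed = NULL),
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(registration_config, args)
}

#' Sample mask-guided patch coordinates
#'
#' Draws `batch_centers` voxels uniformly without replacement from the
#' mask, converts them to normalized coordinates, and expands each into an
#' axis-aligned cubic lattice of `patch_edge_points^3` points with side
#' `patch_side_factor * sigma_c / 100` normalized units, centred on the
#' centre point.
#'
#' @param mask binary mask [pa_volume] (from [vessel_mask()]).
#' @param sigma_c current scale (same units as the schedule).
#' @param config a [registration_config].
#' @return list with `centers` (P x 3 normalized), `coords`
#'   (P*K x 3 normalized, patch-major order), `patch` (integer patch id per
#'   coordinate row), `side` (patch side in normalized units).
#' @export
sample_patch_coordinates <- function(mask, sigma_c, config) {
  stopifnot(is_pa_volume(mask), inherits(config, "registration_config"))
  idx <- which(mask$data > 0)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  sample_patches_from_index(mask, idx, sigma_c, config)
}

# internal fast path: mask linear indices precomputed once per run
sample_patches_from_index <- function(mask, lin_idx, sigma_c, config) {
  P <- config$batch_centers
  replace <- length(lin_idx) < P
  if (replace) {
    warning("mask smaller than batch_centers; sampling with replacement")
  }
  take <- lin_idx[sample.int(length(lin_idx), P, replace = replace)]
  vox <- arrayInd(take, mask$shape) - 1
  centers <- voxel_to_normalized(mask, vox)
  p <- config$patch_edge_points
  side <- config$patch_side_factor * sigma_c / 100
  off1 <- seq(-side / 2, side / 2, length.out = p)
  offs <- as.matrix(expand.grid(x = off1, y = off1, z = off1))
  dimnames(offs) <- NULL
  K <- nrow(offs)
  coords <- centers[rep(seq_len(P), each = K), , drop = FALSE] +
    offs[rep(seq_len(K), times = P), , drop = FALSE]
  list(centers = centers, coords = coords,
       patch = rep(seq_len(P), each = K), side = side)
}

#' Patch-wise normalized cross correlation loss
#'
#' Per patch, `NCC = sum(f~ m~) / sqrt(sum(f~^2) sum(m~^2) + eps)` with
#' centred intensities; the data loss is `1 - mean(NCC)` over patches.
#' Patches whose centred energy falls below `eps` in either image
#' contribute NCC 0 (and zero gradient): a patch mapped onto empty
#' background neither helps nor hurts.
#'
#' @param fixed_patches P x K matrix (rows = patches) of fixed intensities.
#' @param moving_patches P x K matrix of moving intensities.
#' @param eps degeneracy guard.
#' @return scalar data loss.
#' @export
local_ncc_loss <- function(fixed_patches, moving_patches, eps = 1e-8) {
  local_ncc(fixed_patches, moving_patches, eps, want_grad = FALSE)$loss
}

local_ncc <- function(fixed_patches, moving_patches, eps = 1e-8,
                      want_grad = TRUE) {
  F_ <- as.matrix(fixed_patches)
  M_ <- as.matrix(moving_patches)
  if (!identical(dim(F_), dim(M_))) {
    stop("fixed and moving patch matrices must have identical shape",
         call. = FALSE)
  }
  if (ncol(F_) < 2L) stop("patches need at least 2 samples", call. = FALSE)
  P <- nrow(F_)
  Fc <- F_ - rowMeans(F_)
  Mc <- M_ - rowMeans(M_)
  Sf <- rowSums(Fc^2)
  Sm <- rowSums(Mc^2)
  u <- rowSums(Fc * Mc)
  D <- sqrt(Sf * Sm + eps)
  ncc <- u / D
  degen <- (Sf < eps) | (Sm < eps)
  ncc[degen] <- 0
  out <- list(loss = 1 - mean(ncc), ncc = ncc)
  if (want_grad) {
    # d loss / d m_ij; centring needs no correction because the weights of
    # the mean term sum to zero
    g <- Fc / D - (u * Sf / D^3) * Mc
    g[degen, ] <- 0
    out$grad_moving <- -g / P
  }
  out
}

#' Jacobian-determinant regularizer
#'
#' `L_reg = mean(|det J_Phi - 1|)`: penalizes local expansion and
#' shrinkage of the transformation while leaving rotations and shears of
#' unit volume change unpenalized.
#'
#' @param jacobians N x 3 x 3 array of transformation Jacobians.
#' @return scalar regularization loss.
#' @export
jacobian_regularizer <- function(jacobians) {
  jac_reg(jacobians, want_grad = FALSE)$loss
}

jac_reg <- function(J, want_grad = TRUE) {
  if (length(dim(J)) != 3L || any(dim(J)[2:3] != 3L)) {
    stop("`jacobians` must be N x 3 x 3", call. = FALSE)
  }
  a <- J[, 1, 1]; b <- J[, 1, 2]; c <- J[, 1, 3]
  d <- J[, 2, 1]; e <- J[, 2, 2]; f <- J[, 2, 3]
  g <- J[, 3, 1]; h <- J[, 3, 2]; i <- J[, 3, 3]
  det <- a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g)
  out <- list(loss = mean(abs(det - 1)), det = det)
  if (want_grad) {
    N <- length(det)
    s <- sign(det - 1) / N
    G <- array(0, dim = dim(J))
    G[, 1, 1] <- s * (e * i - f * h)
    G[, 1, 2] <- s * (f * g - d * i)
    G[, 1, 3] <- s * (d * h - e * g)
    G[, 2, 1] <- s * (c * h - b * i)
    G[, 2, 2] <- s * (a * i - c * g)
    G[, 2, 3] <- s * (b * g - a * h)
    G[, 3, 1] <- s * (b * f - c * e)
    G[, 3, 2] <- s * (c * d - a * f)
    G[, 3, 3] <- s * (a * e - b * d)
    out$grad <- G
  }
  out
}

# ---- Adam --------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  list(
    mW = lapply(model$W, zero_like), vW = lapply(model$W, zero_like),
    mb = lapply(model$b, zero_like), vb = lapply(model$b, zero_like),
    mWo = zero_like(model$Wo), vWo = zero_like(model$Wo),
    mbo = zero_like(model$bo), vbo = zero_like(model$bo),
    t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8
  )
}

adam_step <- function(model, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  upd <- function(param, grad, m, v) {
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    param <- param - lr * (m / c1) / (sqrt(v / c2) + state$eps)
    list(param = param, m = m, v = v)
  }
  for (l in seq_along(model$W)) {
    r <- upd(model$W[[l]], grads$W[[l]], state$mW[[l]], state$vW[[l]])
    model$W[[l]] <- r$param; state$mW[[l]] <- r$m; state$vW[[l]] <- r$v
    r <- upd(model$b[[l]], grads$b[[l]], state$mb[[l]], state$vb[[l]])
    model$b[[l]] <- r$param; state$mb[[l]] <- r$m; state$vb[[l]] <- r$v
  }
  r <- upd(model$Wo, grads$Wo, state$mWo, state$vWo)
  model$Wo <- r$param; state$mWo <- r$m; state$vWo <- r$v
  r <- upd(model$bo, grads$bo, state$mbo, state$vbo)
  model$bo <- r$param; state$mbo <- r$m; state$vbo <- r$v
  list(model = model, state = state)
}

# ---- the optimization loop ---------------------------------------------

#' Register a moving volume to a fixed volume
#'
#' Runs the coarse-to-fine optimization: for each scale in
#' `config$sigma_schedule` the modulated Frangi vesselness of both volumes
#' is precomputed at that scale; each iteration then samples a batch of
#' mask-guided patch coordinates x, evaluates the fixed vesselness at x and
#' the moving vesselness at `Phi(x) = x + u(x)` by trilinear interpolation,
#' forms the loss `(1 - mean patch NCC) + alpha * mean|det J_Phi - 1|`, and
#' takes one Adam step. One global RNG (from `config$seed`) governs weight
#' initialization and all sampling, so a run is exactly reproducible.
#'
#' @param fixed,moving [pa_volume]s on the same grid convention.
#' @param config a [registration_config].
#' @param verbose print per-stage progress.
#' @return an object of class `vessel_registration`: list with `model`
#'   (the trained `displacement_model`), `history` (tibble of per-iteration
#'   losses), `config`, `mask`, and timing.
#' @export
register <- function(fixed, moving, config = registration_config(),
                     verbose = FALSE) {
  stopifnot(is_pa_volume(fixed), is_pa_volume(moving),
            inherits(config, "registration_config"))
  t0 <- Sys.time()
  set.seed(config$seed)
  arch <- config$arch
  arch$seed <- NULL                 # init from the global stream
  model <- init_network(arch)
  mask <- vessel_mask(fixed, config$mask_params)
  mask_idx <- which(mask$data > 0)

  sched_vox <- config$sigma_schedule
  if (identical(config$sigma_unit, "mm")) {
    sched_vox <- config$sigma_schedule / mean(fixed$spacing)
  }
  n_stage <- length(sched_vox)
  total <- n_stage * config$iters_per_scale
  hist_it <- integer(total); hist_sigma <- numeric(total)
  hist_data <- numeric(total); hist_reg <- numeric(total)
  hist_total <- numeric(total)
  state <- adam_init(model)
  P <- config$batch_centers
  Kp <- config$patch_edge_points^3
  it_global <- 0L

  for (s in seq_len(n_stage)) {
    sigma_c <- sched_vox[s]
    vp <- config$vesselness_params
    vp$sigmas <- sigma_c
    fv <- adaptive_intensity_modulation(frangi_vesselness(fixed, vp),
                                        config$modulation_params)
    mv <- adaptive_intensity_modulation(frangi_vesselness(moving, vp),
                                        config$modulation_params)
    for (it in seq_len(config$iters_per_scale)) {
      batch <- sample_patches_from_index(mask, mask_idx,
                                         config$sigma_schedule[s], config)
      fvals <- sample_intensity(fv, batch$coords)
      fw <- net_forward(model, batch$coords)
      phi <- batch$coords + fw$u
      mg <- sample_intensity_grad(mv, phi)
      # patches are contiguous blocks of Kp rows; rows of the P x Kp
      # matrices are patches
      Fp <- matrix(fvals, nrow = P, ncol = Kp, byrow = TRUE)
      Mp <- matrix(mg$value, nrow = P, ncol = Kp, byrow = TRUE)
      ncc <- local_ncc(Fp, Mp)
      dLdm <- as.numeric(t(ncc$grad_moving))     # back to coordinate order
      Ubar <- dLdm * mg$grad
      grads <- net_backward(model, fw, Ubar)
      # regularizer on the patch centers
      reg_pts <- if (config$reg_on_centers) batch$centers else batch$coords
      fwc <- net_forward(model, reg_pts, want_tangent = TRUE)
      J <- fwc$Ju
      for (ii in 1:3) J[, ii, ii] <- J[, ii, ii] + 1
      reg <- jac_reg(J)
      Jbar <- config$alpha * reg$grad
      gregs <- net_backward(model, fwc,
                            matrix(0, nrow(reg_pts), 3L), Jbar)
      for (l in seq_along(grads$W)) {
        grads$W[[l]] <- grads$W[[l]] + gregs$W[[l]]
        grads$b[[l]] <- grads$b[[l]] + gregs$b[[l]]
      }
      grads$Wo <- grads$Wo + gregs$Wo
      grads$bo <- grads$bo + gregs$bo
      tot <- ncc$loss + config$alpha * reg$loss
      if (!is.finite(tot)) {
        stop(sprintf(
          "non-finite loss at stage %d (sigma=%g), iteration %d: data=%g reg=%g",
          s, sigma_c, it, ncc$loss, reg$loss), call. = FALSE)
      }
      stp <- adam_step(model, grads, state, config$learning_rate)
      model <- stp$model; state <- stp$state
      it_global <- it_global + 1L
      hist_it[it_global] <- it_global
      hist_sigma[it_global] <- config$sigma_schedule[s]
      hist_data[it_global] <- ncc$loss
      hist_reg[it_global] <- reg$loss
      hist_total[it_global] <- tot
    }
    model$training_state$stage <- s
    model$training_state$iteration <- it_global
    if (verbose) {
      last <- which(hist_sigma[seq_len(it_global)] == config$sigma_schedule[s])
      message(sprintf("stage %d/%d (sigma=%g): total loss %.4f -> %.4f",
                      s, n_stage, config$sigma_schedule[s],
                      hist_total[last[1]], hist_total[it_global]))
    }
  }
  history <- tibble::tibble(
    iteration = hist_it, sigma = hist_sigma, data_loss = hist_data,
    reg_loss = hist_reg, total_loss = hist_total
  )
  structure(list(model = model, history = history, config = config,
                 mask = mask,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
            class = "vessel_registration")
}

#' @export
print.vessel_registration <- function(x, ...) {
  cat(sprintf(
    "<vessel_registration> %d stage(s), %d epochs, final loss %.4f (%.1f s)\n",
    length(x$config$sigma_schedule), nrow(x$history),
    x$history$total_loss[nrow(x$history)], x$elapsed_s))
  invisible(x)
}

#' Per-iteration training history of a registration fit
#'
#' @param x a `vessel_registration`.
#' @param ... unused.
#' @return tibble with one row per epoch: iteration, sigma, data_loss,
#'   reg_loss, total_loss.
#' @export
tidy.vessel_registration <- function(x, ...) x$history

#' One-row summary of a registration fit
#'
#' @inheritParams tidy.vessel_registration
#' @return one-row tibble: stages, epochs, final losses, parameter count,
#'   elapsed seconds.
#' @export
glance.vessel_registration <- function(x, ...) {
  n <- nrow(x$history)
  tibble::tibble(
    n_stages = length(x$config$sigma_schedule),
    n_epochs = n,
    final_data_loss = x$history$data_loss[n],
    final_reg_loss = x$history$reg_loss[n],
    final_total_loss = x$history$total_loss[n],
    n_params = n_params(x$model),
    elapsed_s = x$elapsed_s
  )
}

#' Generic tidiers
#'
#' `tidy()` and `glance()` generics (re-exported conventions) for fitted
#' registration objects.
#' @param x object.
#' @param ... passed on.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Warp the moving volume onto a fixed grid
#'
#' `out(x) = moving(Phi(x))` for every voxel x of `output_grid`,
#' trilinearly interpolated; coordinates mapped outside the moving domain
#' are filled with 0.
#'
#' @param model a trained (or identity) `displacement_model`.
#' @param moving the moving [pa_volume].
#' @param output_grid a [pa_volume] defining the output grid (defaults to
#'   the moving grid descriptor).
#' @param chunk points per evaluation chunk.
#' @param fill_value intensity for coordinates mapped outside the moving
#'   domain (default 0, the dark-background convention).
#' @return warped [pa_volume] on `output_grid`.
#' @export
warp_volume <- function(model, moving, output_grid = moving,
                        chunk = 100000L, fill_value = 0) {
  stopifnot(inherits(model, "displacement_model"), is_pa_volume(moving),
            is_pa_volume(output_grid))
  idx <- grid_voxel_coords(output_grid$shape)
  xn <- voxel_to_normalized(output_grid, idx)
  vals <- numeric(nrow(xn))
  for (start in seq(1L, nrow(xn), by = chunk)) {
    end <- min(start + chunk - 1L, nrow(xn))
    blk <- xn[start:end, , drop = FALSE]
    phi <- blk + net_forward(model, blk)$u
    vals[start:end] <- sample_intensity(moving, phi, fill_value)
  }
  pa_volume(array(vals, dim = output_grid$shape),
            spacing = output_grid$spacing,
            frame_tag = paste0(moving$frame_tag, ":warped"))
}

#' Map fixed-image landmarks into the moving frame
#'
#' Feeds the landmark coordinates through the trained network:
#' `x -> Phi(x)`. Input landmarks may be in any frame; they are converted
#' to normalized coordinates of the fixed grid first and must lie inside
#' the `[-1, 1]^3` domain.
#'
#' @param model a `displacement_model`.
#' @param landmarks a [landmark_set] on the fixed image.
#' @param fixed the fixed [pa_volume] (grid geometry for conversion).
#' @return a [landmark_set] in the normalized frame of the moving image,
#'   names preserved in order.
#' @export
transform_landmarks <- function(model, landmarks, fixed) {
  stopifnot(inherits(model, "displacement_model"),
            inherits(landmarks, "landmark_set"), is_pa_volume(fixed))
  lm_norm <- assert_landmarks_in_cube(landmarks, fixed)
  phi <- transform_coords(model, lm_norm$points)
  landmark_set(landmarks$names, phi, frame = "normalized",
               volume_ref = "moving")
}
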