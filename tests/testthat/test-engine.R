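# Sampling, losses, warping, landmark transforms, and a small end-to-end
# self-registration.

test_that("patch sampling: counts, side lengths, mask membership, seeding", {
  ph <- small_phantom(seed = 6)
  mask <- vessel_mask(ph$volume, mask_params(t_surface = 0.4))
  cfg <- registration_config()    # paper defaults: 200 centers, 5^3 patch

  set.seed(1)
  b <- sample_patch_coordinates(mask, sigma_c = 12, config = cfg)
  expect_identical(nrow(b$coords), 200L * 125L)   # 25,000 coordinates
  expect_equal(b$side, 0.3)                       # 2.5 * 12 / 100
  # lattice point spacing 0.075 along each axis
  first_patch <- b$coords[1:125, 1]
  expect_equal(sort(unique(round(diff(sort(unique(first_patch))), 9))), 0.075)

  # every centre lies inside the mask
  vox <- round(normalized_to_voxel(mask, b$centers))
  lin <- 1 + vox[, 1] + mask$shape[1] * (vox[, 2] + mask$shape[2] * vox[, 3])
  expect_true(all(mask$data[lin] > 0))

  # fixed seed reproduces the batch exactly
  set.seed(1)
  b2 <- sample_patch_coordinates(mask, sigma_c = 12, config = cfg)
  expect_identical(b$coords, b2$coords)

  # tiny mask: sampling with replacement plus a warning
  tiny <- pa_volume(array(0, c(8, 8, 8)), spacing = 1)
  tiny$data[4, 4, 4] <- 1
  expect_warning(sample_patch_coordinates(tiny, 6, cfg), "replacement")
})

test_that("local NCC: self-similarity, affine invariance, brute-force oracle", {
  set.seed(10)
  f <- matrix(stats::runif(4 * 125), 4, 125)
  expect_lt(abs(local_ncc_loss(f, f)), 1e-9)   # eps-guarded denominator
  expect_lt(abs(local_ncc_loss(f, 0.5 * f + 3)), 1e-6)

  # brute-force elementwise oracle on one 125-sample patch pair
  m <- matrix(stats::runif(125), 1, 125)
  f1 <- f[1, , drop = FALSE]
  fc <- f1 - mean(f1); mc <- m - mean(m)
  want <- 1 - sum(fc * mc) / sqrt(sum(fc^2) * sum(mc^2) + 1e-8)
  expect_lt(abs(local_ncc_loss(f1, m) - want), 1e-6)

  # constant patch contributes NCC 0
  cst <- matrix(1, 1, 125)
  expect_equal(local_ncc_loss(cst, m), 1)

  # analytic gradient vs finite differences
  r <- vesselreg:::local_ncc(f, f * 0.8 + 0.1)
  h <- 1e-7
  for (k in c(1L, 77L, 300L)) {
    mp <- f * 0.8 + 0.1; mp[k] <- mp[k] + h
    mm <- f * 0.8 + 0.1; mm[k] <- mm[k] - h
    fd <- (local_ncc_loss(f, mp) - local_ncc_loss(f, mm)) / (2 * h)
    expect_lt(abs(fd - r$grad_moving[k]), 1e-5)
  }
})

test_that("jacobian regularizer: identity, diagonal case, loop oracle, gradient", {
  J <- array(0, c(5, 3, 3))
  for (n in 1:5) J[n, , ] <- diag(3)
  expect_equal(jacobian_regularizer(J), 0)
  J1 <- array(diag(c(2, 1, 1)), c(3, 3, 1))
  J1 <- aperm(J1, c(3, 1, 2))
  expect_equal(jacobian_regularizer(J1), 1)

  set.seed(12)
  J <- array(stats::rnorm(9 * 20, sd = 0.4), c(20, 3, 3))
  for (n in 1:20) J[n, , ] <- J[n, , ] + diag(3)
  loop <- mean(vapply(1:20, function(n) abs(det(J[n, , ]) - 1), numeric(1)))
  expect_lt(abs(jacobian_regularizer(J) - loop), 1e-12)

  g <- vesselreg:::jac_reg(J)$grad
  h <- 1e-6
  for (idx in list(c(3, 1, 2), c(17, 3, 3), c(9, 2, 1))) {
    Jp <- J; Jp[idx[1], idx[2], idx[3]] <- Jp[idx[1], idx[2], idx[3]] + h
    Jm <- J; Jm[idx[1], idx[2], idx[3]] <- Jm[idx[1], idx[2], idx[3]] - h
    fd <- (jacobian_regularizer(Jp) - jacobian_regularizer(Jm)) / (2 * h)
    expect_lt(abs(fd - g[idx[1], idx[2], idx[3]]), 1e-6)
  }
})

test_that("warp_volume: identity, pure translation, fill contract", {
  ph <- small_phantom(seed = 9, noise = 0)
  v <- ph$volume
  ident <- tiny_model()
  ident$Wo[] <- 0
  ident$bo[] <- 0
  w <- warp_volume(ident, v)
  expect_lt(max(abs(w$data - v$data)), 1e-6)

  # translation of +5 voxels along x encoded in the final bias
  shift_model <- ident
  shift_model$bo <- c(5 * 2 / (v$shape[1] - 1), 0, 0)
  w5 <- warp_volume(shift_model, v)
  inner <- 1:(v$shape[1] - 5)
  expect_lt(max(abs(w5$data[inner, , ] - v$data[inner + 5, , ])), 1e-6)
  # regions mapping outside the moving domain are exactly 0
  expect_true(all(w5$data[(v$shape[1] - 4):v$shape[1], , ] == 0))
})

test_that("transform_landmarks: identity, analytic translation, bookkeeping", {
  ph <- small_phantom(seed = 9, noise = 0)
  v <- ph$volume
  lm <- ph$landmarks
  ident <- tiny_model()
  ident$Wo[] <- 0
  ident$bo[] <- 0
  out <- transform_landmarks(ident, lm, v)
  expect_identical(out$names, lm$names)
  expect_equal(out$points, convert_landmarks(lm, v, "normalized")$points,
               tolerance = 1e-12)

  shift <- ident
  shift$bo <- c(0.1, -0.05, 0.02)
  got <- transform_landmarks(shift, lm, v)$points
  want <- sweep(convert_landmarks(lm, v, "normalized")$points, 2,
                shift$bo, "+")
  expect_lt(max(abs(got - want)), 1e-3)

  far <- landmark_set("outside", rbind(c(500, 0, 0)), frame = "voxel")
  expect_error(transform_landmarks(ident, far, v), "outside")
})

test_that("raising the regularizer weight shrinks |det J - 1|", {
  ph <- small_phantom(seed = 5)
  def <- generate_deformation(ph$volume, magnitude_target_mm = 3, seed = 7L)
  pair <- make_pair(ph, def)
  vals <- vapply(c(0.95, 9.5, 95), function(alpha) {
    cfg <- reduced_config(seed = 4, sigma_schedule = c(4, 2),
                          iters_per_scale = 100L)
    cfg$alpha <- alpha          # sweep past the [0,1] constructor range
    fit <- register(pair$fixed, pair$moving, cfg)
    vox <- arrayInd(which(fit$mask$data > 0), fit$mask$shape) - 1
    J <- jacobian(fit$model, voxel_to_normalized(pair$fixed, vox))
    mean(abs(vesselreg:::jac_reg(J, want_grad = FALSE)$det - 1))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("self-registration converges to a near-identity field", {
  ph <- small_phantom(seed = 5)
  cfg <- reduced_config(seed = 2, sigma_schedule = c(4, 2),
                        iters_per_scale = 120L)
  fit <- register(ph$volume, ph$volume, cfg)
  expect_s3_class(fit, "vessel_registration")
  expect_identical(nrow(fit$history), 240L)

  mask_idx <- which(fit$mask$data > 0)
  vox <- arrayInd(mask_idx, fit$mask$shape) - 1
  u <- displace(fit$model, voxel_to_normalized(ph$volume, vox))
  uvox <- sweep(u, 2, (ph$volume$shape - 1) / 2, "*")
  expect_lt(mean(sqrt(rowSums(uvox^2))), 0.5)

  # per-stage optimization progress: late-iteration median loss below the
  # early-iteration median
  for (s in unique(fit$history$sigma)) {
    hs <- fit$history$total_loss[fit$history$sigma == s]
    n <- length(hs)
    k <- max(1L, floor(0.1 * n))
    expect_lt(stats::median(hs[(n - k + 1):n]), stats::median(hs[1:k]))
  }

  # tidiers
  expect_identical(tidy(fit), fit$history)
  g <- glance(fit)
  expect_identical(g$n_epochs, 240L)
  expect_identical(g$n_params, n_params(fit$model))
})
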