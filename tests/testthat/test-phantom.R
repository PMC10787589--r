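# Synthetic phantom generator and ground-truth deformations.

test_that("vessel tree: binary-tree counts, radii, reproducibility", {
  for (L in c(3L, 4L)) {
    spec <- phantom_spec(tree_depth = L, seed = 20L + L)
    tr <- suppressWarnings(generate_vessel_tree(spec))
    expect_equal(nrow(tr$edges), 2^L - 1)
    expect_equal(length(tr$branch_nodes), 2^(L - 1) - 1)
    # radii nonincreasing from parent to child
    for (e in seq_len(nrow(tr$edges))) {
      parent <- tr$edges[tr$edges$to == tr$edges$from[e], ]
      if (nrow(parent)) expect_lte(tr$edges$radius[e], parent$radius)
    }
  }
  s <- phantom_spec(seed = 33L)
  t1 <- suppressWarnings(generate_vessel_tree(s))
  t2 <- suppressWarnings(generate_vessel_tree(s))
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$edges, t2$edges)
})

test_that("rasterization: background support, fluence attenuation, landmarks", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L), tree_depth = 3L,
                       segment_length_vox = 16, root_radius_vox = 3,
                       noise_sigma = 0, background_level = 0.02, seed = 5L)
  ph <- rasterize_phantom(generate_vessel_tree(spec), spec)
  # voxels farther than 2 * max radius from all centerlines are exactly
  # background
  pieces <- vesselreg:::subdivide_edges(ph$tree, max_len = 1)
  idx <- grid_voxel_coords(spec$grid_shape)[seq(1, 48^3, by = 97), ]
  mind <- rep(Inf, nrow(idx))
  segs <- rbind(pieces$starts)
  for (s in seq_len(nrow(pieces$starts))) {
    a <- pieces$starts[s, ]; b <- pieces$ends[s, ]
    ab <- b - a; l2 <- max(sum(ab^2), 1e-12)
    t_ <- pmin(pmax(((idx[, 1] - a[1]) * ab[1] + (idx[, 2] - a[2]) * ab[2] +
                       (idx[, 3] - a[3]) * ab[3]) / l2, 0), 1)
    d <- sqrt((idx[, 1] - a[1] - t_ * ab[1])^2 +
                (idx[, 2] - a[2] - t_ * ab[2])^2 +
                (idx[, 3] - a[3] - t_ * ab[3])^2)
    mind <- pmin(mind, d)
  }
  far <- mind > 2 * max(ph$tree$edges$radius)
  lin <- 1 + idx[, 1] + 48 * (idx[, 2] + 48 * idx[, 3])
  expect_true(all(ph$volume$data[lin[far]] == spec$background_level))

  # landmarks inside the grid
  expect_true(all(ph$landmarks$points >= 0))
  expect_true(all(sweep(ph$landmarks$points, 2, spec$grid_shape - 1, "<=")))
})

test_that("depth attenuation of equal tubes follows exp(-depth/tau)", {
  shape <- c(40L, 40L, 120L)
  # equal-radius tubes at depths 10 mm and 40 mm, tau = 30 mm, 1 mm voxels
  t1 <- vesselreg:::rasterize_capsules(shape, matrix(c(5, 20, 10), 1),
                                       matrix(c(34, 20, 10), 1), 3)
  t2 <- vesselreg:::rasterize_capsules(shape, matrix(c(5, 20, 40), 1),
                                       matrix(c(34, 20, 40), 1), 3)
  v0 <- pa_volume(t1 + t2, spacing = 1)
  depth <- depth_map(v0, 3L)
  img <- (t1 + t2) * exp(-depth / 30)
  m1 <- mean(img[t1 > 0.99])
  m2 <- mean(img[t2 > 0.99])
  expect_lt(abs(m1 / m2 - exp(1)), 0.1 * exp(1))
})

test_that("ground-truth deformation: identity, magnitude contract, det J > 0", {
  grid <- pa_volume(array(0, c(48, 48, 48)) + 1, spacing = 0.4)
  id <- generate_deformation(grid, magnitude_target_mm = 0)
  pts <- matrix(stats::runif(30, 0, 18), 10, 3)
  expect_identical(id$phi(pts), pts)
  expect_equal(id$realized_mean_mm, 0)

  def <- generate_deformation(grid, magnitude_target_mm = 8, seed = 3L)
  expect_gte(def$realized_mean_mm, 7.2)
  expect_lte(def$realized_mean_mm, 8.8)
  # determinant positive at every grid node
  X <- voxel_to_mm(grid, grid_voxel_coords(grid$shape))
  dets <- vesselreg:::jac_reg(def$jac(X), want_grad = FALSE)$det
  expect_gt(min(dets), 0)
  # analytic Jacobian consistent with finite differences of phi
  x0 <- matrix(c(9, 7, 11), 1)
  J <- def$jac(x0)[1, , ]
  h <- 1e-5
  for (k in 1:3) {
    e <- matrix(0, 1, 3); e[k] <- h
    fd <- (def$phi(x0 + e) - def$phi(x0 - e)) / (2 * h)
    expect_lt(max(abs(J[, k] - fd)), 1e-6)
  }
  # Newton inverse really inverts
  y <- def$phi(pts)
  expect_lt(max(abs(def$inverse(y) - pts)), 1e-6)
})

test_that("make_pair: identity pair, landmark construction, gain, TRE oracle", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L), tree_depth = 3L,
                       segment_length_vox = 16, root_radius_vox = 3,
                       noise_sigma = 0, seed = 5L)
  ph <- rasterize_phantom(generate_vessel_tree(spec), spec)
  id <- generate_deformation(ph$volume, 0)
  pair0 <- make_pair(ph, id)
  expect_equal(pair0$moving$data, pair0$fixed$data, tolerance = 1e-12)

  def <- generate_deformation(ph$volume, magnitude_target_mm = 5, seed = 7L)
  pair <- make_pair(ph, def)
  want <- mm_to_voxel(pair$fixed,
                      def$phi(voxel_to_mm(pair$fixed,
                                          pair$landmarks_fixed$points)))
  expect_lt(max(abs(pair$landmarks_moving$points - want)), 1e-9)

  # before-registration TRE equals the realized displacement at landmarks
  lmf_n <- convert_landmarks(pair$landmarks_fixed, pair$fixed, "normalized")
  t0 <- tre(lmf_n, pair$landmarks_moving, volume_a = pair$fixed,
            volume_b = pair$moving)
  lm_mm <- voxel_to_mm(pair$fixed, pair$landmarks_fixed$points)
  realized <- mean(sqrt(rowSums((def$phi(lm_mm) - lm_mm)^2)))
  expect_lt(abs(t0$mean_mm - realized), 1e-6)

  # intensity gain scales intra-vessel intensities linearly
  pg <- make_pair(ph, id, intensity_gain = 1.2)
  vessel <- ph$volume$data > 0.5
  ratio <- mean(pg$moving$data[vessel]) / mean(pair0$moving$data[vessel])
  expect_lt(abs(ratio - 1.2), 0.024)

  # FOV crop zeroes outside and flags landmarks
  crop <- rbind(c(0, 0, 0), c(23, 47, 47))
  pc <- make_pair(ph, def, fov_crop = crop)
  expect_true(all(pc$moving$data[25:48, , ] == 0))
  inside <- pc$landmarks_moving$points[, 1] <= 23 &
    apply(pc$landmarks_moving$points >= 0, 1, all) &
    apply(sweep(pc$landmarks_moving$points, 2, c(47, 47, 47), "<="), 1, all)
  expect_identical(pc$in_fov, inside)
})

test_that("resampling mode approximates the re-rasterized moving image", {
  spec <- phantom_spec(grid_shape = c(40L, 40L, 40L), tree_depth = 3L,
                       segment_length_vox = 13, root_radius_vox = 3,
                       noise_sigma = 0, seed = 8L)
  ph <- rasterize_phantom(generate_vessel_tree(spec), spec)
  def <- generate_deformation(ph$volume, magnitude_target_mm = 2, seed = 9L)
  pr <- make_pair(ph, def, mode = "rerasterize")
  ps <- make_pair(ph, def, mode = "resample")
  # same support, values agree except for interpolation blur at tube edges
  expect_gt(stats::cor(as.numeric(pr$moving$data), as.numeric(ps$moving$data)),
            0.95)
})
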