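# Hessian analysis, Frangi vesselness and adaptive intensity modulation.

test_that("hessian eigenvalues: zero curvature, quadratic oracle, sortedness", {
  cv <- pa_volume(array(5, c(12, 12, 12)))
  e <- hessian_eigenvalues(cv, 2)
  expect_lt(max(abs(e$lambda1), abs(e$lambda2), abs(e$lambda3)), 1e-10)

  # separable quadratic f(i,j,k) = i^2: gamma-normalized interior
  # eigenvalues (0, 0, 2 sigma^2)
  n <- 33L
  arr <- array(rep((0:(n - 1))^2, times = n * n), c(n, n, n))
  v <- pa_volume(arr, spacing = 1)
  for (sigma in c(2, 3)) {
    e <- hessian_eigenvalues(v, sigma)
    mid <- 17L
    expect_equal(e$lambda3[mid, mid, mid], 2 * sigma^2, tolerance = 1e-6)
    expect_lt(abs(e$lambda1[mid, mid, mid]), 1e-4)
    expect_lt(abs(e$lambda2[mid, mid, mid]), 1e-4)
  }

  # sortedness |l1| <= |l2| <= |l3| everywhere on a random volume
  r <- random_volume(c(12L, 12L, 12L), seed = 3)
  e <- hessian_eigenvalues(r, 1.5)
  expect_true(all(abs(e$lambda1) <= abs(e$lambda2) + 1e-12))
  expect_true(all(abs(e$lambda2) <= abs(e$lambda3) + 1e-12))
  expect_error(hessian_eigenvalues(r, 0), "positive")
})

test_that("hessian agrees with a dense finite-difference oracle", {
  set.seed(11)
  arr <- array(stats::rnorm(16^3), c(16, 16, 16))
  v <- pa_volume(arr, spacing = 1)
  sigma <- 2
  sm <- vesselreg:::gaussian_smooth_3d(arr, sigma)
  e <- hessian_eigenvalues(v, sigma)
  worst <- 0
  for (p in list(c(8, 8, 8), c(5, 10, 7), c(11, 6, 9))) {
    fd <- matrix(0, 3, 3)
    val <- function(o) sm[p[1] + o[1], p[2] + o[2], p[3] + o[3]]
    for (a in 1:3) for (b in 1:3) {
      ea <- numeric(3); ea[a] <- 1
      eb <- numeric(3); eb[b] <- 1
      fd[a, b] <- if (a == b) {
        val(ea) - 2 * val(numeric(3)) + val(-ea)
      } else {
        (val(ea + eb) - val(ea - eb) - val(-ea + eb) + val(-ea - eb)) / 4
      }
    }
    fd <- fd * sigma^2
    want <- sort(eigen(fd, symmetric = TRUE)$values)
    got <- sort(c(e$lambda1[p[1], p[2], p[3]], e$lambda2[p[1], p[2], p[3]],
                  e$lambda3[p[1], p[2], p[3]]))
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-3)
})

test_that("frangi vesselness: bounds, constant volume, multiscale max", {
  cv <- pa_volume(array(2, c(16, 16, 16)))
  expect_equal(max(frangi_vesselness(cv)$data), 0)

  r <- random_volume(c(16L, 16L, 16L), seed = 8)
  pr <- vesselness_params(sigmas = c(1.5, 2.5))
  out <- frangi_vesselness(r, pr)
  expect_true(all(out$data >= 0 & out$data <= 1))
  s1 <- frangi_vesselness(r, vesselness_params(sigmas = 1.5))
  s2 <- frangi_vesselness(r, vesselness_params(sigmas = 2.5))
  expect_equal(out$data, pmax(s1$data, s2$data))
})

test_that("frangi peaks on the tube centerline, also for oblique tubes", {
  # axis-aligned tube of radius 3
  tv <- tube_volume()
  fr <- frangi_vesselness(tv, vesselness_params(sigmas = 3))
  am <- arrayInd(which.max(fr$data), dim(fr$data)) - 1
  expect_lt(sqrt(sum((am[2:3] - c(20, 20))^2)), 1 + 1e-9)

  # tubes rotated 45 degrees about each axis
  ctr <- c(20, 20, 20)
  dirs <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
  for (d in dirs) {
    d <- d / sqrt(sum(d^2))
    tvr <- tube_volume(a = ctr - 14 * d, b = ctr + 14 * d, radius = 3)
    fr <- frangi_vesselness(tvr, vesselness_params(sigmas = 3))
    am <- arrayInd(which.max(fr$data), dim(fr$data)) - 1
    rel <- am - (ctr - 14 * d)
    perp <- rel - sum(rel * d) * d
    expect_lt(sqrt(sum(perp^2)), 1 + 1e-9)
  }
})

test_that("centerline response is scale-selective near the tube radius", {
  scales <- c(12, 9, 5, 3, 2)
  for (r_tube in c(3, 5)) {
    tv <- tube_volume(shape = c(48L, 48L, 48L), a = c(5, 24, 24),
                      b = c(42, 24, 24), radius = r_tube)
    resp <- vapply(scales, function(s) {
      vesselreg:::frangi_single_scale(tv, s,
                                      vesselness_params(sigmas = s))[25, 25, 25]
    }, numeric(1))
    best <- which.max(resp)
    nearest <- which.min(abs(scales - r_tube))
    expect_lte(abs(best - nearest), 1L)
  }
})

test_that("adaptive modulation: zeros, depth equalization, monotonicity", {
  z <- pa_volume(array(0, c(8, 8, 8)))
  expect_warning(out <- adaptive_intensity_modulation(z), "unchanged")
  expect_equal(out$data, z$data)

  # two identical tubes, the deep one attenuated x0.3: modulation brings
  # the peak ratio closer to 1
  shape <- c(40L, 40L, 64L)
  t1 <- vesselreg:::rasterize_capsules(shape, matrix(c(5, 20, 12), 1),
                                       matrix(c(34, 20, 12), 1), 3)
  t2 <- vesselreg:::rasterize_capsules(shape, matrix(c(5, 20, 50), 1),
                                       matrix(c(34, 20, 50), 1), 3)
  img <- pa_volume(t1 + 0.3 * t2, spacing = 1)
  ves <- frangi_vesselness(img, vesselness_params(sigmas = 3))
  mod <- adaptive_intensity_modulation(ves, modulation_params(depth_axis = 3))
  peak <- function(a, zrange) max(a[, , zrange])
  ratio_before <- peak(ves$data, 45:56) / peak(ves$data, 7:18)
  ratio_after <- peak(mod$data, 45:56) / peak(mod$data, 7:18)
  expect_gt(ratio_after, ratio_before)
  expect_lt(abs(ratio_after - 1), abs(ratio_before - 1))

  # monotone nondecreasing within a depth slab
  set.seed(4)
  v <- pa_volume(array(stats::runif(16^3), c(16, 16, 16)))
  mod <- adaptive_intensity_modulation(v, modulation_params(depth_axis = 3))
  for (k in c(3L, 9L)) {
    x <- as.numeric(v$data[, , k])
    y <- as.numeric(mod$data[, , k])
    ord <- order(x)
    expect_true(all(diff(y[ord]) >= -1e-12))
  }
  expect_true(all(mod$data >= 0 & mod$data <= 1))
})
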