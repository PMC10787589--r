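# Volume I/O, coordinate frames and trilinear sampling.

test_that("write/read round trips are bit-exact in every format", {
  v <- random_volume(c(8L, 8L, 8L), spacing = 0.4)
  for (ext in c(".nii", ".nii.gz", ".nrrd", ".tif")) {
    p <- withr::local_tempfile(fileext = ext)
    write_volume(v, p)
    r <- read_volume(p, spacing = if (ext == ".tif") rep(0.4, 3) else NULL)
    expect_identical(r$data, v$data, label = ext)
    expect_equal(r$spacing, rep(0.4, 3), tolerance = 1e-6, label = ext)
  }
})

test_that("NIfTI header spacing of 0.4 mm isotropic is honoured", {
  v <- random_volume(c(6L, 7L, 8L), spacing = c(0.4, 0.4, 0.4))
  p <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, p)
  r <- read_volume(p)
  expect_equal(r$spacing, c(0.4, 0.4, 0.4), tolerance = 1e-6)
})

test_that("I/O error contracts: missing files, bad targets, TIFF spacing", {
  expect_error(read_volume(file.path(tempdir(), "no-such-file.nii")),
               "not found")
  v <- random_volume()
  expect_error(write_volume(v, file.path(tempdir(), "no-such-dir", "x.nii")),
               "directory")
  p <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, p)
  expect_error(read_volume(p), "spacing")
})

test_that("volumes with non-finite voxels are rejected with a count", {
  arr <- array(1, c(4, 4, 4))
  arr[c(1, 5, 9)] <- NaN
  expect_error(pa_volume(arr), "3 non-finite")
})

test_that("voxel<->normalized mapping is node-centred and bijective", {
  v <- random_volume(c(9L, 8L, 11L))
  # endpoints: index 0 -> -1, index N-1 -> +1
  ends <- voxel_to_normalized(v, rbind(c(0, 0, 0), v$shape - 1))
  expect_equal(ends, rbind(c(-1, -1, -1), c(1, 1, 1)))
  # centre of an odd axis maps to exactly 0
  expect_identical(voxel_to_normalized(v, rbind(c(4, 0, 5)))[c(1, 3)],
                   c(0, 0))
  # round trips (both directions, including out-of-grid points)
  set.seed(1)
  xn <- matrix(stats::runif(300, -1.5, 1.5), 100, 3)
  back <- voxel_to_normalized(v, normalized_to_voxel(v, xn))
  expect_lt(max(abs(back - xn)), 1e-9)
  # voxel -> mm -> normalized consistency
  idx <- matrix(stats::runif(300, 0, 7), 100, 3)
  via_mm <- mm_to_normalized(v, voxel_to_mm(v, idx))
  expect_lt(max(abs(via_mm - voxel_to_normalized(v, idx))), 1e-9)

  # isotropic variant: longest axis spans [-1, 1], others share its scale
  w <- pa_volume(array(1, c(9, 5, 17)))
  corner <- voxel_to_normalized(w, rbind(w$shape - 1), isotropic = TRUE)
  expect_equal(as.numeric(corner), c(0.5, 0.25, 1))
  back <- normalized_to_voxel(w, corner, isotropic = TRUE)
  expect_lt(max(abs(back - rbind(w$shape - 1))), 1e-9)
})

test_that("depth arithmetic follows the 0.4 mm voxel convention", {
  v <- pa_volume(array(0, c(4, 4, 120)) + 1, spacing = 0.4)
  d <- depth_map(v, 3L)
  expect_equal(d[1, 1, 101], 40)  # index 100 at 0.4 mm
  expect_equal(d[1, 1, 1], 0)
  expect_true(all(diff(d[1, 1, ]) > 0))
})

test_that("sample_intensity: nodes, linearity, fill and brute-force oracle", {
  v <- random_volume(c(8L, 8L, 8L))
  idx <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  dimnames(idx) <- NULL
  vals <- sample_intensity(v, voxel_to_normalized(v, idx))
  expect_lt(max(abs(vals - as.numeric(v$data))), 1e-12)

  # midpoint of neighbours 0 and 1 -> 0.5
  v2 <- pa_volume(array(rep(c(0, 1), length.out = 2 * 2 * 2), c(2, 2, 2)))
  mid <- sample_intensity(v2, voxel_to_normalized(v2, rbind(c(0.5, 0, 0))))
  expect_equal(mid, 0.5)

  # out-of-domain -> fill
  expect_identical(sample_intensity(v, rbind(c(2, 0, 0))), 0)
  expect_identical(sample_intensity(v, rbind(c(2, 0, 0)), fill_value = 7), 7)
  expect_error(sample_intensity(v, rbind(c(NA, 0, 0))), "non-finite")

  # brute-force per-point trilinear formula on 1000 random coordinates
  brute <- function(data, vox) {
    i0 <- pmin(pmax(floor(vox), 0), dim(data) - 2)
    f <- vox - i0
    s <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) f[1] else 1 - f[1]) * (if (dj) f[2] else 1 - f[2]) *
        (if (dk) f[3] else 1 - f[3])
      s <- s + w * data[i0[1] + di + 1, i0[2] + dj + 1, i0[3] + dk + 1]
    }
    s
  }
  set.seed(9)
  xs <- matrix(stats::runif(3000, -1, 1), 1000, 3)
  got <- sample_intensity(v, xs)
  want <- apply(normalized_to_voxel(v, xs), 1, brute, data = v$data)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("landmark CSV round trip and frame conversion", {
  v <- random_volume(c(16L, 16L, 16L))
  lm <- landmark_set(c("a", "b"), rbind(c(0, 0, 0), c(15, 7.5, 3)),
                     frame = "voxel")
  p <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, p)
  r <- read_landmarks(p)
  expect_equal(r$points, lm$points)
  expect_identical(r$names, lm$names)
  nrm <- convert_landmarks(lm, v, "normalized")
  expect_equal(nrm$points[1, ], c(-1, -1, -1))
  back <- convert_landmarks(nrm, v, "voxel")
  expect_lt(max(abs(back$points - lm$points)), 1e-9)
  expect_error(landmark_set(c("a", "a"), rbind(c(0, 0, 0), c(1, 1, 1))),
               "unique")
})
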