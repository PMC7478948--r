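test_that("NIfTI write -> read round trip preserves data and geometry", {
  set.seed(10)
  aff <- diag(c(1, 1, 5, 1)); aff[1:3, 4] <- c(-12, -8, -20)
  v <- image_volume(array(rnorm(10 * 12 * 6), c(10, 12, 6)),
                    spacing = c(1, 1, 5), affine = aff, modality = "flair")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path, provenance = list(step = "unit-test"))
  v2 <- read_volume(path, modality = "flair")
  expect_identical(v2$data, v$data)          # bit-exact data
  expect_equal(v2$affine, v$affine, tolerance = 1e-6)
  expect_equal(v2$spacing, c(1, 1, 5), tolerance = 1e-6)  # anisotropy kept
  # sidecar carries the modality
  expect_identical(read_volume(path)$modality, "flair")
})

test_that("reading rejects missing files and non-3D images", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 3))), p4)
  expect_error(read_volume(p4), "3D")
})

test_that("volume construction enforces the container invariants", {
  expect_error(image_volume(matrix(0, 3, 3)), "3D")
  expect_error(image_volume(array(0, c(3, 3, 3)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(image_volume(array(0.5, c(3, 3, 3)), modality = "mask"),
               "mask")
  expect_error(image_volume(array(1.5, c(3, 3, 3)), modality = "probability"),
               "probability")
  bad_aff <- diag(4); bad_aff[1, 1] <- 0
  expect_error(image_volume(array(0, c(3, 3, 3)), affine = bad_aff),
               "singular")
})

test_that("resampling: identity, exact one-voxel shift, mask binariness", {
  set.seed(11)
  v <- image_volume(array(rnorm(12 * 10 * 8), c(12, 10, 8)),
                    spacing = c(2, 2, 4))
  ident <- resample(v, rigid_transform(), v)
  expect_equal(ident$data, v$data, tolerance = 1e-12)

  # translation by exactly one voxel along axis 1 with nearest interpolation
  # equals an index shift with zero-filled border
  shift <- rigid_transform(translation = c(v$spacing[1], 0, 0))
  out <- resample(v, shift, v, interpolation = "nearest")
  expected <- array(0, dim(v$data))
  expected[1:11, , ] <- v$data[2:12, , ]
  expect_equal(out$data, expected)

  m <- image_volume(array(as.numeric(runif(12 * 10 * 8) < 0.4), c(12, 10, 8)),
                    spacing = c(2, 2, 4), modality = "mask")
  warped <- resample(m, rigid_transform(rotation = c(4, -3, 7),
                                        translation = c(3, -2, 5),
                                        center = grid_center_world(m)),
                     m, interpolation = "nearest")
  expect_true(all(warped$data %in% c(0, 1)))
  expect_error(resample(m, NULL, m, interpolation = "linear"), "nearest")
})

test_that("resampling through T then T^-1 restores the interior of a smooth field", {
  g <- seq(-1, 1, length.out = 32)
  sm <- outer(outer(exp(-g^2 * 2), exp(-g^2 * 3)), exp(-seq(-1, 1,
                                                            length.out = 16)^2))
  v <- image_volume(array(sm, c(32, 32, 16)), spacing = c(2, 2, 4))
  tr <- rigid_transform(rotation = c(3, -2, 4), translation = c(3, -2, 2),
                        center = grid_center_world(v))
  fwd <- resample(v, tr, v, "linear")
  back <- resample(fwd, invert_transform(tr), v, "linear")
  interior <- array(FALSE, dim(v$data))
  interior[5:28, 5:28, 3:14] <- TRUE
  mae <- mean(abs(back$data[interior] - v$data[interior]))
  expect_lt(mae, 0.02 * diff(range(v$data)))
})

test_that("volume_ml follows voxel arithmetic and is additive over disjoint masks", {
  empty <- image_volume(array(0, c(5, 5, 5)), modality = "mask")
  expect_equal(volume_ml(empty), 0)

  unit <- image_volume(array(1, c(10, 10, 10)), spacing = c(1, 1, 1),
                       modality = "mask")
  expect_equal(volume_ml(unit), 1.0)  # 1000 voxels x 1 mm^3

  a <- array(0, c(10, 10, 10)); a[1:2, 1:10, 1:10] <- 1  # 200 voxels
  m <- image_volume(a, spacing = c(0.5, 0.5, 5), modality = "mask")
  expect_equal(volume_ml(m), 0.25)    # 200 x 1.25 mm^3 / 1000

  expect_error(volume_ml(image_volume(array(0.3, c(3, 3, 3)))), "binary")

  set.seed(12)
  x <- array(as.numeric(runif(1000) < 0.3), c(10, 10, 10))
  y <- array(as.numeric(runif(1000) < 0.3), c(10, 10, 10)) * (1 - x)
  mk <- function(d) image_volume(d, spacing = c(1.5, 1.5, 3),
                                 modality = "mask")
  expect_equal(volume_ml(mk(pmin(x + y, 1))),
               volume_ml(mk(x)) + volume_ml(mk(y)))
})

test_that("transform algebra: inverse composition is the identity, parameters round-trip", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- rigid_transform(runif(3, -10, 10), runif(3, -8, 8),
                         center = runif(3, -20, 20))
    M <- compose_transforms(t, invert_transform(t))
    pt <- c(runif(3, -30, 30), 1)
    expect_lt(max(abs((M %*% pt - pt)[1:3])), 1e-6)
  }
  a <- affine_transform(c(3, -2, 5), c(1, -4, 2), c(1.1, 0.9, 1.05),
                        center = c(10, 20, 5))
  a2 <- ctwml:::from_matrix(transform_matrix(a), center = c(10, 20, 5),
                            affine = TRUE)
  expect_equal(a2$rotation, a$rotation, tolerance = 1e-9)
  expect_equal(a2$translation, a$translation, tolerance = 1e-9)
  expect_equal(a2$scale, a$scale, tolerance = 1e-9)
  expect_error(affine_transform(scale = c(1, -1, 1)), "positive")
})
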