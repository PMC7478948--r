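test_that("overlap statistics satisfy the Dice identities", {
  a <- array(0, c(10, 10, 10)); a[1:3, , 1:10] <- 1   # 300 voxels
  b <- array(0, c(10, 10, 10)); b[2:6, , 1:10] <- 1   # 500 voxels, 200 shared
  x <- image_volume(a, spacing = c(1, 1, 1), modality = "mask")
  y <- image_volume(b, spacing = c(1, 1, 1), modality = "mask")
  os <- overlap_stats(x, y)
  expect_equal(os$dice, 2 * 200 / 800)
  expect_equal(os$vol_X_ml, os$vol_intersection_ml + os$vol_X_only_ml)
  expect_equal(os$vol_Y_ml, os$vol_intersection_ml + os$vol_Y_only_ml)

  same <- overlap_stats(x, x)
  expect_equal(same$dice, 1)
  expect_equal(same$vol_X_only_ml, 0)
  expect_equal(same$vol_Y_only_ml, 0)

  c2 <- array(0, c(10, 10, 10)); c2[8:10, , ] <- 1
  expect_equal(overlap_stats(x, image_volume(c2, modality = "mask",
                                             spacing = c(1, 1, 1)))$dice, 0)

  empty <- image_volume(array(0, c(10, 10, 10)), spacing = c(1, 1, 1),
                        modality = "mask")
  both <- overlap_stats(empty, empty)
  expect_equal(both$dice, 0)
  expect_true(both$both_empty)

  small <- image_volume(array(0, c(5, 5, 5)), modality = "mask")
  expect_error(overlap_stats(x, small), "grid")
})

test_that("Dice from overlap_stats matches a brute-force voxel loop", {
  for (seed in 1:20) {
    mp <- random_mask_pair(seed)
    expect_identical(overlap_stats(mp$x, mp$y)$dice,
                     brute_force_dice(mp$x, mp$y))
  }
})

test_that("volume correlation and OLS line match closed-form hand computations", {
  perfect <- volume_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)

  anti <- volume_correlation(c(1, 2, 3), c(3, 2, 1))
  expect_equal(anti$pearson_r, -1)

  # (0,0), (1,2), (2,4): y = FLAIR, x = CT; regression of CT on FLAIR
  h <- volume_correlation(c(0, 1, 2), c(0, 2, 4))
  expect_equal(h$pearson_r, 1, tolerance = 1e-12)
  expect_equal(h$slope, 0.5, tolerance = 1e-12)  # hand OLS: 10/20
  expect_equal(h$intercept, 0, tolerance = 1e-12)

  expect_error(volume_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(volume_correlation(c(1, 2), c(1, 2)))
})

test_that("Bland-Altman summaries follow the population-SD convention", {
  same <- bland_altman(c(1, 5, 9), c(1, 5, 9))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$loa_lower, 0)
  expect_equal(same$loa_upper, 0)

  shift <- bland_altman(c(3, 7, 11), c(1, 5, 9))
  expect_equal(shift$mean_difference, 2)
  expect_equal(shift$sd_difference, 0)

  tri <- bland_altman(c(0, 1, 2), c(1, 1, 1))  # differences -1, 0, 1
  expect_equal(tri$mean_difference, 0)
  expect_equal(tri$sd_difference, sqrt(2 / 3))      # population SD
  expect_equal(tri$loa_upper, 1.96 * sqrt(2 / 3))
})

test_that("threshold fitting matches the brute-force search and its tie rule", {
  v <- c(1, 2, 10, 11, 30, 31)
  lab <- c("0_1", "0_1", "2", "2", "3", "3")
  ft <- fit_fazekas_thresholds(v, lab)
  bf <- brute_force_thresholds(v, lab)
  expect_equal(ft$t_low, bf$t_low)
  expect_equal(ft$t_high, bf$t_high)
  expect_equal(ft$train_accuracy, 1)
  expect_equal(ft$t_low, 6)    # first midpoint achieving perfect split
  expect_equal(ft$t_high, 20.5)

  # one overlapping point: accuracy (n-1)/n, agreed with brute force
  v2 <- c(1, 2, 9, 1.5, 10, 11, 30, 31)
  lab2 <- c("0_1", "0_1", "0_1", "2", "2", "2", "3", "3")
  ft2 <- fit_fazekas_thresholds(v2, lab2)
  bf2 <- brute_force_thresholds(v2, lab2)
  expect_equal(ft2$train_accuracy, bf2$acc)
  expect_equal(ft2$train_accuracy, 7 / 8)
  expect_equal(c(ft2$t_low, ft2$t_high), c(bf2$t_low, bf2$t_high))

  # random labels never dip below the majority-class floor
  set.seed(8)
  v3 <- runif(30, 0, 50)
  lab3 <- sample(rep(c("0_1", "2", "3"), 10))
  ft3 <- fit_fazekas_thresholds(v3, lab3)
  expect_gte(ft3$train_accuracy, 1 / 3)

  expect_error(fit_fazekas_thresholds(c(1, 2), c("0_1", "2")), "classes")
})

test_that("cross-validated Fazekas grading separates clean strata and is scale-equivariant", {
  set.seed(12)
  v <- c(runif(20, 0, 2), runif(20, 6, 14), runif(20, 26, 55))
  lab <- rep(c("0_1", "2", "3"), each = 20)
  cv <- cross_validated_fazekas(v, lab, n_folds = 10, seed = 2)
  expect_equal(cv$accuracy, 1)
  expect_true(all(cv$confusion[upper.tri(cv$confusion)] == 0))
  expect_true(all(cv$confusion[lower.tri(cv$confusion)] == 0))
  expect_equal(as.vector(diag(cv$confusion)), c(20, 20, 20))

  cv2 <- cross_validated_fazekas(v * 3.7, lab, n_folds = 10, seed = 2)
  expect_equal(cv2$accuracy, cv$accuracy)
  expect_identical(cv2$confusion, cv$confusion)
})

test_that("confusion accuracy reproduces the worked-example matrices", {
  cms <- example_fazekas_confusion()
  expect_equal(rowSums(cms$ct), c("0_1" = 50, "2" = 48, "3" = 49))
  expect_equal(rowSums(cms$flair), c("0_1" = 50, "2" = 48, "3" = 49))
  expect_equal(round(confusion_accuracy(cms$ct), 2), 0.78)
  expect_equal(round(confusion_accuracy(cms$flair), 2), 0.78)
  expect_equal(confusion_accuracy(diag(c(10, 10, 10))), 1)
  expect_error(confusion_accuracy(matrix(0, 3, 3)), "empty")
})
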