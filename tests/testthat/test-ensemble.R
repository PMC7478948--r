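test_that("fold plans partition subjects with balanced sizes, deterministically", {
  ids <- sprintf("s%03d", 1:147)
  plan <- make_fold_plan(ids, n_folds = 10, n_repetitions = 10, seed = 9)
  for (r in 1:10) {
    sizes <- as.vector(table(plan$assignment[r, ]))
    expect_equal(length(sizes), 10)
    expect_equal(sum(sizes), 147)
    expect_lte(max(sizes) - min(sizes), 1)      # 147 = 7 x 15 + 3 x 14
    expect_equal(sort(unique(sizes)), c(14, 15))
  }
  plan2 <- make_fold_plan(ids, n_folds = 10, n_repetitions = 10, seed = 9)
  expect_identical(plan$assignment, plan2$assignment)

  forced <- make_fold_plan(sprintf("s%02d", 1:10), n_folds = 10,
                           n_repetitions = 2, seed = 1)
  expect_equal(as.vector(table(forced$assignment[1, ])), rep(1L, 10))
  expect_error(make_fold_plan(sprintf("s%02d", 1:5), n_folds = 10), "folds")
})

test_that("stratified fold plans spread every group over the folds", {
  ids <- sprintf("s%03d", 1:45)
  strata <- rep(c("0_1", "2", "3"), each = 15)
  plan <- make_fold_plan(ids, n_folds = 3, n_repetitions = 3, seed = 2,
                         strata = strata)
  for (r in 1:3) {
    tab <- table(strata, plan$assignment[r, ])
    expect_true(all(tab == 5))  # 15 per group / 3 folds
  }
})

test_that("threshold_map applies the inclusive comparison", {
  base <- array(0.25, c(6, 6, 2))
  pv <- image_volume(base, modality = "probability")
  expect_true(all(threshold_map(pv, 0.25)$data == 1))
  pv2 <- image_volume(array(0.249, c(6, 6, 2)), modality = "probability")
  expect_true(all(threshold_map(pv2, 0.25)$data == 0))
  expect_warning(threshold_map(pv, 1.5), "outside")
  # volume after thresholding equals the brute-force voxel count
  set.seed(5)
  pr <- image_volume(array(runif(6 * 6 * 2), c(6, 6, 2)),
                     spacing = c(2, 2, 4), modality = "probability")
  m <- threshold_map(pr, 0.25)
  expect_equal(volume_ml(m), sum(pr$data >= 0.25) * 16 / 1000)
})

test_that("a tiny CV ensemble satisfies the averaging and integrity contracts", {
  # small grids and a small network keep this fast; the contracts under
  # test are scale-free
  subjects <- lapply(c(301, 302, 303, 304, 305, 306), function(s)
    aligned_subject(s, c("2", "3")[1 + s %% 2], grid = c(64, 64, 10)))
  subjects <- lapply(subjects, function(s)
    list(image = s$ct, label = s$label, mask = s$mask,
         fazekas_label = s$fazekas_label))
  names(subjects) <- sprintf("t%02d", 1:6)
  spec <- model_spec(depth = 2, base_channels = 4, epochs = 4)
  plan1 <- make_fold_plan(names(subjects), n_folds = 3, n_repetitions = 1,
                          seed = 4)
  res1 <- run_cv_ensemble(subjects, plan1, spec, threshold = 0.25,
                          n_patches = 24)
  # degenerate ensemble: the mean map is the single model's map
  for (id in names(res1)) {
    expect_identical(res1[[id]]$mean_probability$data,
                     res1[[id]]$repetition_maps[[1]]$data)
  }

  plan3 <- make_fold_plan(names(subjects), n_folds = 3, n_repetitions = 3,
                          seed = 4)
  res3 <- run_cv_ensemble(subjects, plan3, spec, threshold = 0.25,
                          n_patches = 24)
  for (id in names(res3)) {
    r <- res3[[id]]
    expect_equal(r$n_contributing_models, 3)
    # decomposition: stored mean equals the recomputed arithmetic mean
    recomputed <- (r$repetition_maps[[1]]$data + r$repetition_maps[[2]]$data +
                     r$repetition_maps[[3]]$data) / 3
    expect_equal(r$mean_probability$data, recomputed, tolerance = 1e-15)
    # mask/volume consistency
    expect_identical(r$final_mask$data,
                     array(as.numeric(r$mean_probability$data >= 0.25),
                           dim(r$mean_probability$data)))
    expect_equal(r$wml_volume_ml, volume_ml(r$final_mask))
    # volume is non-increasing in the threshold
    vols <- sapply(seq(0, 1, by = 0.1), function(th)
      volume_ml(threshold_map(r$mean_probability, th)))
    expect_true(all(diff(vols) <= 0))
  }
  # plan mismatch is rejected
  bad <- make_fold_plan(sprintf("x%02d", 1:6), n_folds = 3,
                        n_repetitions = 1, seed = 1)
  expect_error(run_cv_ensemble(subjects, bad, spec), "cover")
})

test_that("averaging repetitions stabilizes per-subject volumes across ensemble seeds", {
  subjects <- lapply(c(311, 312, 313, 314, 315, 316), function(s)
    aligned_subject(s, c("2", "3")[1 + s %% 2], grid = c(64, 64, 10)))
  subjects <- lapply(subjects, function(s)
    list(image = s$ct, label = s$label, mask = s$mask,
         fazekas_label = s$fazekas_label))
  names(subjects) <- sprintf("u%02d", 1:6)
  # the models must actually segment for the robustness claim to be in
  # scope; 8 epochs over 48 patches is the smallest scale where they do
  spec <- model_spec(depth = 2, base_channels = 4, epochs = 8)
  ens_vol <- NULL; single_vol <- NULL
  for (seed in 1:5) {
    plan <- make_fold_plan(names(subjects), n_folds = 3, n_repetitions = 3,
                           seed = seed * 100)
    res <- run_cv_ensemble(subjects, plan, spec, threshold = 0.25,
                           n_patches = 48)
    ens_vol <- rbind(ens_vol, sapply(res, function(r) r$wml_volume_ml))
    single_vol <- rbind(single_vol, sapply(res, function(r)
      volume_ml(threshold_map(r$repetition_maps[[1]], 0.25))))
  }
  # per subject, the ensemble-mean volume varies less across seeds than a
  # single repetition's volume does (averaging improves robustness)
  v_ens <- apply(ens_vol, 2, var)
  v_one <- apply(single_vol, 2, var)
  expect_lt(mean(v_ens), mean(v_one))
})
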