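# Shared fixtures, built in code and memoized so expensive objects (trained
# networks, the end-to-end cohort run) are computed once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# an aligned (no misalignment), z-scored phantom subject; cheap building
# block for CNN and ensemble tests that do not exercise registration
aligned_subject <- function(seed, group = "2", grid = c(64, 64, 24),
                            spacing = c(2, 2, 4)) {
  p <- generate_pair(phantom_spec(grid_shape = grid, spacing = spacing,
                                  fazekas_target = group, seed = seed,
                                  misalignment = rigid_transform()))
  zf <- zscore_in_mask(p$flair, p$brain_mask)
  zc <- zscore_in_mask(p$ct, p$brain_mask)
  list(image = zf$volume, ct = zc$volume, label = p$wml_truth,
       mask = p$brain_mask, id = sprintf("s%04d", seed),
       fazekas_label = p$fazekas_label, pair = p)
}

flair_training_cohort <- function() memo("flair_cohort", {
  mapply(aligned_subject, seed = 201:206,
         group = rep(c("0_1", "2", "3"), 2), SIMPLIFY = FALSE)
})

# FLAIR-trained network shared across learning/consistency tests
flair_model <- function() memo("flair_model", {
  ps <- sample_patches(flair_training_cohort(), n_patches = 256,
                       lesion_fraction = 0.5, seed = 31)
  train_cnn(model_spec(seed = 17), ps)
})

# CT-trained network (cross-modality labels) on moderate/severe subjects
ct_model <- function() memo("ct_model", {
  cohort <- lapply(flair_training_cohort(), function(s) {
    list(image = s$ct, label = s$label, mask = s$mask, id = s$id)
  })
  ps <- sample_patches(cohort, n_patches = 256, lesion_fraction = 0.5,
                       seed = 37)
  train_cnn(model_spec(seed = 19), ps)
})

random_mask_pair <- function(seed, d = c(16, 16, 16), p = 0.3) {
  set.seed(seed)
  a <- array(as.numeric(runif(prod(d)) < p), d)
  b <- array(as.numeric(runif(prod(d)) < p), d)
  list(x = image_volume(a, modality = "mask"),
       y = image_volume(b, modality = "mask"))
}

# independent brute-force Dice: explicit voxel loop, no set arithmetic
brute_force_dice <- function(x, y) {
  nx <- 0L; ny <- 0L; ni <- 0L
  xv <- as.vector(x$data); yv <- as.vector(y$data)
  for (i in seq_along(xv)) {
    if (xv[i] == 1) nx <- nx + 1L
    if (yv[i] == 1) ny <- ny + 1L
    if (xv[i] == 1 && yv[i] == 1) ni <- ni + 1L
  }
  if (nx + ny == 0) return(0)
  2 * ni / (nx + ny)
}

# independent brute-force threshold search for the Fazekas classifier:
# same candidate set and tie rule as documented, naive loops
brute_force_thresholds <- function(v, lab) {
  sv <- sort(unique(v))
  cand <- c(0, if (length(sv) > 1) (sv[-length(sv)] + sv[-1]) / 2, Inf)
  best_acc <- -1; best <- c(NA, NA)
  for (tl in cand) for (th in cand) {
    if (th <= tl) next
    pred <- ifelse(v < tl, "0_1", ifelse(v < th, "2", "3"))
    acc <- sum(pred == lab) / length(v)
    if (acc > best_acc + 1e-12) { best_acc <- acc; best <- c(tl, th) }
  }
  list(t_low = best[1], t_high = best[2], acc = best_acc)
}

# the scaled-down end-to-end pipeline run shared by the acceptance tests:
# 45 phantom pairs (15 per Fazekas group), full preprocessing, 3 folds x
# 3 repetitions, threshold 0.25
end_to_end_run <- function() memo("end_to_end", {
  cohort <- generate_cohort(c(15, 15, 15), phantom_spec(), seed = 4242)
  pre <- lapply(cohort$pairs, preprocess_pair)
  subjects <- lapply(pre, function(s)
    list(image = s$ct, label = s$label, mask = s$mask,
         fazekas_label = s$fazekas_label))
  names(subjects) <- names(cohort$pairs)
  plan <- make_fold_plan(names(subjects), n_folds = 3, n_repetitions = 3,
                         seed = 7, strata = cohort$manifest$fazekas_label)
  results <- run_cv_ensemble(subjects, plan, model_spec(),
                             threshold = 0.25, n_patches = 224,
                             lesion_fraction = 1 / 3)
  report <- evaluate_cohort(results, subjects, n_folds = 10, seed = 3)
  list(cohort = cohort, pre = pre, subjects = subjects, plan = plan,
       results = results, report = report)
})
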