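#' Cross-validation fold plan
#'
#' Assigns subjects to folds for each repetition of a repeated k-fold
#' cross-validation. Within a repetition every subject is in exactly one
#' fold, fold sizes differ by at most one, and (optionally) folds are
#' stratified so each Fazekas group is spread evenly — preventing training
#' folds with no severe cases at small cohort sizes. The plan is
#' deterministic given the seed.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param n_folds Folds per repetition (default 10).
#' @param n_repetitions Repetitions with re-randomized assignment
#'   (default 10).
#' @param seed Integer seed.
#' @param strata Optional factor (same length as `subject_ids`) to
#'   stratify by, e.g. Fazekas group.
#' @return An object of class `fold_plan` with an
#'   `n_repetitions x n_subjects` assignment matrix of fold indices.
#' @export
make_fold_plan <- function(subject_ids, n_folds = 10, n_repetitions = 10,
                           seed = 1L, strata = NULL) {
  n <- length(subject_ids)
  if (n < n_folds)
    stop("need at least as many subjects (", n, ") as folds (", n_folds, ")")
  if (!is.null(strata)) stopifnot(length(strata) == n)
  set.seed(seed)
  assignment <- matrix(NA_integer_, n_repetitions, n,
                       dimnames = list(NULL, subject_ids))
  for (r in seq_len(n_repetitions)) {
    if (is.null(strata)) {
      ord <- sample.int(n)
    } else {
      # shuffle within strata, concatenate; cyclic fold labels then spread
      # every stratum evenly over folds
      ord <- unlist(lapply(split(seq_len(n), strata), sample), use.names = FALSE)
    }
    folds <- rep(sample.int(n_folds), length.out = n)
    assignment[r, ord] <- folds
  }
  structure(list(n_subjects = n, n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 assignment = assignment, seed = as.integer(seed),
                 subject_ids = subject_ids),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d subjects, %d folds x %d repetitions (seed %d)\n",
              x$n_subjects, x$n_folds, x$n_repetitions, x$seed))
  invisible(x)
}

#' Threshold a probability map into a binary mask
#'
#' The comparison is inclusive: voxels with probability greater than or
#' equal to the threshold become lesion.
#'
#' @param prob Probability `image_volume`.
#' @param threshold Probability cut (default 0.25).
#' @return A binary `image_volume`.
#' @export
threshold_map <- function(prob, threshold = 0.25) {
  stopifnot(inherits(prob, "image_volume"))
  if (threshold < 0 || threshold > 1)
    warning("threshold ", threshold, " lies outside [0, 1]")
  with_data(prob, array(as.numeric(prob$data >= threshold), dim(prob$data)),
            modality = "mask")
}

#' Repeated cross-validation segmentation ensemble
#'
#' For each repetition of the fold plan, one network per fold is trained on
#' the out-of-fold subjects' CT patches (labels: FLAIR-derived lesion
#' masks) and predicts the probability maps of its test-fold subjects, so
#' each subject receives exactly `n_repetitions` independent maps. The
#' final per-subject segmentation is the arithmetic mean map thresholded
#' (inclusively) at `threshold`. All training/sampling seeds derive from
#' `plan$seed` and are recorded in the result.
#'
#' @param cohort List of `preprocessed_subject`s (or lists with `id`,
#'   `image` = CT volume, `label`, `mask`); names are subject ids.
#' @param plan A [make_fold_plan()] covering exactly the cohort subjects.
#' @param spec A [model_spec()]; its seed field is overridden per
#'   fold/repetition.
#' @param threshold Final probability threshold (default 0.25).
#' @param n_patches Training patches per fold model (default 160).
#' @param lesion_fraction Lesion patch fraction for sampling (default 0.5).
#' @param keep_repetition_maps Keep the per-repetition probability maps in
#'   each result (default TRUE; needed for the decomposition checks).
#' @param verbose Print per-repetition progress.
#' @return A list of class `ensemble_results`: per subject an
#'   `ensemble_result` with `mean_probability`, `final_mask`,
#'   `wml_volume_ml`, `n_contributing_models` and (optionally)
#'   `repetition_maps`; plus attribute `seed_ledger`.
#' @export
run_cv_ensemble <- function(cohort, plan, spec = model_spec(),
                            threshold = 0.25, n_patches = 160,
                            lesion_fraction = 0.5,
                            keep_repetition_maps = TRUE, verbose = FALSE) {
  ids <- names(cohort) %||% vapply(cohort, function(s) s$id, character(1))
  names(cohort) <- ids
  if (!setequal(ids, plan$subject_ids))
    stop("fold plan does not cover exactly the cohort's subjects")
  subjects <- lapply(cohort, function(s) {
    list(image = s$image %||% s$ct, label = s$label, mask = s$mask,
         id = s$id %||% "")
  })
  for (i in seq_along(subjects)) subjects[[i]]$id <- ids[i]

  maps <- lapply(ids, function(i) vector("list", plan$n_repetitions))
  names(maps) <- ids
  ledger <- list()
  for (r in seq_len(plan$n_repetitions)) {
    rep_seed <- (plan$seed * 131 + r * 104729) %% 2147483587
    for (f in seq_len(plan$n_folds)) {
      test_ids <- plan$subject_ids[plan$assignment[r, ] == f]
      train_ids <- setdiff(plan$subject_ids, test_ids)
      fold_seed <- (rep_seed + f * 7919) %% 2147483587
      ps <- sample_patches(subjects[train_ids], n_patches = n_patches,
                           lesion_fraction = lesion_fraction,
                           patch = spec$patch_size, seed = fold_seed)
      mspec <- spec; mspec$seed <- as.integer((fold_seed + 17) %% 2147483587)
      model <- train_cnn(mspec, ps)
      for (id in test_ids) {
        maps[[id]][[r]] <- predict_probability(model, subjects[[id]]$image,
                                               subjects[[id]]$mask)
      }
      ledger[[length(ledger) + 1]] <- list(repetition = r, fold = f,
                                           patch_seed = fold_seed,
                                           model_seed = mspec$seed)
    }
    if (verbose) message("repetition ", r, "/", plan$n_repetitions, " done")
  }
  results <- lapply(ids, function(id) {
    got <- !vapply(maps[[id]], is.null, logical(1))
    if (sum(got) != plan$n_repetitions)
      stop("pipeline integrity error: subject ", id, " has ", sum(got),
           " of ", plan$n_repetitions, " predictions")
    mp <- Reduce(`+`, lapply(maps[[id]], function(v) v$data)) /
      plan$n_repetitions
    ref <- maps[[id]][[1]]
    mean_prob <- image_volume(mp, ref$spacing, ref$affine, "probability")
    fm <- threshold_map(mean_prob, threshold)
    structure(list(subject_id = id, mean_probability = mean_prob,
                   final_mask = fm, wml_volume_ml = volume_ml(fm),
                   n_contributing_models = plan$n_repetitions,
                   repetition_maps = if (keep_repetition_maps) maps[[id]]
                                     else NULL,
                   threshold = threshold),
              class = "ensemble_result")
  })
  names(results) <- ids
  structure(results, class = "ensemble_results", seed_ledger = ledger)
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %s: %.2f mL from %d models (threshold %.2f)\n",
              x$subject_id, x$wml_volume_ml, x$n_contributing_models,
              x$threshold))
  invisible(x)
}
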