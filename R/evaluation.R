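#' Overlap statistics between two binary segmentations
#'
#' Computes the Dice similarity index
#' `Dice = 2|X ∩ Y| / (|X| + |Y|)` — with `X` the CT segmentation and `Y`
#' the FLAIR (reference) segmentation — together with the volumes (mL) of
#' the intersection and of the voxels segmented in only one of the two
#' images. Dice of two empty masks is defined as 0 and flagged.
#'
#' @param seg_ct,seg_flair Binary `image_volume`s on the same grid.
#' @return An object of class `overlap_stats` with fields `dice`,
#'   `vol_X_ml`, `vol_Y_ml`, `vol_intersection_ml`, `vol_X_only_ml`,
#'   `vol_Y_only_ml`, `both_empty`.
#' @export
overlap_stats <- function(seg_ct, seg_flair) {
  stopifnot(inherits(seg_ct, "image_volume"), inherits(seg_flair, "image_volume"))
  if (!all(dim(seg_ct$data) == dim(seg_flair$data)) ||
      !isTRUE(all.equal(seg_ct$spacing, seg_flair$spacing, tolerance = 1e-6)))
    stop("segmentations must share the same grid")
  if (!is_binary(seg_ct) || !is_binary(seg_flair))
    stop("overlap_stats() requires binary masks")
  voxml <- prod(seg_ct$spacing) / 1000
  x <- seg_ct$data > 0; y <- seg_flair$data > 0
  nx <- sum(x); ny <- sum(y); ni <- sum(x & y)
  both_empty <- (nx + ny) == 0
  dice <- if (both_empty) 0 else 2 * ni / (nx + ny)
  structure(list(dice = dice,
                 vol_X_ml = nx * voxml, vol_Y_ml = ny * voxml,
                 vol_intersection_ml = ni * voxml,
                 vol_X_only_ml = (nx - ni) * voxml,
                 vol_Y_only_ml = (ny - ni) * voxml,
                 both_empty = both_empty),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("<overlap_stats> Dice %.3f  |X| %.2f mL  |Y| %.2f mL  |X∩Y| %.2f mL\n",
              x$dice, x$vol_X_ml, x$vol_Y_ml, x$vol_intersection_ml))
  invisible(x)
}

#' Pearson correlation and least-squares line of CT vs FLAIR volumes
#'
#' Ordinary least squares of the CT volume on the FLAIR volume, plus the
#' Pearson correlation coefficient.
#'
#' @param vol_ct_ml,vol_flair_ml Numeric vectors of per-subject volumes
#'   (mL), equal length >= 3, each with nonzero variance.
#' @return List with `pearson_r`, `slope`, `intercept`, `n`.
#' @export
volume_correlation <- function(vol_ct_ml, vol_flair_ml) {
  stopifnot(length(vol_ct_ml) == length(vol_flair_ml),
            length(vol_ct_ml) >= 3)
  if (sd(vol_ct_ml) == 0 || sd(vol_flair_ml) == 0)
    stop("undefined correlation: zero variance")
  r <- cor(vol_ct_ml, vol_flair_ml)
  # closed-form OLS of CT on FLAIR
  xb <- mean(vol_flair_ml); yb <- mean(vol_ct_ml)
  slope <- sum((vol_flair_ml - xb) * (vol_ct_ml - yb)) /
    sum((vol_flair_ml - xb)^2)
  list(pearson_r = r, slope = slope, intercept = yb - slope * xb,
       n = length(vol_ct_ml))
}

#' Bland-Altman agreement summary
#'
#' Differences are CT minus FLAIR; limits of agreement are
#' `mean ± 1.96 · SD` with the population SD.
#'
#' @inheritParams volume_correlation
#' @return List with `mean_difference`, `sd_difference`, `loa_lower`,
#'   `loa_upper`, and a data.frame `points` of per-subject (mean,
#'   difference) pairs for plotting.
#' @export
bland_altman <- function(vol_ct_ml, vol_flair_ml) {
  stopifnot(length(vol_ct_ml) == length(vol_flair_ml),
            length(vol_ct_ml) >= 3)
  d <- vol_ct_ml - vol_flair_ml
  m <- (vol_ct_ml + vol_flair_ml) / 2
  mu <- mean(d)
  sdd <- sqrt(mean((d - mu)^2))
  list(mean_difference = mu, sd_difference = sdd,
       loa_lower = mu - 1.96 * sdd, loa_upper = mu + 1.96 * sdd,
       points = data.frame(mean = m, difference = d))
}

#' Fit Fazekas volume thresholds
#'
#' Searches a pair of volume cut points `(t_low, t_high)` separating the
#' three Fazekas groups (0-1 below `t_low`, 2 in `[t_low, t_high)`, 3 at or
#' above `t_high`), maximizing training accuracy by exhaustive search over
#' the midpoints of consecutive distinct sorted volumes plus 0 and +Inf
#' sentinels. Ties are broken toward the lexicographically smallest
#' `(t_low, t_high)` pair.
#'
#' @param volumes_ml Numeric vector of WML volumes (mL).
#' @param labels Character/factor vector with levels `"0_1"`, `"2"`, `"3"`;
#'   all three must be present.
#' @return An object of class `fazekas_thresholds`: `t_low`, `t_high`,
#'   `train_accuracy`.
#' @export
fit_fazekas_thresholds <- function(volumes_ml, labels) {
  labels <- as.character(labels)
  stopifnot(length(volumes_ml) == length(labels))
  if (!all(c("0_1", "2", "3") %in% labels))
    stop("all three Fazekas classes must be present")
  sv <- sort(unique(volumes_ml))
  cand <- c(0, if (length(sv) > 1) (head(sv, -1) + sv[-1]) / 2, Inf)
  best <- c(-1, NA, NA)
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (cand[j] <= cand[i]) next
      acc <- mean(classify_fazekas(volumes_ml, cand[i], cand[j]) == labels)
      if (acc > best[1] + 1e-12) best <- c(acc, cand[i], cand[j])
    }
  }
  structure(list(t_low = best[2], t_high = best[3],
                 train_accuracy = best[1]),
            class = "fazekas_thresholds")
}

classify_fazekas <- function(v, t_low, t_high) {
  ifelse(v < t_low, "0_1", ifelse(v < t_high, "2", "3"))
}

#' Cross-validated Fazekas estimation from WML volumes
#'
#' Fits volume thresholds on each training split and applies them to the
#' held-out split, accumulating a 3x3 confusion matrix (rows: visual score,
#' columns: automatic score) over all test predictions.
#'
#' @param volumes_ml,labels As [fit_fazekas_thresholds()].
#' @param n_folds Folds (default 10).
#' @param seed Fold assignment seed.
#' @param stratified Stratify folds by label (default TRUE; prevents folds
#'   whose training split misses a class).
#' @return List with `confusion` (3x3 matrix), `accuracy`
#'   (trace / total), `fold_thresholds` and `predictions`.
#' @export
cross_validated_fazekas <- function(volumes_ml, labels, n_folds = 10,
                                    seed = 1L, stratified = TRUE) {
  labels <- as.character(labels)
  n <- length(volumes_ml)
  stopifnot(n >= n_folds)
  if (!all(c("0_1", "2", "3") %in% labels))
    stop("all three Fazekas classes must be present")
  plan <- make_fold_plan(sprintf("s%03d", seq_len(n)), n_folds = n_folds,
                         n_repetitions = 1, seed = seed,
                         strata = if (stratified) labels else NULL)
  fold <- plan$assignment[1, ]
  lev <- c("0_1", "2", "3")
  cm <- matrix(0L, 3, 3, dimnames = list(visual = lev, automatic = lev))
  preds <- rep(NA_character_, n)
  thr <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 3) {
      warning("fold ", f, " training split misses a class; skipped")
      next
    }
    ft <- fit_fazekas_thresholds(volumes_ml[tr], labels[tr])
    thr[[f]] <- ft
    te <- which(fold == f)
    preds[te] <- classify_fazekas(volumes_ml[te], ft$t_low, ft$t_high)
  }
  ok <- !is.na(preds)
  for (i in which(ok))
    cm[labels[i], preds[i]] <- cm[labels[i], preds[i]] + 1L
  list(confusion = cm, accuracy = confusion_accuracy(cm),
       fold_thresholds = thr, predictions = preds)
}

#' Accuracy of a 3x3 confusion matrix
#'
#' The share of correct estimates: trace divided by the grand total.
#'
#' @param cm 3x3 non-negative count matrix (rows: visual score, columns:
#'   automatic score).
#' @return Accuracy fraction.
#' @examples
#' confusion_accuracy(example_fazekas_confusion()$ct)  # 0.78
#' @export
confusion_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(all(dim(cm) == c(3, 3)), all(cm >= 0))
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Cohort-level evaluation report
#'
#' Bundles all per-subject and cohort statistics: per-subject Dice and
#' correct/incorrect volumes against the reference segmentations, Pearson
#' correlation and OLS line of CT vs reference volumes, Bland-Altman
#' summary, and the cross-validated Fazekas confusion matrix and accuracy
#' from the CT volumes.
#'
#' @param results `ensemble_results` from [run_cv_ensemble()].
#' @param cohort The preprocessed cohort (providing `label` reference masks
#'   and `fazekas_label`s), in the same order/names.
#' @param n_folds Folds for the Fazekas cross-validation (default 10).
#' @param seed Seed for the Fazekas fold assignment.
#' @return A list of class `evaluation_report`: `per_subject` data.frame,
#'   `correlation`, `bland_altman`, `fazekas` (confusion + accuracy),
#'   `mean_dice`, `mean_dice_by_group`.
#' @export
evaluate_cohort <- function(results, cohort, n_folds = 10, seed = 1L) {
  ids <- names(results)
  stopifnot(all(ids %in% names(cohort)))
  per <- do.call(rbind, lapply(ids, function(id) {
    os <- overlap_stats(results[[id]]$final_mask, cohort[[id]]$label)
    data.frame(subject_id = id,
               fazekas_label = cohort[[id]]$fazekas_label,
               dice = os$dice, vol_ct_ml = os$vol_X_ml,
               vol_flair_ml = os$vol_Y_ml,
               vol_intersection_ml = os$vol_intersection_ml,
               vol_ct_only_ml = os$vol_X_only_ml,
               vol_flair_only_ml = os$vol_Y_only_ml,
               stringsAsFactors = FALSE)
  }))
  corr <- volume_correlation(per$vol_ct_ml, per$vol_flair_ml)
  ba <- bland_altman(per$vol_ct_ml, per$vol_flair_ml)
  fz <- cross_validated_fazekas(per$vol_ct_ml, per$fazekas_label,
                                n_folds = n_folds, seed = seed)
  structure(list(per_subject = per, correlation = corr, bland_altman = ba,
                 fazekas = fz, mean_dice = mean(per$dice),
                 mean_dice_by_group = tapply(per$dice, per$fazekas_label,
                                             mean)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  n = %d subjects; mean Dice %.3f\n", nrow(x$per_subject),
              x$mean_dice))
  cat(sprintf("  volume correlation r = %.3f, OLS slope %.3f\n",
              x$correlation$pearson_r, x$correlation$slope))
  cat(sprintf("  Fazekas accuracy (CV) = %.2f\n", x$fazekas$accuracy))
  invisible(x)
}
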