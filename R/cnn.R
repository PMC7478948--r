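#' CNN model specification
#'
#' Hyperparameters of the residual U-shaped segmentation network. The
#' architecture is a 2D encoder-decoder over 64 x 64 axial patches: per
#' resolution level one residual unit (`y = relu(x + conv3x3(x))`),
#' stride-2 convolutions down, nearest-neighbour upsampling with 1x1
#' channel projection and an additive encoder skip up, and a 1x1 output
#' convolution producing one lesion logit per pixel. Training minimizes
#' pixelwise binary cross-entropy with Adam.
#'
#' @param depth Number of resolution levels (default 3).
#' @param base_channels Channels at the finest level; doubled per level
#'   (default 8, sized for CPU training).
#' @param residual_blocks_per_level Residual units per level (fixed at 1 in
#'   this implementation).
#' @param loss Loss identifier; only `"bce"` is implemented.
#' @param learning_rate Adam step size (default 2e-3).
#' @param epochs Training epochs (default 20).
#' @param batch_size Patches per gradient step (default 16).
#' @param patch_size In-plane patch edge in pixels (default 64; must be
#'   divisible by `2^(depth-1)`).
#' @param seed Seed for weight initialization and shuffling.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(depth = 3, base_channels = 8,
                       residual_blocks_per_level = 1, loss = "bce",
                       learning_rate = 2e-3, epochs = 20, batch_size = 16,
                       patch_size = 64, seed = 1L) {
  stopifnot(depth >= 2, base_channels >= 1, loss == "bce",
            residual_blocks_per_level == 1,
            patch_size %% 2^(depth - 1) == 0)
  structure(list(architecture_id = "uresnet-like", depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 residual_blocks_per_level = 1L, loss_id = loss,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size), seed = as.integer(seed)),
            class = "model_spec")
}

#' Sample training patches from axial slices
#'
#' Draws 64 x 64 in-plane patches (image + binary label) from a cohort of
#' preprocessed volumes. A target fraction of patches is guaranteed to
#' contain at least one lesion pixel whenever the cohort has lesions;
#' volumes smaller than the patch are zero-padded.
#'
#' @param volumes List of subjects; each a list with `image`
#'   (`image_volume`, z-scored), `label` (binary `image_volume`), `mask`
#'   (binary `image_volume`) and optionally `id`.
#' @param n_patches Number of patches to draw.
#' @param lesion_fraction Minimum fraction of lesion-containing patches
#'   (default 0.5).
#' @param patch Patch edge (default 64).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A list of class `patch_set`: `image` and `label` 3D arrays
#'   (patch x patch x n) plus a data.frame `info` (subject, slice, corner).
#' @export
sample_patches <- function(volumes, n_patches, lesion_fraction = 0.5,
                           patch = 64, seed = 1L) {
  stopifnot(n_patches >= 1, lesion_fraction >= 0, lesion_fraction <= 1)
  set.seed(seed)
  ns <- length(volumes)
  # per-subject, per-slice lesion pixel counts
  les_slices <- lapply(volumes, function(v)
    which(apply(v$label$data, 3, sum) > 0))
  any_lesion <- any(vapply(les_slices, length, integer(1)) > 0)
  n_les <- round(lesion_fraction * n_patches)
  if (!any_lesion && n_les > 0) {
    warning("cohort contains no lesion pixels; returning background patches")
    n_les <- 0
  }
  img <- array(0, c(patch, patch, n_patches))
  lab <- array(0, c(patch, patch, n_patches))
  info <- data.frame(subject = character(n_patches),
                     slice = integer(n_patches),
                     corner_i = integer(n_patches),
                     corner_j = integer(n_patches), stringsAsFactors = FALSE)
  lesion_pool <- do.call(rbind, lapply(seq_len(ns), function(s) {
    sl <- les_slices[[s]]
    if (!length(sl)) return(NULL)
    cbind(s, sl)
  }))
  all_pool <- do.call(rbind, lapply(seq_len(ns), function(s) {
    sl <- which(apply(volumes[[s]]$mask$data, 3, sum) > 0)
    if (!length(sl)) sl <- seq_len(dim(volumes[[s]]$mask$data)[3])
    cbind(s, sl)
  }))
  for (k in seq_len(n_patches)) {
    want_lesion <- k <= n_les
    pool <- if (want_lesion) lesion_pool else all_pool
    row <- pool[sample.int(nrow(pool), 1), ]
    s <- row[1]; z <- row[2]
    im <- volumes[[s]]$image$data[, , z]
    lb <- volumes[[s]]$label$data[, , z]
    d <- dim(im)
    if (any(d < patch)) { # zero-pad small grids
      pi <- matrix(0, max(d[1], patch), max(d[2], patch))
      pl <- pi
      pi[seq_len(d[1]), seq_len(d[2])] <- im
      pl[seq_len(d[1]), seq_len(d[2])] <- lb
      im <- pi; lb <- pl; d <- dim(im)
    }
    if (want_lesion && any(lb > 0)) {
      pix <- which(lb > 0, arr.ind = TRUE)
      p <- pix[sample.int(nrow(pix), 1), ]
      ci <- min(max(1, p[1] - sample.int(patch, 1) + 1), d[1] - patch + 1)
      cj <- min(max(1, p[2] - sample.int(patch, 1) + 1), d[2] - patch + 1)
    } else {
      ci <- sample.int(d[1] - patch + 1, 1)
      cj <- sample.int(d[2] - patch + 1, 1)
    }
    img[, , k] <- im[ci:(ci + patch - 1), cj:(cj + patch - 1)]
    lab[, , k] <- lb[ci:(ci + patch - 1), cj:(cj + patch - 1)]
    info$subject[k] <- volumes[[s]]$id %||% as.character(s)
    info$slice[k] <- z; info$corner_i[k] <- ci; info$corner_j[k] <- cj
  }
  structure(list(image = img, label = lab, info = info),
            class = "patch_set")
}

#' Train the segmentation network
#'
#' @param spec A [model_spec()].
#' @param patches A `patch_set` from [sample_patches()] (at least one
#'   lesion-containing patch).
#' @return An object of class `trained_model`: `spec`, `params` (weight
#'   list), `training_subjects`, `loss_curve` (mean BCE per epoch).
#' @export
train_cnn <- function(spec, patches) {
  stopifnot(inherits(spec, "model_spec"), inherits(patches, "patch_set"))
  if (!any(patches$label > 0))
    stop("training error: no lesion-containing patches")
  fit <- cpp_cnn_train(patches$image, patches$label, spec$depth,
                       spec$base_channels, spec$learning_rate, spec$epochs,
                       spec$batch_size, spec$seed)
  structure(list(spec = spec, params = fit$params,
                 training_subjects = unique(patches$info$subject),
                 loss_curve = as.numeric(fit$loss_curve)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> depth %d, %d base channels; %d epochs, final loss %.5f\n",
    x$spec$depth, x$spec$base_channels, length(x$loss_curve),
    utils::tail(x$loss_curve, 1)))
  invisible(x)
}

#' Voxelwise lesion probability for a full volume
#'
#' Applies the trained network slice by slice. In-plane the volume is
#' covered by 64 x 64 tiles with 50% overlap (stride 32); each pixel's
#' probability is the mean over all tiles covering it. Volumes smaller than
#' one patch are zero-padded. Probabilities are zeroed outside the brain
#' mask.
#'
#' @param model A `trained_model`.
#' @param vol Preprocessed (z-scored) `image_volume`.
#' @param mask Binary brain mask on the same grid.
#' @return A probability `image_volume`.
#' @export
predict_probability <- function(model, vol, mask) {
  stopifnot(inherits(model, "trained_model"), inherits(vol, "image_volume"))
  patch <- model$spec$patch_size
  d <- dim(vol$data)
  H <- max(d[1], patch); W <- max(d[2], patch)
  ci <- tile_corners(H, patch); cj <- tile_corners(W, patch)
  ntile <- length(ci) * length(cj)
  # batch all tiles of all slices through one C++ call
  X <- array(0, c(patch, patch, ntile * d[3]))
  k <- 0
  for (z in seq_len(d[3])) {
    sl <- matrix(0, H, W)
    sl[seq_len(d[1]), seq_len(d[2])] <- vol$data[, , z]
    for (a in ci) for (b in cj) {
      k <- k + 1
      X[, , k] <- sl[a:(a + patch - 1), b:(b + patch - 1)]
    }
  }
  P <- cpp_cnn_predict(model$params, X, model$spec$depth,
                       model$spec$base_channels)
  out <- array(0, d)
  k <- 0
  for (z in seq_len(d[3])) {
    acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
    for (a in ci) for (b in cj) {
      k <- k + 1
      ii <- a:(a + patch - 1); jj <- b:(b + patch - 1)
      acc[ii, jj] <- acc[ii, jj] + P[, , k]
      cnt[ii, jj] <- cnt[ii, jj] + 1
    }
    out[, , z] <- (acc / cnt)[seq_len(d[1]), seq_len(d[2])]
  }
  out <- out * (mask$data > 0)
  image_volume(out, vol$spacing, vol$affine, "probability")
}

tile_corners <- function(extent, patch, stride = patch / 2) {
  if (extent <= patch) return(1L)
  cs <- seq(1L, extent - patch + 1L, by = stride)
  if (utils::tail(cs, 1) != extent - patch + 1L)
    cs <- c(cs, extent - patch + 1L)
  as.integer(cs)
}
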