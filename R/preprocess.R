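#' Brain extraction by thresholding and morphology
#'
#' A deliberately simple skull-stripping stand-in: Otsu threshold on the
#' intensity histogram, retain the largest 6-connected component, fill
#' internal holes.
#'
#' @param vol An intensity `image_volume`.
#' @return A binary `image_volume` (single connected component, no holes).
#' @export
extract_brain <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  thr <- otsu_threshold(as.vector(vol$data))
  fg <- vol$data > thr
  if (!any(fg)) stop("brain extraction error: no foreground above threshold")
  lab <- cpp_label3d(as.integer(fg), dim(vol$data))
  m <- as.integer(lab == 1L)
  m <- cpp_fill_holes(m, dim(vol$data))
  if (!any(m == 1L)) stop("brain extraction error: empty mask")
  image_volume(array(as.numeric(m), dim(vol$data)), vol$spacing, vol$affine,
               "mask")
}

otsu_threshold <- function(x, nbins = 256) {
  r <- range(x)
  if (diff(r) == 0) stop("constant image: no threshold exists")
  h <- tabulate(pmin(nbins, floor((x - r[1]) / diff(r) * nbins) + 1), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / nbins * diff(r)
}

#' Registration result
#'
#' @param transform Estimated transform.
#' @param final_metric Similarity at the optimum (NMI for rigid, soft Dice
#'   for the 9-DOF mask registration).
#' @param converged Logical convergence flag.
#' @param iterations Total metric evaluations used.
#' @return An object of class `registration_result`.
#' @keywords internal
registration_result <- function(transform, final_metric, converged,
                                iterations) {
  structure(list(transform = transform, final_metric = final_metric,
                 converged = converged, iterations = iterations),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> metric %.5f  converged %s  (%d evals)\n",
              x$final_metric, x$converged, x$iterations))
  print(x$transform)
  invisible(x)
}

#' Spatial normalization: 9-DOF affine registration of a brain mask to a
#' template mask
#'
#' Initializes from mask centroids and per-axis second moments, then
#' polishes rotation/translation/scale by maximizing a soft Dice overlap
#' (linear interpolation of the moving mask) with Nelder-Mead, in a
#' two-level coarse-to-fine scheme capped at 200 evaluations per level.
#' The returned metric is guaranteed not to be worse than the metric at the
#' identity or at the moment initialization.
#'
#' @param brain_mask Binary subject mask (moving).
#' @param template_mask Binary template mask (fixed; defines the target grid).
#' @return A `registration_result` holding an [affine_transform()] that maps
#'   template world coordinates into subject world coordinates (i.e. the
#'   transform to use when resampling subject images onto the template grid).
#' @export
normalize_spatial <- function(brain_mask, template_mask) {
  stopifnot(is_binary(brain_mask), is_binary(template_mask))
  fixed <- template_mask
  center <- grid_center_world(fixed)

  stat <- function(v) {
    w <- voxel_world_coords(v)[as.vector(v$data) > 0, , drop = FALSE]
    list(mu = colMeans(w), sd = apply(w, 2, sd))
  }
  sf <- stat(fixed); sm <- stat(brain_mask)
  s0 <- sm$sd / sf$sd
  t0 <- sm$mu - (s0 * (sf$mu - center) + center)
  p0 <- c(0, 0, 0, t0, log(s0))

  # continuous (smoothed) masks: softening the jagged voxelized boundary
  # makes the overlap metric sensitive at sub-voxel scale
  mov <- gaussian_smooth(with_data(brain_mask, brain_mask$data,
                                   modality = "flair"), brain_mask$spacing)
  fdat <- gaussian_smooth(with_data(fixed, fixed$data, modality = "flair"),
                          fixed$spacing)$data
  evals <- 0L
  metric <- function(p, fx, mv) {
    evals <<- evals + 1L
    tr <- affine_transform(rotation = p[1:3], translation = p[4:6],
                           scale = exp(p[7:9]), center = center)
    m <- resample(mv, tr, fx, "linear")$data
    2 * sum(m * fx$data) / (sum(m) + sum(fx$data))
  }
  fix_obj <- with_data(fixed, fdat, modality = "flair")
  coarse_f <- downsample2(fix_obj); coarse_m <- downsample2(mov)

  d0 <- metric(rep(0, 9), fix_obj, mov)  # identity (scales are log-coded)
  dm <- metric(p0, fix_obj, mov)
  if (dm < 1e-6 && d0 < 1e-6)
    return(registration_result(affine_transform(center = center), 0, FALSE,
                               evals))
  o1 <- optim(p0, function(p) -metric(p, coarse_f, coarse_m),
              method = "Nelder-Mead", control = list(maxit = 200))
  o2 <- optim(o1$par, function(p) -metric(p, fix_obj, mov),
              method = "Nelder-Mead",
              control = list(maxit = 200, reltol = 1e-10))
  cand <- list(rep(0, 9), p0, o2$par)
  vals <- vapply(cand, metric, numeric(1), fx = fix_obj, mv = mov)
  best <- which.max(vals)
  p <- cand[[best]]
  registration_result(
    affine_transform(rotation = p[1:3], translation = p[4:6],
                     scale = exp(p[7:9]), center = center),
    final_metric = vals[best],
    converged = vals[best] >= d0 && vals[best] > 0, iterations = evals)
}

#' Rigid CT-to-FLAIR registration by normalized mutual information
#'
#' Estimates the 6-parameter rigid transform aligning a moving image to a
#' fixed image by maximizing normalized mutual information,
#' `NMI = (H(F) + H(M)) / H(F, M)`, computed from a 32-bin joint histogram
#' over the in-mask overlap domain. Optimization is two-level
#' coarse-to-fine Nelder-Mead (cap 200 evaluations per level) preceded by a
#' coarse translation grid search. The returned transform is never worse
#' (in NMI) than the identity.
#'
#' @param moving,fixed Intensity `image_volume`s with overlapping fields of
#'   view.
#' @param mask Optional binary mask in fixed space restricting the metric
#'   domain (default: voxels above the fixed image's Otsu threshold).
#' @param nbins Histogram bins per axis (default 32).
#' @param max_translation Half-width (mm) of the initial translation search
#'   grid.
#' @param smooth_sigma_mm Gaussian pre-smoothing SD in mm applied to both
#'   images before the metric is evaluated (default: one voxel of the fixed
#'   image per axis). Smoothing suppresses the interpolation artifact by
#'   which resampling averages the moving image's noise and spuriously
#'   sharpens the joint histogram away from alignment.
#' @return A `registration_result` whose transform maps fixed world
#'   coordinates to moving world coordinates; apply with
#'   `resample(moving, result$transform, fixed)`.
#' @export
register_rigid_nmi <- function(moving, fixed, mask = NULL, nbins = 32,
                               max_translation = 4, smooth_sigma_mm = NULL) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  center <- grid_center_world(fixed)
  if (is.null(mask)) {
    thr <- otsu_threshold(as.vector(fixed$data))
    mdat <- fixed$data > thr
  } else mdat <- mask$data > 0
  if (is.null(smooth_sigma_mm)) smooth_sigma_mm <- fixed$spacing
  if (any(smooth_sigma_mm > 0)) {
    fixed <- gaussian_smooth(fixed, smooth_sigma_mm)
    moving <- gaussian_smooth(moving, smooth_sigma_mm)
  }

  rng_f <- range(fixed$data); rng_m <- range(moving$data)
  evals <- 0L
  nmi_of <- function(fvals, mvals) {
    H <- cpp_joint_hist(fvals, mvals, nbins, rng_f[1], rng_f[2],
                        rng_m[1], rng_m[2])
    n <- sum(H)
    if (n < 100) return(0)
    pj <- H / n
    px <- rowSums(pj); py <- colSums(pj)
    hx <- -sum(px[px > 0] * log(px[px > 0]))
    hy <- -sum(py[py > 0] * log(py[py > 0]))
    hxy <- -sum(pj[pj > 0] * log(pj[pj > 0]))
    if (hxy == 0) return(0)
    (hx + hy) / hxy
  }
  metric <- function(p, fx, mv, sel) {
    evals <<- evals + 1L
    tr <- rigid_transform(rotation = p[1:3], translation = p[4:6],
                          center = center)
    m <- resample(mv, tr, fx, "linear", fill = NA)$data
    nmi_of(fx$data[sel], m[sel])
  }

  cf <- downsample2(fixed); cm <- downsample2(moving)
  csel <- downsample2(with_data(fixed, array(as.numeric(mdat), dim(fixed$data)),
                                modality = "flair"))$data > 0.5

  # translation pre-search on the coarse level
  steps <- seq(-max_translation, max_translation, by = 2)
  best_t <- c(0, 0, 0); best_v <- -Inf
  for (tx in steps) for (ty in steps) for (tz in steps) {
    v <- metric(c(0, 0, 0, tx, ty, tz), cf, cm, csel)
    if (v > best_v) { best_v <- v; best_t <- c(tx, ty, tz) }
  }
  p0 <- c(0, 0, 0, best_t)
  o1 <- optim(p0, function(p) -metric(p, cf, cm, csel),
              method = "Nelder-Mead",
              control = list(maxit = 200, reltol = 1e-9))
  o2 <- optim(o1$par, function(p) -metric(p, fixed, moving, mdat),
              method = "Nelder-Mead",
              control = list(maxit = 200, reltol = 1e-10))
  ident_v <- metric(rep(0, 6), fixed, moving, mdat)
  final_v <- metric(o2$par, fixed, moving, mdat)
  # converged: the optimum improved on the identity (the iteration caps mean
  # optim()'s own code reports maxit more often than not)
  if (final_v >= ident_v) {
    p <- o2$par; v <- final_v; conv <- TRUE
  } else {
    p <- rep(0, 6); v <- ident_v; conv <- FALSE
  }
  registration_result(
    rigid_transform(rotation = p[1:3], translation = p[4:6], center = center),
    final_metric = v, converged = conv, iterations = evals)
}

#' Z-score intensity normalization within a brain mask
#'
#' Centres and scales intensities so that the in-mask mean is 0 and the
#' in-mask population SD (denominator n) is 1; out-of-mask voxels are set
#' to 0.
#'
#' @param vol Intensity `image_volume`.
#' @param mask Binary `image_volume` on the same grid.
#' @return A list: `volume` (normalized `image_volume`) and `params`
#'   (list with `mean_in_mask`, `sd_in_mask`).
#' @export
zscore_in_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "image_volume"), is_binary(mask),
            all(dim(vol$data) == dim(mask$data)))
  sel <- mask$data > 0
  n <- sum(sel)
  if (n < 2) stop("normalization error: fewer than 2 in-mask voxels")
  x <- vol$data[sel]
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))  # population SD
  if (sigma == 0) stop("normalization error: zero variance within mask")
  out <- array(0, dim(vol$data))
  out[sel] <- (x - mu) / sigma
  list(volume = with_data(vol, out),
       params = list(mean_in_mask = mu, sd_in_mask = sigma))
}

#' Run the full preprocessing chain on one phantom pair
#'
#' Mirrors the analysis pipeline: (1) brain extraction from FLAIR (or use
#' the supplied mask); (2) 9-DOF spatial normalization of the brain mask to
#' the template mask; (3) rigid registration of CT to FLAIR by NMI; (4)
#' resampling of FLAIR, mask, lesion labels and CT onto the template grid
#' (the CT through the composed rigid-then-affine mapping, one
#' interpolation); (5) z-scoring of both channels within the brain mask.
#'
#' @param pair A `phantom_pair` (or any list with `flair`, `ct`,
#'   `brain_mask`, `wml_truth` volumes).
#' @param template Binary template mask (default [template_mask()] at the
#'   pair's geometry).
#' @param use_provided_mask Use `pair$brain_mask` instead of running
#'   [extract_brain()] (default TRUE; set FALSE to exercise extraction).
#' @param do_affine Apply the spatial normalization step (default TRUE).
#' @return A list of class `preprocessed_subject`: z-scored `flair` and
#'   `ct` in template space, `mask`, `label` (lesion truth), the two
#'   `registration_result`s, and the `NormalizationParams` of both channels.
#' @export
preprocess_pair <- function(pair, template = NULL, use_provided_mask = TRUE,
                            do_affine = TRUE) {
  if (is.null(template))
    template <- template_mask(dim(pair$flair$data), pair$flair$spacing)
  mask <- if (use_provided_mask) pair$brain_mask else extract_brain(pair$flair)

  rig <- register_rigid_nmi(pair$ct, pair$flair, mask = mask)

  if (do_affine) {
    aff <- normalize_spatial(mask, template)
    t_aff <- aff$transform
  } else {
    aff <- NULL
    t_aff <- rigid_transform(center = grid_center_world(template))
  }
  flair_t <- resample(pair$flair, t_aff, template, "linear")
  mask_t <- resample(mask, t_aff, template, "nearest")
  label_t <- resample(pair$wml_truth, t_aff, template, "nearest")
  ct_t <- resample(pair$ct, compose_transforms(rig$transform, t_aff),
                   template, "linear")

  zf <- zscore_in_mask(flair_t, mask_t)
  zc <- zscore_in_mask(ct_t, mask_t)
  structure(list(flair = zf$volume, ct = zc$volume, mask = mask_t,
                 label = label_t, rigid = rig, affine = aff,
                 norm_flair = zf$params, norm_ct = zc$params,
                 fazekas_label = pair$fazekas_label %||% NA_character_),
            class = "preprocessed_subject")
}
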