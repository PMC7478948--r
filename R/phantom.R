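#' Specification of a paired FLAIR/CT phantom
#'
#' Describes one synthetic subject: an ellipsoidal "brain" with smooth
#' internal texture, blob-shaped white matter lesions placed in the
#' periventricular/deep white matter shell, a high-contrast hyperintense
#' FLAIR channel, a low-contrast (hypodense) noisier CT channel, and a known
#' rigid misalignment applied to the CT channel.
#'
#' Intensities are built on an arbitrary scale (tissue base 10) that the
#' pipeline later z-scores away; the contrast parameters are expressed as a
#' lesion-minus-tissue gap in units of roughly one in-brain SD ("z-units").
#' Lesions are hyperintense on FLAIR (`flair_contrast > 0`) and hypodense on
#' CT (`ct_contrast < 0`, smaller in magnitude), so `ct_contrast <
#' flair_contrast` always.
#'
#' @param grid_shape Integer length-3 grid (default `c(64, 64, 24)`: small
#'   enough for CPU training, anisotropic like clinical acquisitions).
#' @param spacing Voxel size mm (default `c(2, 2, 4)`, i.e. thick axial
#'   slices).
#' @param n_lesions Explicit lesion count, or `NULL` (default) to add
#'   lesions until the target load drawn from the Fazekas group interval is
#'   reached.
#' @param lesion_radius_range Lesion radius interval in mm.
#' @param fazekas_target `"0_1"`, `"2"` or `"3"`; selects the lesion-load
#'   interval.
#' @param load_intervals_ml Named list of per-group total-load intervals in
#'   mL; defaults 0-2 / 5-15 / 25-60 (monotone, well separated strata).
#' @param flair_contrast,ct_contrast Lesion intensity gap (z-units);
#'   `ct_contrast` must be smaller than `flair_contrast`.
#' @param noise_sd_flair,noise_sd_ct Additive Gaussian noise SD (z-units);
#'   CT is noisier by default.
#' @param misalignment A [rigid_transform()] giving the CT-to-FLAIR
#'   correction that a registration should recover, or `NULL` (default) to
#'   draw one with rotations <= 5 deg and translations <= 4 mm.
#' @param seed Integer seed; the pair is fully deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 24), spacing = c(2, 2, 4),
                         n_lesions = NULL, lesion_radius_range = c(2, 7),
                         fazekas_target = c("2", "0_1", "3"),
                         load_intervals_ml = list("0_1" = c(0, 2),
                                                  "2" = c(5, 15),
                                                  "3" = c(25, 60)),
                         flair_contrast = 2.5, ct_contrast = -1.2,
                         noise_sd_flair = 0.3, noise_sd_ct = 0.5,
                         misalignment = NULL, seed = 1L) {
  fazekas_target <- match.arg(fazekas_target)
  if (!(ct_contrast < flair_contrast))
    stop("ct_contrast must be smaller than flair_contrast (CT shows WML at lower contrast)")
  iv <- load_intervals_ml
  if (!(iv[["0_1"]][2] <= iv[["2"]][1] && iv[["2"]][2] <= iv[["3"]][1]))
    stop("load intervals must be disjoint and increasing: 0_1 < 2 < 3")
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 n_lesions = n_lesions,
                 lesion_radius_range = lesion_radius_range,
                 fazekas_target = fazekas_target,
                 load_intervals_ml = iv,
                 flair_contrast = flair_contrast, ct_contrast = ct_contrast,
                 noise_sd_flair = noise_sd_flair, noise_sd_ct = noise_sd_ct,
                 misalignment = misalignment, seed = as.integer(seed)),
            class = "phantom_spec")
}

# canonical brain semi-axes (mm); deliberately unequal so rotations are
# identifiable by registration
.brain_axes <- c(44, 54, 34)

#' Brain mask of the mean anatomical template
#'
#' Canonical-pose ellipsoidal brain mask used as the target of 9-DOF spatial
#' normalization. Phantom subjects are jittered versions of this shape.
#'
#' @param grid_shape,spacing Grid geometry (defaults as [phantom_spec()]).
#' @return A binary `image_volume`.
#' @export
template_mask <- function(grid_shape = c(64, 64, 24), spacing = c(2, 2, 4)) {
  g <- phantom_geometry(grid_shape, spacing)
  rho <- ellipsoid_rho(g$coords, g$center, .brain_axes)
  image_volume(array(as.numeric(rho <= 1), grid_shape), spacing = spacing,
               affine = g$affine, modality = "mask")
}

phantom_geometry <- function(grid_shape, spacing) {
  affine <- diag(c(spacing, 1))
  d <- grid_shape
  center <- as.vector(affine %*% c((d - 1) / 2, 1))[1:3]
  x <- (seq_len(d[1]) - 1) * spacing[1]
  y <- (seq_len(d[2]) - 1) * spacing[2]
  z <- (seq_len(d[3]) - 1) * spacing[3]
  coords <- list(x = x, y = y, z = z)
  list(affine = affine, center = center, coords = coords, dim = d)
}

# normalized ellipsoid radius field over the grid
ellipsoid_rho <- function(coords, center, axes) {
  nx <- (coords$x - center[1]) / axes[1]
  ny <- (coords$y - center[2]) / axes[2]
  nz <- (coords$z - center[3]) / axes[3]
  sqrt(outer(outer(nx^2, ny^2, `+`), nz^2, `+`))
}

# squared mm distance field from a point, with optional per-axis radii
ellipsoid_q <- function(coords, pt, radii) {
  nx <- (coords$x - pt[1]) / radii[1]
  ny <- (coords$y - pt[2]) / radii[2]
  nz <- (coords$z - pt[3]) / radii[3]
  sqrt(outer(outer(nx^2, ny^2, `+`), nz^2, `+`))
}

#' Generate one paired FLAIR/CT phantom
#'
#' Deterministic given `spec$seed`. The FLAIR and CT channels share the same
#' anatomy (ellipsoidal brain plus smooth texture); lesions appear with high
#' positive contrast on FLAIR and low negative contrast on CT; the CT is
#' resampled through the inverse of the stored misalignment so that rigid
#' registration of CT to FLAIR should recover `true_misalignment`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_pair` with fields `flair`, `ct`,
#'   `brain_mask`, `wml_truth` (all `image_volume`s; masks in FLAIR space),
#'   `true_misalignment` ([rigid_transform()]), `fazekas_label`, and the
#'   realized `n_lesions` / `true_volume_ml`.
#' @examples
#' p <- generate_pair(phantom_spec(fazekas_target = "3", seed = 7))
#' volume_ml(p$wml_truth)
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- phantom_geometry(spec$grid_shape, spec$spacing)
  d <- g$dim
  voxvol <- prod(spec$spacing)

  axes <- .brain_axes * runif(3, 0.96, 1.04)
  rho <- ellipsoid_rho(g$coords, g$center, axes)
  brain <- rho <= 1

  # smooth anatomical texture shared by both channels: sum of random bumps
  texture <- array(0, d)
  for (k in seq_len(10)) {
    ctr <- g$center + runif(3, -0.5, 0.5) * axes
    sdk <- runif(1, 8, 22)
    amp <- rnorm(1, 0, 0.55)
    texture <- texture + amp * exp(-ellipsoid_q(g$coords, ctr, rep(sdk, 3))^2 / 2)
  }

  # lesions: blobs in the periventricular / deep white matter shell
  interval <- spec$load_intervals_ml[[spec$fazekas_target]]
  lesion <- array(FALSE, d)
  profile <- array(0, d)
  n_placed <- 0L
  if (is.null(spec$n_lesions)) {
    w <- diff(interval)
    target <- runif(1, interval[1] + 0.05 * w, interval[2] - 0.15 * w)
    attempts <- 0L
    while (sum(lesion) * voxvol / 1000 < target) {
      attempts <- attempts + 1L
      if (attempts > 500L)
        stop("phantom generation error: lesion load target infeasible inside mask")
      rem <- target - sum(lesion) * voxvol / 1000
      # cap the blob radius so even a maximally stretched blob cannot push
      # the load past the target by more than one minimum-radius blob
      rcap <- (3 * rem * 1000 / (4 * pi))^(1 / 3) / 1.2
      r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
      r <- max(spec$lesion_radius_range[1], min(r, rcap))
      placed <- place_lesion(g, axes, r)
      if (is.null(placed)) next
      q <- ellipsoid_q(g$coords, placed$ctr, placed$radii)
      supp <- q <= 1 & brain & rho <= 0.95
      if (!any(supp)) next
      lesion <- lesion | supp
      profile <- pmax(profile, pmin(1, pmax(0, (1 - q) / 0.3)) * supp)
      n_placed <- n_placed + 1L
    }
  } else if (spec$n_lesions > 0) {
    for (k in seq_len(spec$n_lesions)) {
      r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
      placed <- place_lesion(g, axes, r)
      if (is.null(placed)) next
      q <- ellipsoid_q(g$coords, placed$ctr, placed$radii)
      supp <- q <= 1 & brain & rho <= 0.95
      lesion <- lesion | supp
      profile <- pmax(profile, pmin(1, pmax(0, (1 - q) / 0.3)) * supp)
      n_placed <- n_placed + 1L
    }
  }
  true_vol <- sum(lesion) * voxvol / 1000
  label <- volume_to_label(true_vol, spec$load_intervals_ml)

  flair_arr <- ifelse(brain, 10 + texture + spec$flair_contrast * profile, 0) +
    rnorm(prod(d), 0, ifelse(brain, spec$noise_sd_flair, 0.06))
  ct_arr <- ifelse(brain, 10 + 0.7 * texture + spec$ct_contrast * profile, 0)
  dim(flair_arr) <- d; dim(ct_arr) <- d

  flair <- image_volume(flair_arr, spec$spacing, g$affine, "flair")
  ct_aligned <- image_volume(ct_arr, spec$spacing, g$affine, "ct")

  mis <- spec$misalignment
  if (is.null(mis))
    mis <- rigid_transform(rotation = runif(3, -5, 5),
                           translation = runif(3, -4, 4),
                           center = g$center)
  else
    mis <- rigid_transform(mis$rotation, mis$translation, center = g$center)
  # misalign the noiseless CT, then add acquisition noise in the observed
  # frame (noise is a property of the scan, not of the anatomy)
  ct <- resample(ct_aligned, invert_transform(mis), ct_aligned, "linear")
  ct_brain <- resample(
    image_volume(array(as.numeric(brain), d), spec$spacing, g$affine, "mask"),
    invert_transform(mis), ct_aligned, "nearest")
  ct$data <- ct$data +
    array(rnorm(prod(d), 0, ifelse(ct_brain$data > 0, spec$noise_sd_ct, 0.06)), d)

  structure(list(
    flair = flair, ct = ct,
    brain_mask = image_volume(array(as.numeric(brain), d), spec$spacing,
                              g$affine, "mask"),
    wml_truth = image_volume(array(as.numeric(lesion), d), spec$spacing,
                             g$affine, "mask"),
    true_misalignment = mis, fazekas_label = label,
    n_lesions = n_placed, true_volume_ml = true_vol, spec = spec),
    class = "phantom_pair")
}

place_lesion <- function(g, axes, r_mm) {
  for (k in seq_len(30)) {
    u <- runif(3, -1, 1)
    rho_c <- sqrt(sum(u^2))
    if (rho_c < 0.25 || rho_c > 0.7) next
    ctr <- g$center + u * axes
    radii <- r_mm * runif(3, 0.8, 1.2)
    return(list(ctr = ctr, radii = radii))
  }
  NULL
}

volume_to_label <- function(v, intervals) {
  if (v < intervals[["2"]][1]) "0_1"
  else if (v < intervals[["3"]][1]) "2"
  else "3"
}

#' Generate a Fazekas-stratified phantom cohort
#'
#' Produces `sum(n_per_group)` phantom pairs with per-group lesion loads
#' drawn from the group intervals; all per-subject seeds are derived
#' deterministically from the cohort seed.
#'
#' @param n_per_group Integer length-3: subjects in groups 0-1, 2, 3
#'   (e.g. `c(50, 48, 49)` mirrors a 147-subject clinical cohort).
#' @param base_spec Template [phantom_spec()]; per-subject specs vary only
#'   the target group and seed.
#' @param seed Cohort seed.
#' @return A list of class `phantom_cohort`: `pairs` (list of
#'   `phantom_pair`) and `manifest` (data.frame with subject_id,
#'   fazekas_label, true_volume_ml, seed).
#' @export
generate_cohort <- function(n_per_group, base_spec = phantom_spec(),
                            seed = 1L) {
  stopifnot(length(n_per_group) == 3, all(n_per_group >= 1))
  groups <- rep(c("0_1", "2", "3"), times = n_per_group)
  n <- length(groups)
  seeds <- (as.numeric(seed) * 10007 + seq_len(n) * 7919) %% 2147483587 + 1
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$fazekas_target <- groups[i]
    sp$seed <- as.integer(seeds[i])
    pairs[[i]] <- generate_pair(sp)
  }
  ids <- sprintf("subj%03d", seq_len(n))
  manifest <- data.frame(subject_id = ids, fazekas_label = groups,
                         true_volume_ml = vapply(pairs, function(p)
                           p$true_volume_ml, numeric(1)),
                         seed = as.integer(seeds),
                         stringsAsFactors = FALSE)
  names(pairs) <- ids
  structure(list(pairs = pairs, manifest = manifest, seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects (%s)\n", nrow(x$manifest),
              paste(table(x$manifest$fazekas_label), collapse = "/")))
  invisible(x)
}
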