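#' Resample a volume onto a reference grid through a spatial transform
#'
#' For every voxel of the reference grid, the transform maps its world
#' coordinates into the moving volume's world space and the moving volume is
#' interpolated there. Out-of-field voxels are filled with 0 (background;
#' brain-extracted images are 0 outside the head).
#'
#' @param vol Moving `image_volume`.
#' @param transform A `rigid_transform`, `affine_transform` or 4x4
#'   world-to-world matrix mapping reference world coords to `vol` world
#'   coords. `NULL` means identity.
#' @param reference `image_volume` defining the output grid (default `vol`).
#' @param interpolation `"linear"` or `"nearest"`. Masks must use
#'   `"nearest"` (so outputs stay binary).
#' @param fill Fill value outside the moving field of view (default 0;
#'   `NA` is used internally by registration to delimit the overlap domain).
#' @return An `image_volume` on the reference grid, same modality as `vol`.
#' @examples
#' v <- image_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
#' ident <- resample(v, rigid_transform(), v)
#' all.equal(ident$data, v$data)
#' @export
resample <- function(vol, transform = NULL, reference = vol,
                     interpolation = c("linear", "nearest"), fill = 0) {
  stopifnot(inherits(vol, "image_volume"), inherits(reference, "image_volume"))
  interpolation <- match.arg(interpolation)
  if (vol$modality == "mask" && interpolation != "nearest")
    stop("masks must be resampled with nearest-neighbour interpolation")
  Tw <- if (is.null(transform)) diag(4) else transform_matrix(transform)
  M <- solve(vol$affine) %*% Tw %*% reference$affine
  dout <- dim(reference$data)
  out <- cpp_resample(as.vector(vol$data), dim(vol$data), M, dout,
                      interpolation == "linear", fill)
  res <- image_volume(array(out, dout), spacing = reference$spacing,
                      affine = reference$affine, modality = vol$modality)
  res
}

#' Separable Gaussian smoothing of a volume
#'
#' Convolves each axis with a discrete Gaussian (truncated at 3 sigma).
#' Used to regularize intensities before histogram-based registration.
#'
#' @param vol An `image_volume`.
#' @param sigma_mm Gaussian SD in mm, scalar or per-axis.
#' @return A smoothed `image_volume` (modality preserved unless binary
#'   constraints would break, in which case the result is tagged as
#'   intensity data).
#' @export
gaussian_smooth <- function(vol, sigma_mm = 2) {
  sigma_mm <- rep(as.numeric(sigma_mm), length.out = 3)
  a <- vol$data
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_mm[ax] / vol$spacing[ax]  # sigma in voxels
    if (s <= 0) next
    h <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-h, h))^2 / (2 * s^2))
    k <- k / sum(k)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (o in -h:h) {
      idx <- seq_len(n)
      tgt <- idx + o
      ok <- tgt >= 1 & tgt <= n
      K[cbind(idx[ok], tgt[ok])] <- K[cbind(idx[ok], tgt[ok])] + k[o + h + 1]
    }
    K <- K / rowSums(K)  # renormalize at the borders
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, nrow = dp[1])
    dim(m) <- dp
    a <- aperm(m, order(perm))
  }
  mod <- if (vol$modality %in% c("mask", "probability")) "flair" else vol$modality
  image_volume(a, vol$spacing, vol$affine, mod)
}

# block-mean downsampling by 2 in-plane and (if possible) through-plane;
# used by the multi-resolution registration pyramid
downsample2 <- function(vol) {
  d <- dim(vol$data)
  f <- ifelse(d >= 8 & d %% 2 == 0, 2L, 1L)
  nd <- d %/% f
  a <- vol$data[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]),
                seq_len(nd[3] * f[3]), drop = FALSE]
  dim(a) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  a <- apply(a, c(2, 4, 6), mean)
  shift <- (f - 1) / 2
  A <- vol$affine %*% rbind(cbind(diag(as.numeric(f)), shift), c(0, 0, 0, 1))
  image_volume(a, spacing = vol$spacing * f, affine = A,
               modality = if (vol$modality %in% c("mask", "probability"))
                 "flair" else vol$modality)
}
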