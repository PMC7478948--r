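#' 3D image volume container
#'
#' The universal carrier for all image data in the pipeline: a 3D scalar
#' array plus voxel spacing (mm), a 4x4 grid-index-to-world affine (NIfTI
#' convention, 0-based indices, world units mm) and a modality tag.
#'
#' @param data 3D numeric array. For `modality = "mask"` values must be in
#'   \{0, 1\}; for `"probability"` values must lie in \[0, 1\].
#' @param spacing Numeric length-3, voxel size per axis in mm (all > 0).
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm.
#'   Default: `diag(c(spacing, 1))` (origin at voxel (0,0,0)).
#' @param modality One of `"flair"`, `"ct"`, `"mask"`, `"probability"`.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `affine`, `modality`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 5),
#'                   modality = "mask")
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                         modality = c("flair", "ct", "mask", "probability")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("upper-left 3x3 of `affine` is singular")
  storage.mode(data) <- "double"
  v <- structure(list(data = data, spacing = spacing, affine = affine,
                      modality = modality),
                 class = "image_volume")
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  if (v$modality == "mask") {
    u <- unique(as.vector(v$data))
    if (!all(u %in% c(0, 1)))
      stop("a volume tagged 'mask' may contain only 0 and 1")
  } else if (v$modality == "probability") {
    r <- range(v$data)
    if (r[1] < 0 || r[2] > 1)
      stop("a volume tagged 'probability' must lie in [0, 1]")
  }
  invisible(v)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %d x %d x %d  spacing %.3g x %.3g x %.3g mm\n",
              x$modality, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_binary <- function(x) {
  all(unique(as.vector(if (inherits(x, "image_volume")) x$data else x)) %in% c(0, 1))
}

#' Replace the data of a volume, keeping its geometry
#'
#' @param vol An `image_volume` providing spacing/affine.
#' @param data New 3D array (same dimensions).
#' @param modality Modality tag for the result (default: keep).
#' @return A new `image_volume`.
#' @export
with_data <- function(vol, data, modality = vol$modality) {
  stopifnot(inherits(vol, "image_volume"), all(dim(data) == dim(vol$data)))
  image_volume(data, spacing = vol$spacing, affine = vol$affine,
               modality = modality)
}

#' Lesion volume of a binary mask in millilitres
#'
#' Number of foreground voxels times the voxel volume (product of the three
#' spacings, in mm^3), divided by 1000.
#'
#' @param mask A binary `image_volume`.
#' @return Volume in mL.
#' @examples
#' m <- image_volume(array(1, c(10, 10, 10)), spacing = c(1, 1, 1),
#'                   modality = "mask")
#' volume_ml(m)  # 1 mL
#' @export
volume_ml <- function(mask) {
  stopifnot(inherits(mask, "image_volume"))
  if (!is_binary(mask))
    stop("volume_ml() requires a binary mask")
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' World coordinates of the grid centre
#'
#' @param vol An `image_volume`.
#' @return Length-3 world coordinates (mm) of the volume centre.
#' @export
grid_center_world <- function(vol) {
  d <- dim(vol$data)
  as.vector(vol$affine %*% c((d - 1) / 2, 1))[1:3]
}

# world coordinates of every voxel; returns n x 3 matrix (lazy, cached upstream)
voxel_world_coords <- function(vol) {
  d <- dim(vol$data)
  idx <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  sweep(idx %*% t(vol$affine[1:3, 1:3]), 2, vol$affine[1:3, 4], `+`)
}
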