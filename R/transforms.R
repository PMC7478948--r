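#' Rigid spatial transform (6 degrees of freedom)
#'
#' Parametric mapping of world coordinates: `w' = R (w - c) + c + t`, with
#' `R` the rotation built from ZYX Euler angles (degrees) and `t` the
#' translation (mm). The rotation centre `c` is carried with the transform
#' so parameters remain comparable between an applied perturbation and a
#' registration estimate. In resampling, transforms map *fixed-image* world
#' coordinates to *moving-image* world coordinates (pull-back convention).
#'
#' @param rotation Length-3 Euler angles in degrees (x, y, z; applied as
#'   `Rz %*% Ry %*% Rx`).
#' @param translation Length-3 offsets in mm.
#' @param center Length-3 rotation centre in world mm (default origin).
#' @return An object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(rotation = c(0, 0, 5), translation = c(2, 0, 0))
#' transform_matrix(t)
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = c("rigid_transform", "spatial_transform"))
}

#' Affine spatial transform (9 degrees of freedom)
#'
#' As [rigid_transform()] plus strictly positive per-axis scale factors:
#' `w' = R S (w - c) + c + t` with `S = diag(scale)`.
#'
#' @inheritParams rigid_transform
#' @param scale Length-3 strictly positive per-axis scale factors.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                             scale = c(1, 1, 1), center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(scale) == 3, length(center) == 3)
  scale <- as.numeric(scale)
  if (any(scale <= 0)) stop("scale factors must be strictly positive")
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 scale = scale, center = as.numeric(center)),
            class = c("affine_transform", "spatial_transform"))
}

euler_rotation <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# extract ZYX Euler angles (degrees) from a rotation matrix
euler_angles <- function(R) {
  beta <- asin(max(-1, min(1, -R[3, 1])))
  alpha <- atan2(R[3, 2], R[3, 3])
  gamma <- atan2(R[2, 1], R[1, 1])
  c(alpha, beta, gamma) * 180 / pi
}

#' 4x4 homogeneous matrix of a spatial transform
#'
#' @param t A `rigid_transform`, `affine_transform`, or a 4x4 matrix
#'   (returned unchanged).
#' @return 4x4 matrix mapping world coordinates to world coordinates.
#' @export
transform_matrix <- function(t) {
  if (is.matrix(t)) {
    stopifnot(all(dim(t) == c(4, 4)))
    return(t)
  }
  stopifnot(inherits(t, "spatial_transform"))
  R <- euler_rotation(t$rotation)
  if (inherits(t, "affine_transform")) R <- R %*% diag(t$scale)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t$center + t$translation - R %*% t$center
  M
}

#' Invert a spatial transform
#'
#' The inverse carries the same rotation centre, so that composing a
#' transform with its inverse maps any point to itself.
#'
#' @param t A `rigid_transform` or `affine_transform`.
#' @return A transform of the same class.
#' @export
invert_transform <- function(t) {
  M <- solve(transform_matrix(t))
  from_matrix(M, center = t$center,
              affine = inherits(t, "affine_transform"))
}

#' Compose two spatial transforms
#'
#' Returns the transform equivalent to applying `second` first and `first`
#' to its output: `w' = first(second(w))`. In the resampling convention this
#' is what maps the final fixed grid through `second` (e.g. template-to-
#' subject affine) and then `first` (e.g. subject FLAIR-to-CT rigid).
#'
#' @param first,second Transforms or 4x4 matrices.
#' @return A 4x4 world-to-world matrix.
#' @export
compose_transforms <- function(first, second) {
  transform_matrix(first) %*% transform_matrix(second)
}

# rebuild a parametric transform from a 4x4 matrix and a rotation centre
from_matrix <- function(M, center = c(0, 0, 0), affine = FALSE) {
  A <- M[1:3, 1:3]
  if (affine) {
    s <- sqrt(colSums(A^2))
    R <- A %*% diag(1 / s)
    rot <- euler_angles(R)
    tr <- M[1:3, 4] - center + as.vector(A %*% center)
    affine_transform(rotation = rot, translation = tr, scale = s,
                     center = center)
  } else {
    rot <- euler_angles(A)
    tr <- M[1:3, 4] - center + as.vector(A %*% center)
    rigid_transform(rotation = rot, translation = tr, center = center)
  }
}

#' @export
print.spatial_transform <- function(x, ...) {
  kind <- if (inherits(x, "affine_transform")) "affine (9-DOF)" else "rigid (6-DOF)"
  cat(sprintf("<%s> rot (deg): %s  trans (mm): %s\n", kind,
              paste(sprintf("%.3f", x$rotation), collapse = ", "),
              paste(sprintf("%.3f", x$translation), collapse = ", ")))
  if (!is.null(x$scale))
    cat(sprintf("  scale: %s\n", paste(sprintf("%.4f", x$scale), collapse = ", ")))
  invisible(x)
}
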