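#' Read a NIfTI-1 volume
#'
#' Reads a 3D `.nii`/`.nii.gz` file into an [image_volume()], taking spacing
#' from the header `pixdim` and the affine from the sform (falling back to
#' the qform). If a sidecar JSON written by [write_volume()] is present its
#' recorded modality tag is used.
#'
#' @param path Path to a NIfTI-1 file.
#' @param modality Modality tag; default `"auto"` reads the sidecar JSON if
#'   present, else guesses from the data values (binary -> mask).
#' @return An `image_volume`.
#' @export
read_volume <- function(path, modality = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D in ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (identical(modality, "auto")) {
    side <- sidecar_path(path)
    if (file.exists(side)) {
      meta <- jsonlite::read_json(side)
      modality <- meta$modality %||% "flair"
    } else {
      modality <- if (all(as.vector(img) %in% c(0, 1))) "mask" else "flair"
    }
  }
  image_volume(array(as.vector(img), dim = d), spacing = spacing,
               affine = aff, modality = modality)
}

#' Write a volume as NIfTI-1 with a JSON sidecar
#'
#' Masks are written as unsigned 8-bit, probability maps as 32-bit float,
#' and intensity images as 32-bit float. A sidecar `<stem>.json` records the
#' modality tag and optional provenance (transforms applied, normalization
#' parameters).
#'
#' @param vol An `image_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param provenance Optional named list stored in the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, provenance = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  # masks: uint8; probability maps: 32-bit float; intensity images: double
  # (keeps write -> read round trips bit-exact for image data)
  datatype <- switch(vol$modality, mask = "uint8", probability = "float",
                     "double")
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  xf <- structure(vol$affine, code = 2L)
  img <- RNifti::`sform<-`(img, xf)
  img <- RNifti::`qform<-`(img, xf)
  RNifti::writeNifti(img, path, datatype = datatype)
  meta <- c(list(modality = vol$modality, spacing = vol$spacing),
            provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
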