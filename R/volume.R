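#' Construct a volume region of interest
#'
#' Couples a 3D intensity array with a binary tumor mask on the same voxel
#' grid and the voxel spacing in mm. Arrays are indexed (x, y, z) in voxel
#' space; all geometric quantities are converted to mm via `spacing`. No
#' orientation or affine resampling is performed.
#'
#' @param intensities 3D numeric array.
#' @param mask 3D array of the same shape; values > 0 mark the ROI.
#' @param spacing Numeric length-3 vector of positive voxel edge lengths (mm).
#' @return An object of class `volume_roi`.
#' @export
volume_roi <- function(intensities, mask, spacing = c(1, 1, 1)) {
  if (length(dim(intensities)) != 3L)
    abort_validation("`intensities` must be a 3D array")
  if (!identical(dim(intensities), dim(mask)))
    abort_geometry(sprintf(
      "image (%s) and mask (%s) grids differ",
      paste(dim(intensities), collapse = "x"),
      paste(dim(mask), collapse = "x")))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_validation("`spacing` must be 3 positive voxel edge lengths in mm")
  m <- array(as.integer(mask > 0), dim = dim(mask))
  if (sum(m) == 0L) abort_roi("mask is empty: no voxels in the ROI")
  structure(
    list(intensities = intensities, mask = m, spacing = spacing),
    class = "volume_roi"
  )
}

#' @export
print.volume_roi <- function(x, ...) {
  cat(sprintf("<volume_roi> grid %s, %d ROI voxels, spacing %s mm\n",
              paste(dim(x$intensities), collapse = "x"), sum(x$mask),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

roi_values <- function(roi) roi$intensities[roi$mask > 0L]

#' Read an image/mask pair from NIfTI files
#'
#' Loads a 3D image volume and a binary mask (values > 0 become 1) from
#' NIfTI files on the same grid; voxel spacing is taken from the image
#' header.
#'
#' @param image_path Path to the intensity volume (`.nii` / `.nii.gz`).
#' @param mask_path Path to the mask volume on the same grid.
#' @return A [volume_roi()].
#' @export
read_volume <- function(image_path, mask_path) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) abort_io(sprintf("file not found: %s", p))
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  volume_roi(array(as.numeric(img), dim = dim(img)),
             array(as.numeric(msk), dim = dim(msk)),
             spacing = spacing)
}
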