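#' Segment the entire cusp from the background
#'
#' Binarizes the cusp (soft tissue plus calcifications) with the configured
#' gray threshold (default range 25-255, both bounds inclusive), restricted
#' to an optional region of interest that removes the sample holder, then
#' fills small holes with a morphological closing (square of size 5 applied
#' per XY slice by default; a 3D cube is config-switchable).
#'
#' @param volume8 8-bit [image_volume()] or 3D integer array.
#' @param config a [pipeline_config()].
#' @param roi_mask optional logical array of the same shape; voxels outside
#'   it (e.g. the sample holder) are excluded before closing.
#' @return 3D logical cusp mask.
#' @export
segment_cusp <- function(volume8, config = pipeline_config(), roi_mask = NULL) {
  data <- vol_data(volume8)
  mask <- data >= config$cusp_threshold
  if (!is.null(roi_mask)) {
    check_same_shape(data, roi_mask, "roi mask")
    mask <- mask & roi_mask
  }
  off <- if (config$closing_3d) {
    k <- (config$closing_kernel - 1L) %/% 2L
    offsets_ball3d(k, "cube")
  } else {
    offsets_square2d(config$closing_kernel)
  }
  binary_close(mask, off)
}

#' Physical volume of a binary mask
#'
#' @param mask 3D logical array.
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @return Volume in mm^3: voxel count times `(voxel_size_um / 1000)^3`.
#' @examples
#' mask_volume_mm3(array(TRUE, c(10, 10, 10)), 14)
#' @export
mask_volume_mm3 <- function(mask, voxel_size_um) {
  sum(mask) * (voxel_size_um / 1000)^3
}
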