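#' Convert a 16-bit volume to 8-bit with histogram-range normalization
#'
#' Linear map sending the dataset minimum to 0 and the dataset maximum to
#' 255 (the dynamic range of the dataset), with rounding half away from
#' zero. Optionally the endpoints can be taken at robust percentiles
#' instead of the strict min/max, with values outside clipped; this is off
#' by default.
#'
#' @param volume16 an [image_volume()] (any bit depth accepted; ≥2 distinct
#'   gray values required).
#' @param percentile_clip `NULL` (strict min/max, the default) or a length-2
#'   vector of lower/upper percentiles in `[0, 100]`, e.g. `c(0.01, 99.99)`.
#' @return An 8-bit [image_volume()].
#' @export
convert_16_to_8 <- function(volume16, percentile_clip = NULL) {
  data <- vol_data(volume16)
  if (!is.null(percentile_clip)) {
    stopifnot(length(percentile_clip) == 2L, percentile_clip[1] < percentile_clip[2])
    ends <- quantile(data, probs = percentile_clip / 100, names = FALSE, type = 1)
    lo <- ends[1]; hi <- ends[2]
  } else {
    lo <- min(data); hi <- max(data)
  }
  if (hi <= lo) {
    stop("degenerate gray range: volume has fewer than 2 distinct values", call. = FALSE)
  }
  mapped <- round_half_away(255 * (as.numeric(data) - lo) / (hi - lo))
  out <- array(as.integer(clamp(mapped, 0, 255)), dim(data))
  image_volume(out, vol_voxel_um(volume16), bit_depth = 8L)
}

#' Reference anchors for cross-dataset gray normalization
#'
#' Mean gray values of the two reference materials present in every scan: a
#' borosilicate bead (high density) and the sample holder (low density).
#' These anchor the gray scale of a dataset so that different scans can be
#' mapped onto a common reference scale.
#'
#' @param holder_mean,bead_mean mean gray values of the holder and bead
#'   regions, in `[0, 255]`, `holder_mean != bead_mean`.
#' @return An object of class `reference_anchors`.
#' @export
reference_anchors <- function(holder_mean, bead_mean) {
  stopifnot(is.numeric(holder_mean), is.numeric(bead_mean),
            length(holder_mean) == 1L, length(bead_mean) == 1L)
  if (holder_mean < 0 || holder_mean > 255 || bead_mean < 0 || bead_mean > 255) {
    stop("anchor means must lie in [0, 255]", call. = FALSE)
  }
  if (holder_mean == bead_mean) {
    stop("degenerate anchors: holder and bead means are equal", call. = FALSE)
  }
  structure(list(holder_mean = holder_mean, bead_mean = bead_mean),
            class = "reference_anchors")
}

#' Measure an anchor region mean
#'
#' Arithmetic mean gray value under a region mask (e.g. a manually drawn or
#' phantom-provided bead/holder region).
#'
#' @param volume8 an [image_volume()] or 3D array.
#' @param region_mask logical array of the same shape, non-empty.
#' @return The mean gray value (numeric scalar).
#' @export
measure_anchor <- function(volume8, region_mask) {
  data <- vol_data(volume8)
  check_same_shape(data, region_mask, "region mask")
  if (!any(region_mask)) stop("empty anchor region mask", call. = FALSE)
  mean(data[region_mask])
}

#' Normalize a dataset onto a reference gray scale
#'
#' Applies the unique affine gray-value map sending the target dataset's
#' (holder, bead) anchor means onto the reference dataset's, then rounds
#' half away from zero and clamps to `[0, 255]`. Re-measuring the anchors on
#' the output reproduces the reference anchors to within one gray level.
#'
#' @param volume8 8-bit [image_volume()] to normalize.
#' @param target_anchors [reference_anchors()] measured on `volume8`.
#' @param ref_anchors [reference_anchors()] of the reference dataset.
#' @return The normalized 8-bit [image_volume()].
#' @export
normalize_to_reference <- function(volume8, target_anchors, ref_anchors) {
  stopifnot(inherits(target_anchors, "reference_anchors"),
            inherits(ref_anchors, "reference_anchors"))
  data <- vol_data(volume8)
  slope <- (ref_anchors$bead_mean - ref_anchors$holder_mean) /
    (target_anchors$bead_mean - target_anchors$holder_mean)
  mapped <- ref_anchors$holder_mean +
    slope * (as.numeric(data) - target_anchors$holder_mean)
  out <- array(as.integer(clamp(round_half_away(mapped), 0, 255)), dim(data))
  image_volume(out, vol_voxel_um(volume8), bit_depth = 8L)
}
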