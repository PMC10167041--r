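#' Pipeline configuration
#'
#' Every numeric parameter of the analysis protocol in one auditable
#' record. Defaults are the protocol values: cusp binarization threshold 25
#' (range 25-255, inclusive), density-class lower bounds 75/139/197
#' (low/moderate/high), a 5x5 slice-wise closing to fill small holes in the
#' cusp, a 2x2 slice-wise opening on the moderate/low density selections, a
#' 2-voxel exclusion dilation of the high-density class and a 1-voxel
#' compensation dilation of every class, removal of particles of 10 voxels
#' or fewer, size-class boundaries 1e-3 and 1 mm^3, a 0.7 mm "healthy
#' thickness" threshold and 26-neighbourhood particle connectivity.
#'
#' `dilation_kernel` selects the 3D structuring element used for the
#' "dilate by k voxels" steps: `"ball"` (Euclidean ball of radius k; for
#' k = 1 the 6-neighbour cross) or `"cube"` (k iterations of the 3x3x3
#' cube, i.e. the Chebyshev ball). The ball is the default because the
#' partial-volume erosion it compensates is isotropic; the cube inflates a
#' compensated sphere by about 1.5 voxels of radius and overshoots the true
#' volume for blur-scale inclusions. `closing_3d` switches the cusp closing
#' from the default slice-wise square to a 3D cube.
#'
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param cusp_threshold gray-value lower bound of the cusp (soft tissue +
#'   calcification).
#' @param calc_threshold_low,calc_threshold_mid,calc_threshold_high lower
#'   gray bounds of the low/moderate/high density classes.
#' @param closing_kernel edge length (odd) of the square closing kernel.
#' @param opening_kernel edge length of the square opening kernel.
#' @param hd_dilation_voxels exclusion dilation radius of the high-density
#'   class before re-segmenting moderate/low densities.
#' @param compensation_dilation_voxels final per-class compensation dilation
#'   radius.
#' @param min_particle_voxels particles with at most this many voxels are
#'   discarded.
#' @param size_bounds_mm3 micro/meso and meso/macro volume boundaries (mm^3).
#' @param thin_threshold_mm thickness below which cusp volume counts as
#'   "normal thickness".
#' @param connectivity particle adjacency rule, 6 or 26.
#' @param dilation_kernel `"ball"` or `"cube"` (see Details).
#' @param closing_3d logical; close the cusp with a 3D cube instead of the
#'   slice-wise square.
#' @param percentile_clip passed to [convert_16_to_8()]; `NULL` keeps the
#'   strict min/max dynamic range.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(voxel_size_um = 14,
                            cusp_threshold = 25L,
                            calc_threshold_low = 75L,
                            calc_threshold_mid = 139L,
                            calc_threshold_high = 197L,
                            closing_kernel = 5L,
                            opening_kernel = 2L,
                            hd_dilation_voxels = 2L,
                            compensation_dilation_voxels = 1L,
                            min_particle_voxels = 10L,
                            size_bounds_mm3 = c(1e-3, 1),
                            thin_threshold_mm = 0.7,
                            connectivity = 26L,
                            dilation_kernel = c("ball", "cube"),
                            closing_3d = FALSE,
                            percentile_clip = NULL) {
  cfg <- list(
    voxel_size_um = as.numeric(voxel_size_um),
    cusp_threshold = as.integer(cusp_threshold),
    calc_threshold_low = as.integer(calc_threshold_low),
    calc_threshold_mid = as.integer(calc_threshold_mid),
    calc_threshold_high = as.integer(calc_threshold_high),
    closing_kernel = as.integer(closing_kernel),
    opening_kernel = as.integer(opening_kernel),
    hd_dilation_voxels = as.integer(hd_dilation_voxels),
    compensation_dilation_voxels = as.integer(compensation_dilation_voxels),
    min_particle_voxels = as.integer(min_particle_voxels),
    size_bounds_mm3 = as.numeric(size_bounds_mm3),
    thin_threshold_mm = as.numeric(thin_threshold_mm),
    connectivity = as.integer(connectivity),
    dilation_kernel = match.arg(dilation_kernel),
    closing_3d = isTRUE(closing_3d),
    percentile_clip = percentile_clip
  )
  with(cfg, {
    if (!(0 < cusp_threshold && cusp_threshold < calc_threshold_low &&
          calc_threshold_low < calc_threshold_mid &&
          calc_threshold_mid < calc_threshold_high && calc_threshold_high <= 255)) {
      stop("thresholds must satisfy 0 < cusp < low < mid < high <= 255", call. = FALSE)
    }
    if (length(size_bounds_mm3) != 2L || diff(size_bounds_mm3) <= 0) {
      stop("`size_bounds_mm3` must be strictly increasing", call. = FALSE)
    }
    if (closing_kernel < 1L || closing_kernel %% 2L == 0L) {
      stop("`closing_kernel` must be odd and >= 1", call. = FALSE)
    }
    if (opening_kernel < 1L) stop("`opening_kernel` must be >= 1", call. = FALSE)
    if (!connectivity %in% c(6L, 26L)) stop("`connectivity` must be 6 or 26", call. = FALSE)
    if (voxel_size_um <= 0) stop("`voxel_size_um` must be positive", call. = FALSE)
  })
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(val)) "NULL" else paste(format(val), collapse = ", ")))
  }
  invisible(x)
}
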