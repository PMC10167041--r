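#' Label connected calcified particles
#'
#' A calcified particle is a maximal set of mutually connected
#' calcification voxels (no distinction of density). Components are found
#' under the configured adjacency (26-neighbourhood by default, i.e. face,
#' edge and corner contacts; 6 restricts to face contacts) and labelled
#' 1..K in raster-scan order of each component's first voxel.
#'
#' @param calc_mask 3D logical mask.
#' @param connectivity 6 or 26.
#' @return 3D integer label array (0 = background).
#' @export
label_particles <- function(calc_mask, connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("`connectivity` must be 6 or 26", call. = FALSE)
  if (!is.logical(calc_mask) || length(dim(calc_mask)) != 3L) {
    stop("`calc_mask` must be a 3D logical array", call. = FALSE)
  }
  labels <- label_cc_3d(calc_mask, dim(calc_mask), connectivity)
  dim(labels) <- dim(calc_mask)
  labels
}

#' Remove small particles
#'
#' Particles of `min_particle_voxels` voxels or fewer (default 10) are not
#' considered; remaining labels are recompacted to 1..K' preserving their
#' raster order.
#'
#' @param labels 3D integer label array from [label_particles()].
#' @param min_particle_voxels particles with voxel count `<=` this are
#'   dropped.
#' @return Filtered, recompacted 3D integer label array.
#' @export
filter_small <- function(labels, min_particle_voxels = 10L) {
  k <- max(labels)
  if (k == 0L) return(labels)
  counts <- tabulate(labels[labels > 0L], nbins = k)
  keep <- counts > min_particle_voxels
  remap <- integer(k + 1L)
  remap[which(keep) + 1L] <- seq_len(sum(keep))
  out <- remap[labels + 1L]
  dim(out) <- dim(labels)
  out
}

#' Particle morphometry
#'
#' Per-particle volumes and the three-tier size classification: microscale
#' particles have a volume below or equal to 1e-3 mm^3, macroscale
#' particles 1 mm^3 or above, and mesoscale particles lie strictly in
#' between. Sample-level summaries follow: particle count per class,
#' largest particle volume and its share of the total calcification
#' volume, and particles per mm^3 of entire-cusp volume.
#'
#' @param labels filtered 3D integer label array (see [filter_small()]).
#' @param cusp_volume_mm3 entire-cusp volume in mm^3 (> 0), the per-sample
#'   normalizer for particle density.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param config a [pipeline_config()] (size-class boundaries).
#' @return An object of class `particle_table`: data frame `particles`
#'   (id, voxel_count, volume_mm3, size_class) and list `summary`
#'   (n_particles, n_micro, n_meso, n_macro, largest_volume_mm3,
#'   largest_fraction, particles_per_mm3, total_volume_mm3, plus the class
#'   boundaries expressed in voxels for auditability).
#' @export
particle_metrics <- function(labels, cusp_volume_mm3, voxel_size_um,
                             config = pipeline_config()) {
  if (!is.numeric(cusp_volume_mm3) || cusp_volume_mm3 <= 0) {
    stop("`cusp_volume_mm3` must be positive", call. = FALSE)
  }
  vox_mm3 <- (voxel_size_um / 1000)^3
  k <- max(labels)
  counts <- if (k > 0L) tabulate(labels[labels > 0L], nbins = k) else integer(0)
  vols <- counts * vox_mm3
  lo <- config$size_bounds_mm3[1]
  hi <- config$size_bounds_mm3[2]
  # micro closed above, macro closed below; the 1e-9 relative guard keeps
  # volumes that are exactly on a boundary (up to the float error of the
  # cubed voxel size) on the closed side
  cls <- ifelse(vols <= lo * (1 + 1e-9), "micro",
                ifelse(vols >= hi * (1 - 1e-9), "macro", "meso"))
  particles <- data.frame(id = seq_len(k), voxel_count = counts,
                          volume_mm3 = vols,
                          size_class = factor(cls, levels = c("micro", "meso", "macro")))
  total <- sum(vols)
  summary <- list(
    n_particles = k,
    n_micro = sum(cls == "micro"),
    n_meso = sum(cls == "meso"),
    n_macro = sum(cls == "macro"),
    largest_volume_mm3 = if (k > 0L) max(vols) else 0,
    largest_fraction = if (total > 0) max(vols) / total else NA_real_,
    particles_per_mm3 = k / cusp_volume_mm3,
    total_volume_mm3 = total,
    micro_bound_voxels = lo / vox_mm3,
    macro_bound_voxels = hi / vox_mm3
  )
  structure(list(particles = particles, summary = summary),
            class = "particle_table")
}

#' @export
print.particle_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<particle_table> %d particles (micro %d / meso %d / macro %d)\n",
              s$n_particles, s$n_micro, s$n_meso, s$n_macro))
  cat(sprintf("  largest %.4g mm^3 (%.1f%% of calcification), %.3g particles/mm^3\n",
              s$largest_volume_mm3, 100 * s$largest_fraction, s$particles_per_mm3))
  invisible(x)
}
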