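#' 3D grayscale image volume
#'
#' Container for an isotropic 3D voxel grid of gray values, the raw material
#' of every pipeline stage. Slices are XY planes stacked along the third
#' array dimension (Z). Gray values are integers within the declared bit
#' depth (8-bit after conversion; 16-bit is allowed at ingest, as produced
#' by CT reconstruction).
#'
#' @param data 3D integer array of gray values.
#' @param voxel_size_um physical edge length of one (isotropic) voxel, in
#'   micrometres. All three dimensions share this size; anisotropic voxels
#'   are rejected.
#' @param bit_depth 8 or 16.
#' @return An object of class `image_volume` with fields `data`,
#'   `voxel_size_um` and `bit_depth`.
#' @examples
#' v <- image_volume(array(7L, c(4, 4, 3)), voxel_size_um = 14)
#' dim(v$data)
#' @export
image_volume <- function(data, voxel_size_um, bit_depth = 8L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (length(data) == 0L) stop("volume must be non-empty", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a single positive number", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  storage.mode(data) <- "integer"
  vmax <- if (bit_depth == 8L) 255L else 65535L
  rng <- range(data)
  if (rng[1] < 0L || rng[2] > vmax) {
    stop(sprintf("gray values outside [0, %d] for declared %d-bit depth", vmax, bit_depth),
         call. = FALSE)
  }
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 bit_depth = bit_depth),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, %d-bit, %.3g um/voxel\n",
              d[1], d[2], d[3], x$bit_depth, x$voxel_size_um))
  cat(sprintf("  gray range [%d, %d]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

# Accept either an image_volume or a bare 3D array; returns the integer array.
vol_data <- function(volume) {
  if (inherits(volume, "image_volume")) return(volume$data)
  if (is.array(volume) && length(dim(volume)) == 3L) return(volume)
  stop("expected an `image_volume` or a 3D array", call. = FALSE)
}

vol_voxel_um <- function(volume, voxel_size_um = NULL) {
  if (!is.null(voxel_size_um)) return(as.numeric(voxel_size_um))
  if (inherits(volume, "image_volume")) return(volume$voxel_size_um)
  stop("`voxel_size_um` must be given when the input is a bare array", call. = FALSE)
}

check_same_shape <- function(a, b, what = "mask") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s shape %s does not match volume shape %s", what,
                 paste(dim(b), collapse = "x"), paste(dim(a), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Round half away from zero; used everywhere gray values are quantized.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
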