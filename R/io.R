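#' Read a slice stack into a 3D volume
#'
#' Reads a directory of single-channel grayscale slice images (16-bit TIFF as
#' exported by the reconstruction software, or 8-bit TIFF/PNG) and stacks
#' them along Z. Slice order is given by the lexicographic sort of the file
#' names, which is how reconstruction exports are numbered.
#'
#' @param directory_path directory containing the slice images.
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @return An [image_volume()]; Z index follows sorted file name order.
#' @seealso [write_stack()]
#' @export
read_stack <- function(directory_path, voxel_size_um) {
  if (!dir.exists(directory_path)) {
    stop(sprintf("directory not found: %s", directory_path), call. = FALSE)
  }
  files <- list.files(directory_path, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) {
    stop(sprintf("no slice images (.tif/.tiff/.png) in %s", directory_path),
         call. = FALSE)
  }
  files <- files[order(basename(files), method = "radix")]
  slices <- lapply(files, read_slice)
  dims <- vapply(slices, function(s) dim(s$data), integer(2))
  depths <- vapply(slices, function(s) s$bits, integer(1))
  if (length(unique(depths)) != 1L) {
    stop("mixed bit depths across slices", call. = FALSE)
  }
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("mixed slice dimensions", call. = FALSE)
  }
  data <- array(0L, c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]]$data
  image_volume(data, voxel_size_um, bit_depth = depths[1])
}

read_slice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  } else {
    img <- png::readPNG(path)
    bits <- 8L
    img <- as.integer(round_half_away(img * 255))
    dim(img) <- dim(png::readPNG(path))[1:2]
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) stop(sprintf("%s is not single-channel", path), call. = FALSE)
    img <- img[, , 1]
  }
  m <- as.integer(img)
  dim(m) <- dim(img)
  list(data = m, bits = as.integer(bits))
}

#' Write a volume or mask as a slice stack
#'
#' Writes one file per Z slice with zero-padded numeric suffixes, so that a
#' lexicographic sort restores the original order. 8-bit and 16-bit volumes
#' are stored losslessly; binary masks are stored as 8-bit stacks with
#' values 0/255.
#'
#' @param volume an [image_volume()], a 3D integer array (treated with the
#'   given `bit_depth`), or a 3D logical mask.
#' @param directory_path output directory (created if missing).
#' @param prefix file name prefix.
#' @param bit_depth used when `volume` is a bare integer array.
#' @return Invisibly, the vector of file paths written.
#' @export
write_stack <- function(volume, directory_path, prefix = "slice", bit_depth = 8L) {
  if (is.array(volume) && is.logical(volume)) {
    data <- array(ifelse(volume, 255L, 0L), dim(volume))
    bits <- 8L
  } else if (inherits(volume, "image_volume")) {
    data <- volume$data
    bits <- volume$bit_depth
  } else {
    data <- vol_data(volume)
    bits <- as.integer(bit_depth)
  }
  if (!dir.exists(directory_path)) dir.create(directory_path, recursive = TRUE)
  vmax <- if (bits == 8L) 255 else 65535
  nz <- dim(data)[3]
  width <- max(4L, nchar(as.character(nz)))
  paths <- file.path(directory_path,
                     sprintf("%s_%0*d.tif", prefix, width, seq_len(nz)))
  for (k in seq_len(nz)) {
    tiff::writeTIFF(data[, , k] / vmax, paths[k], bits.per.sample = bits,
                    compression = "none")
  }
  invisible(paths)
}

#' Persist a thickness map as a float slice stack
#'
#' Local thickness values (mm) are stored as 32-bit float TIFF slices
#' normalised to `[0, 1]` together with a JSON sidecar holding the scale
#' factor, because TIFF float samples are clamped to that range by the
#' writer. [read_thickness_stack()] restores the mm values.
#'
#' @param map a `thickness_map` from [local_thickness()].
#' @param directory_path output directory.
#' @return Invisibly, the sidecar path.
#' @export
write_thickness_stack <- function(map, directory_path) {
  stopifnot(inherits(map, "thickness_map"))
  if (!dir.exists(directory_path)) dir.create(directory_path, recursive = TRUE)
  scale_mm <- max(map$data, 1e-12)
  nz <- dim(map$data)[3]
  width <- max(4L, nchar(as.character(nz)))
  for (k in seq_len(nz)) {
    tiff::writeTIFF(map$data[, , k] / scale_mm,
                    file.path(directory_path, sprintf("thickness_%0*d.tif", width, k)),
                    bits.per.sample = 32L, compression = "none")
  }
  sidecar <- file.path(directory_path, "thickness_scale.json")
  jsonlite::write_json(list(scale_mm = scale_mm, voxel_size_um = map$voxel_size_um),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_thickness_stack
#' @export
read_thickness_stack <- function(directory_path) {
  sidecar <- jsonlite::read_json(file.path(directory_path, "thickness_scale.json"))
  files <- sort(list.files(directory_path, pattern = "^thickness_.*\\.tif$",
                           full.names = TRUE))
  slices <- lapply(files, function(f) tiff::readTIFF(f))
  data <- array(0, c(dim(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]] * sidecar$scale_mm
  structure(list(data = data, voxel_size_um = sidecar$voxel_size_um),
            class = "thickness_map")
}
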