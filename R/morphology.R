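# Binary morphology on 3D logical arrays, implemented as shift-based set
# operations. Kernels are given as integer offset matrices (n x 3). Slice-wise
# 2D kernels are offsets with dz = 0. Erosion and dilation use the standard
# adjoint convention, so opening/closing with the same (possibly even,
# top-left anchored) structuring element are translation-consistent and
# idempotent.

shift_mask <- function(m, d) {
  dm <- dim(m)
  out <- array(FALSE, dm)
  idx_dst <- idx_src <- vector("list", 3L)
  for (a in 1:3) {
    if (abs(d[a]) >= dm[a]) return(out)
    if (d[a] >= 0) {
      idx_dst[[a]] <- seq.int(d[a] + 1L, dm[a])
      idx_src[[a]] <- seq.int(1L, dm[a] - d[a])
    } else {
      idx_dst[[a]] <- seq.int(1L, dm[a] + d[a])
      idx_src[[a]] <- seq.int(1L - d[a], dm[a])
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Square 2D kernel applied per XY slice. Odd sizes are centred; even sizes
# are anchored at the top-left voxel of the kernel footprint.
offsets_square2d <- function(size) {
  r <- if (size %% 2L == 1L) -(size - 1L) %/% 2L + seq_len(size) - 1L else seq_len(size) - 1L
  as.matrix(expand.grid(dx = r, dy = r, dz = 0L))
}

# 3D ball (Euclidean, radius k) or cube (Chebyshev, radius k) offsets.
offsets_ball3d <- function(k, kernel = c("ball", "cube")) {
  kernel <- match.arg(kernel)
  r <- -k:k
  g <- as.matrix(expand.grid(dx = r, dy = r, dz = r))
  if (kernel == "ball") g[rowSums(g^2) <= k^2, , drop = FALSE] else g
}

#' Binary dilation / erosion / opening / closing
#'
#' Low-level morphology used by the segmentation protocol. `offsets` is an
#' integer matrix of structuring-element offsets (columns dx, dy, dz);
#' helpers for the protocol kernels are selected through
#' [pipeline_config()]. Voxels outside the array are background.
#'
#' @param mask 3D logical array.
#' @param offsets n x 3 integer matrix of structuring-element offsets.
#' @return 3D logical array of the same shape.
#' @keywords internal
#' @export
binary_dilate <- function(mask, offsets) {
  storage.mode(offsets) <- "integer"
  out <- morph_3d(mask, dim(mask), offsets, TRUE)
  dim(out) <- dim(mask)
  out
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, offsets) {
  storage.mode(offsets) <- "integer"
  out <- morph_3d(mask, dim(mask), offsets, FALSE)
  dim(out) <- dim(mask)
  out
}

#' @rdname binary_dilate
#' @export
binary_open <- function(mask, offsets) binary_dilate(binary_erode(mask, offsets), offsets)

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, offsets) {
  # computed on a padded array so that closing is extensive (mask voxels at
  # the array border are never removed), matching the unbounded-domain
  # definition exactly: no offset reaches beyond the padding
  r <- max(abs(offsets))
  dm <- dim(mask)
  padded <- array(FALSE, dm + 2L * r)
  padded[r + seq_len(dm[1]), r + seq_len(dm[2]), r + seq_len(dm[3])] <- mask
  closed <- binary_erode(binary_dilate(padded, offsets), offsets)
  closed[r + seq_len(dm[1]), r + seq_len(dm[2]), r + seq_len(dm[3]), drop = FALSE]
}

# Protocol dilation "by k voxels" with the configured 3D kernel.
dilate_by_voxels <- function(mask, k, kernel = "ball") {
  if (k <= 0L) return(mask)
  if (kernel == "cube") {
    for (i in seq_len(k)) mask <- binary_dilate(mask, offsets_ball3d(1L, "cube"))
    mask
  } else {
    binary_dilate(mask, offsets_ball3d(k, "ball"))
  }
}
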