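#' Gray-value histogram of a volume
#'
#' Counts over the 8-bit gray range, optionally restricted to a mask (the
#' density thresholds are computed over cusp voxels only, so that the
#' background does not dominate the class variance).
#'
#' @param volume8 8-bit [image_volume()] or 3D integer array.
#' @param mask optional logical array of the same shape.
#' @return Integer vector of length 256, named "0".."255".
#' @export
gray_histogram <- function(volume8, mask = NULL) {
  data <- vol_data(volume8)
  if (!is.null(mask)) {
    check_same_shape(data, mask)
    data <- data[mask]
  }
  counts <- tabulate(as.integer(data) + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}

#' Multilevel Otsu threshold selection
#'
#' Selects `n_thresholds` gray values maximizing the between-class variance
#' of the resulting `n_thresholds + 1` classes. A threshold `t` is the first
#' gray value of its upper class, so the classes are
#' `[0, t1), [t1, t2), ..., [tn, 255]`; with the default three thresholds
#' these are soft tissue and the low/moderate/high density strata. The
#' search is exhaustive over all increasing threshold tuples; ties are
#' broken by the lexicographically smallest tuple.
#'
#' @param gray_histogram integer vector of 256 gray-value counts (see
#'   [gray_histogram()]), with at least `n_thresholds + 1` occupied bins.
#' @param n_thresholds number of thresholds (1 to 3; the protocol uses 3).
#' @return Integer vector of thresholds in increasing order, with the
#'   maximized between-class criterion in attribute `"criterion"`.
#' @export
multilevel_otsu <- function(gray_histogram, n_thresholds = 3L) {
  counts <- as.numeric(gray_histogram)
  if (length(counts) != 256L || any(counts < 0) || any(!is.finite(counts))) {
    stop("`gray_histogram` must be 256 non-negative counts", call. = FALSE)
  }
  n_thresholds <- as.integer(n_thresholds)
  if (!n_thresholds %in% 1:3) stop("`n_thresholds` must be 1, 2 or 3", call. = FALSE)
  if (sum(counts > 0) < n_thresholds + 1L) {
    stop("degenerate histogram: fewer occupied bins than classes", call. = FALSE)
  }
  CW <- c(0, cumsum(counts))
  CM <- c(0, cumsum(counts * (0:255)))
  # Between-class contribution of the class covering grays i..j-1 (0-based).
  S <- function(i, j) {
    w <- CW[j + 1L] - CW[i + 1L]
    m <- CM[j + 1L] - CM[i + 1L]
    ifelse(w > 0, m * m / w, 0)
  }

  if (n_thresholds == 1L) {
    t1 <- 1:255
    sc <- S(0L, t1) + S(t1, 256L)
    best <- which.max(sc)
    res <- t1[best]
    crit <- sc[best]
  } else if (n_thresholds == 2L) {
    grid <- expand.grid(t2 = 2:255, t1 = 1:254)  # t1-major lexicographic below
    grid <- grid[grid$t2 > grid$t1, ]
    grid <- grid[order(grid$t1, grid$t2), ]
    sc <- S(0L, grid$t1) + S(grid$t1, grid$t2) + S(grid$t2, 256L)
    best <- which.max(sc)
    res <- c(grid$t1[best], grid$t2[best])
    crit <- sc[best]
  } else {
    # Enumerate (t2, t3) pairs once, lexicographically; scan t1 ascending.
    t2 <- rep.int(2:254, 253:1)
    t3 <- unlist(lapply(2:254, function(b) (b + 1L):255L), use.names = FALSE)
    tail_sc <- S(t2, t3) + S(t3, 256L)
    # First pair index whose t2 exceeds a given t1 (pairs are t2-major).
    start_at <- c(1L, cumsum(253:1) + 1L)  # start_at[t1] for t1 = 1..253
    crit <- -Inf
    res <- NULL
    for (t1 in 1:253) {
      i0 <- start_at[t1]
      idx <- i0:length(t2)
      sc <- S(0L, t1) + S(t1, t2[idx]) + tail_sc[idx]
      b <- which.max(sc)
      if (sc[b] > crit) {
        crit <- sc[b]
        res <- c(t1, t2[idx[b]], t3[idx[b]])
      }
    }
  }
  res <- as.integer(res)
  attr(res, "criterion") <- crit - (CM[257] ^ 2) / max(CW[257], 1)
  res
}

#' Pool per-sample thresholds
#'
#' Component-wise arithmetic mean of the per-sample multilevel thresholds
#' (rounded half away from zero), applied to all samples so that every
#' dataset is segmented with the same gray bounds; the component-wise
#' standard deviation is reported alongside.
#'
#' @param per_sample_thresholds a list of equal-length threshold vectors or
#'   a matrix with one row per sample.
#' @return A list with `mean` (integer vector) and `sd` (numeric vector).
#' @examples
#' pooled_thresholds(list(c(74, 138, 196), c(76, 140, 198)))
#' @export
pooled_thresholds <- function(per_sample_thresholds) {
  if (is.list(per_sample_thresholds)) {
    if (length(per_sample_thresholds) == 0L) stop("no threshold samples", call. = FALSE)
    lens <- lengths(per_sample_thresholds)
    if (length(unique(lens)) != 1L) stop("threshold tuples differ in length", call. = FALSE)
    m <- do.call(rbind, per_sample_thresholds)
  } else {
    m <- as.matrix(per_sample_thresholds)
  }
  if (nrow(m) == 0L) stop("no threshold samples", call. = FALSE)
  mu <- as.integer(round_half_away(colMeans(m)))
  if (ncol(m) > 1L && any(diff(mu) <= 0)) {
    stop("pooled thresholds are not strictly increasing", call. = FALSE)
  }
  s <- if (nrow(m) > 1L) apply(m, 2L, sd) else rep(0, ncol(m))
  list(mean = mu, sd = s)
}
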