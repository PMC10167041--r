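# Independent brute-force oracles used to verify the package's optimized
# implementations. They share no code with the implementation paths beyond
# base R.

# --- Otsu ------------------------------------------------------------------

# Normalized between-class variance for a given threshold tuple, computed
# from first principles (class weights and means).
oracle_between_class <- function(counts, thresholds) {
  bounds <- c(0L, as.integer(thresholds), 256L)
  g <- 0:255
  n <- sum(counts)
  mu_t <- sum(counts * g) / n
  s <- 0
  for (k in seq_len(length(bounds) - 1L)) {
    sel <- g >= bounds[k] & g < bounds[k + 1L]
    w <- sum(counts[sel])
    if (w > 0) {
      mu <- sum(counts[sel] * g[sel]) / w
      s <- s + (w / n) * (mu - mu_t)^2
    }
  }
  s
}

# Exhaustive single-threshold search, fully naive.
oracle_otsu1 <- function(counts) {
  best <- -Inf; best_t <- NA_integer_
  for (t in 1:255) {
    v <- oracle_between_class(counts, t)
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}

# Exhaustive three-threshold search. Enumerates every increasing triple in
# lexicographic order; weights/means come from cumulative moments but the
# score is the normalized sigma_B^2 (a different algebraic path than the
# implementation's unnormalized sum of M^2/W).
oracle_otsu3 <- function(counts) {
  counts <- as.numeric(counts)
  g <- 0:255
  n <- sum(counts)
  mu_t <- sum(counts * g) / n
  CW <- c(0, cumsum(counts))
  CM <- c(0, cumsum(counts * g))
  cls <- function(i, j) {  # grays i..j-1
    w <- CW[j + 1L] - CW[i + 1L]
    m <- CM[j + 1L] - CM[i + 1L]
    ifelse(w > 0, (w / n) * (m / w - mu_t)^2, 0)
  }
  t2 <- rep.int(2:254, 253:1)
  t3 <- unlist(lapply(2:254, function(b) (b + 1L):255L), use.names = FALSE)
  tail_sc <- cls(t2, t3) + cls(t3, 256L)
  start_at <- c(1L, cumsum(253:1) + 1L)
  best <- -Inf; best_t <- NULL
  for (t1 in 1:253) {
    idx <- start_at[t1]:length(t2)
    sc <- cls(0L, t1) + cls(t1, t2[idx]) + tail_sc[idx]
    b <- which.max(sc)
    if (sc[b] > best) { best <- sc[b]; best_t <- c(t1, t2[idx[b]], t3[idx[b]]) }
  }
  best_t
}

random_histogram <- function() {
  counts <- numeric(256)
  n_spikes <- sample(4:10, 1)
  pos <- sample(0:255, n_spikes)
  counts[pos + 1] <- sample(50:5000, n_spikes, replace = TRUE)
  if (runif(1) < 0.5) {
    # add a broad noise floor over a random window
    a <- sample(0:200, 1); b <- a + sample(20:55, 1)
    counts[(a:b) + 1] <- counts[(a:b) + 1] + sample(0:30, b - a + 1, replace = TRUE)
  }
  counts
}

# --- Connected components --------------------------------------------------

# Fixpoint label propagation: every foreground voxel starts with its own
# linear index; iteratively take the minimum over the neighbourhood until
# stable; then rename labels in order of first appearance (raster order).
oracle_label <- function(mask, connectivity) {
  dm <- dim(mask)
  lab <- array(NA_real_, dm)
  lab[mask] <- which(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  shift_arr <- function(a, d) {
    out <- array(Inf, dm)
    src <- dst <- vector("list", 3)
    for (ax in 1:3) {
      if (abs(d[ax]) >= dm[ax]) return(out)
      if (d[ax] >= 0) { dst[[ax]] <- (1 + d[ax]):dm[ax]; src[[ax]] <- 1:(dm[ax] - d[ax]) }
      else { dst[[ax]] <- 1:(dm[ax] + d[ax]); src[[ax]] <- (1 - d[ax]):dm[ax] }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  work <- lab
  work[is.na(work)] <- Inf
  repeat {
    new <- work
    for (i in seq_len(nrow(offs))) {
      new <- pmin(new, shift_arr(work, offs[i, ]))
    }
    new[!mask] <- Inf
    if (identical(new, work)) break
    work <- new
  }
  roots <- work[mask]
  ids <- match(roots, unique(roots))  # first appearance in raster order
  out <- array(0L, dm)
  out[mask] <- ids
  out
}

random_mask <- function(max_dim = 40L) {
  dm <- sample(5:max_dim, 3, replace = TRUE)
  p <- runif(1, 0.05, 0.55)
  array(runif(prod(dm)) < p, dm)
}

# --- Thickness -------------------------------------------------------------

# Brute-force EDT: for every foreground voxel, the minimum distance to any
# in-array background voxel or to the nearest out-of-array voxel centre.
oracle_edt <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  d <- rep(Inf, nrow(idx))
  if (nrow(bg) > 0) {
    for (i in seq_len(nrow(idx))) {
      d[i] <- sqrt(min((bg[, 1] - idx[i, 1])^2 + (bg[, 2] - idx[i, 2])^2 +
                         (bg[, 3] - idx[i, 3])^2))
    }
  }
  border <- pmin(idx[, 1], dm[1] + 1 - idx[, 1],
                 idx[, 2], dm[2] + 1 - idx[, 2],
                 idx[, 3], dm[3] + 1 - idx[, 3])
  pmin(d, border)
}

# Brute-force largest-inscribed-sphere thickness under the package's
# normative convention: sphere at q has radius EDT(q) - 1/2 and covers p
# iff |p - q| <= EDT(q); thickness is the diameter of the largest covering
# sphere.
oracle_thickness <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  r <- oracle_edt(mask)
  th <- rep(0, nrow(idx))
  for (j in seq_len(nrow(idx))) {
    d2 <- (idx[, 1] - idx[j, 1])^2 + (idx[, 2] - idx[j, 2])^2 +
      (idx[, 3] - idx[j, 3])^2
    covered <- d2 <= r[j]^2 + 1e-9
    val <- 2 * (r[j] - 0.5)
    th[covered] <- pmax(th[covered], val)
  }
  out <- array(0, dm)
  out[mask] <- th
  out
}

# Digital ball of a given diameter (voxel centre within radius d/2).
digital_ball <- function(diameter, pad = 4L) {
  R <- diameter / 2
  n <- 2L * (ceiling(R) + pad) + 1L
  c0 <- (n + 1) / 2
  x <- seq_len(n) - c0
  d2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  array(d2 <= R^2 + 1e-9, c(n, n, n))
}

# Random blob masks (thresholded smoothed noise) for structured test cases.
random_blob_mask <- function(dim3, smooth = 2L, level = 0.6) {
  a <- array(runif(prod(dim3)), dim3)
  for (i in seq_len(smooth)) {
    a <- (a +
            a[c(1, seq_len(dim3[1] - 1)), , ] + a[c(seq_len(dim3[1] - 1) + 1, dim3[1]), , ] +
            a[, c(1, seq_len(dim3[2] - 1)), ] + a[, c(seq_len(dim3[2] - 1) + 1, dim3[2]), ] +
            a[, , c(1, seq_len(dim3[3] - 1))] + a[, , c(seq_len(dim3[3] - 1) + 1, dim3[3])]) / 7
  }
  a > quantile(a, level)
}

# --- misc ------------------------------------------------------------------

# Small fast phantom for unit tests: same physical geometry on a coarser
# 100 um grid.
small_phantom_spec <- function(seed, ...) {
  phantom_spec(shape = c(96L, 96L, 48L), voxel_size_um = 100, seed = seed, ...)
}

rotations_90 <- list(
  function(m) aperm(m, c(2, 1, 3))[dim(m)[2]:1, , , drop = FALSE],  # 90 deg about z
  function(m) aperm(m, c(1, 3, 2))[, dim(m)[3]:1, , drop = FALSE],  # 90 deg about x
  function(m) aperm(m, c(3, 2, 1))[, , dim(m)[1]:1, drop = FALSE]   # 90 deg about y
)

translate_mask <- function(mask, pad = c(2L, 3L, 1L)) {
  dm <- dim(mask)
  out <- array(FALSE, dm + 2L * pad)
  out[pad[1] + seq_len(dm[1]), pad[2] + seq_len(dm[2]), pad[3] + seq_len(dm[3])] <- mask
  out
}
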