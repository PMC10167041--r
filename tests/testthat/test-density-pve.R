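cfg14 <- pipeline_config(voxel_size_um = 14)

test_that("calcification segmentation uses the inclusive 75-255 band inside the cusp", {
  v <- array(60L, c(6, 6, 2))
  v[2, 2, 1] <- 80L
  v[3, 3, 1] <- 75L
  v[4, 4, 1] <- 250L
  cusp <- array(TRUE, dim(v)); cusp[4, 4, 1] <- FALSE
  m <- segment_calcification(v, cusp, cfg14)
  expect_true(m[2, 2, 1])
  expect_true(m[3, 3, 1])        # bound inclusive
  expect_false(m[4, 4, 1])       # outside the cusp mask
  expect_equal(sum(m), 2)
})

test_that("volume fraction is |calc| / |cusp| with the documented edge cases", {
  cusp <- array(TRUE, c(4, 4, 4))
  expect_equal(calc_volume_fraction(cusp, cusp), 1)
  expect_equal(calc_volume_fraction(array(FALSE, dim(cusp)), cusp), 0)
  expect_error(calc_volume_fraction(cusp, array(FALSE, dim(cusp))), "empty cusp")
})

test_that("an undegraded phantom yields the ground-truth volume fraction exactly", {
  sp <- small_phantom_spec(seed = 5, psf_sigma_voxels = 0, noise_sigma = 0)
  ph <- generate_phantom(sp)
  g <- sp$gray
  calc16 <- (ph$volume$data >= g$ld * 257L) & ph$truth$cusp_mask
  expect_equal(calc_volume_fraction(calc16, ph$truth$cusp_mask),
               ph$truth$calc_fraction)
})

test_that("the PVE protocol decomposes an unblurred single-density block exactly", {
  v <- array(40L, c(15, 15, 15))
  v[7:9, 7:9, 7:9] <- 220L
  cusp <- v >= 25L
  res <- pve_decompose(v, cusp, pipeline_config(voxel_size_um = 14,
                                                dilation_kernel = "ball"))
  # ball (6-neighbour) compensation: 27 + 6 faces * 9 voxels
  expect_equal(sum(res$hd), 81)
  expect_equal(sum(res$md), 0)
  expect_equal(sum(res$ld), 0)
  expect_equal(res$direct_volume_mm3, 27 * (14 / 1000)^3)
})

test_that("density classes are disjoint, inside the cusp, and empty without calcification", {
  sp <- small_phantom_spec(seed = 8)
  ph <- generate_phantom(sp)
  v8 <- convert_16_to_8(ph$volume)
  cfg <- pipeline_config(voxel_size_um = 100)
  cusp <- segment_cusp(v8, cfg, ph$truth$roi_mask)
  res <- pve_decompose(v8$data, cusp, cfg)
  expect_false(any(res$hd & res$md))
  expect_false(any(res$hd & res$ld))
  expect_false(any(res$md & res$ld))
  expect_true(all(cusp[res$hd | res$md | res$ld]))
  expect_true(is.finite(res$volume_loss_fraction))

  # all-soft-tissue cusp: every class empty, loss defined as 0
  v <- array(50L, c(10, 10, 6))
  none <- pve_decompose(v, v >= 25L, cfg14)
  expect_equal(sum(none$hd) + sum(none$md) + sum(none$ld), 0)
  expect_equal(none$volume_loss_fraction, 0)
})

test_that("the PVE volume loss is invariant under translation and 90-degree rotation", {
  set.seed(21)
  v <- array(40L, c(18, 14, 12))
  v[4:8, 4:7, 4:6] <- 220L
  v[12:15, 9:12, 7:9] <- 120L
  v[4:6, 10:12, 8:10] <- 160L
  cusp <- v >= 25L
  base <- pve_decompose(v, cusp, cfg14)

  # translation within a larger array
  vt <- array(0L, c(24, 22, 20))
  vt[3 + seq_len(18), 5 + seq_len(14), 2 + seq_len(12)] <- v
  vt[vt == 0L] <- 40L
  shifted <- pve_decompose(vt, vt >= 25L, cfg14)
  expect_equal(shifted$volume_loss_fraction, base$volume_loss_fraction)

  # axis-aligned 90-degree rotation
  vr <- aperm(v, c(2, 1, 3))[dim(v)[2]:1, , , drop = FALSE]
  rotated <- pve_decompose(vr, vr >= 25L, cfg14)
  expect_equal(rotated$volume_loss_fraction, base$volume_loss_fraction)
})
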