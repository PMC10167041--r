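test_that("an axial slab has thickness equal to its voxel height at interior columns", {
  m <- array(FALSE, c(40, 40, 15))
  m[, , 4:12] <- TRUE  # 9-voxel slab, wide in XY
  tm <- local_thickness(m, 1000)  # 1 mm voxels for direct readout
  interior <- tm$data[15:25, 15:25, 4:12]
  expect_true(all(abs(interior - 9) < 1e-9))
  expect_true(all(tm$data[, , c(1:3, 13:15)] == 0))
  expect_true(all(tm$data[m] > 0))
})

test_that("empty masks give an all-zero map and an error on summary", {
  tm <- local_thickness(array(FALSE, c(5, 5, 5)), 14)
  expect_true(all(tm$data == 0))
  expect_error(thickness_summary(tm), "empty")
})

test_that("thickness matches the brute-force largest-inscribed-sphere oracle", {
  set.seed(31)
  masks <- list(digital_ball(16, pad = 2L))
  for (rep in 1:4) masks <- c(masks, list(random_blob_mask(c(14, 14, 14), 1, 0.55)))
  for (rep in 1:3) masks <- c(masks, list(random_mask(12L)))
  for (m in masks) {
    tm <- local_thickness(m, 1000)
    expect_equal(tm$data, oracle_thickness(m), tolerance = 1e-12)
  }
})

test_that("eroding the mask never increases thickness anywhere", {
  set.seed(32)
  m <- random_blob_mask(c(20, 20, 16), 2, 0.5)
  er <- binary_erode(m, valve3d:::offsets_ball3d(1L, "ball"))
  t0 <- local_thickness(m, 1000)$data
  t1 <- local_thickness(er, 1000)$data
  expect_true(all(t1[er] <= t0[er] + 1e-9))
})

test_that("thickness is invariant under translation and 90-degree rotations", {
  set.seed(33)
  m <- random_blob_mask(c(16, 14, 12), 2, 0.55)
  base <- local_thickness(m, 1000)$data
  tr <- local_thickness(translate_mask(m), 1000)$data
  expect_equal(sort(tr[tr > 0]), sort(base[base > 0]))
  for (rot in rotations_90) {
    r <- local_thickness(rot(m), 1000)$data
    expect_equal(sort(r[r > 0]), sort(base[base > 0]))
  }
})

test_that("volume-proportion summaries reflect uniform and two-slab phantoms", {
  # restrict a map to its interior, away from array-border wedges
  crop_map <- function(tm, mx, my) {
    tm$data <- tm$data[mx[1]:mx[2], my[1]:my[2], , drop = FALSE]
    tm
  }

  # uniform slab, 10 voxels at 50 um; an even-height digital slab measures
  # one voxel less than its height (no voxel centre sits on the mid-plane)
  m <- array(FALSE, c(60, 60, 20)); m[, , 6:15] <- TRUE
  s <- thickness_summary(crop_map(local_thickness(m, 50), c(12, 49), c(12, 49)), 0.7)
  expect_equal(s$fraction_below_threshold, 1.0)
  expect_equal(s$mean_thickness_mm, 0.45, tolerance = 1e-9)

  # 1.0 mm slab: no interior volume below 0.7 mm
  m2 <- array(FALSE, c(60, 60, 30)); m2[, , 6:25] <- TRUE
  s2 <- thickness_summary(crop_map(local_thickness(m2, 50), c(12, 49), c(12, 49)), 0.7)
  expect_equal(s2$fraction_below_threshold, 0.0)

  # joined slabs of 1.0 and 0.5 mm with equal interior voxel volumes
  m3 <- array(FALSE, c(136, 48, 30))
  m3[1:48, , 6:25] <- TRUE     # 1.0 mm limb
  m3[49:136, , 6:15] <- TRUE   # 0.5 mm limb
  s3 <- thickness_summary(crop_map(local_thickness(m3, 50), c(9, 128), c(9, 40)), 0.7)
  expect_equal(s3$fraction_below_threshold, 0.5, tolerance = 0.05)

  # histogram fractions always sum to one
  expect_equal(sum(s3$histogram$volume_fraction), 1, tolerance = 1e-9)
})

test_that("digital balls recover their nominal diameter within discretization error", {
  for (d in c(8, 12, 16, 24)) {
    m <- digital_ball(d)
    tm <- local_thickness(m, 1000)
    mean_th <- mean(tm$data[m])
    expect_lt(abs(mean_th - d) / d, 0.10)
  }
})

test_that("the overlay export returns untouched thickness values", {
  m <- array(FALSE, c(12, 12, 6)); m[3:10, 3:10, 2:5] <- TRUE
  calc <- array(FALSE, dim(m)); calc[5:7, 5:7, 3] <- TRUE
  tm <- local_thickness(m, 100)
  ov <- thickness_calc_overlay(tm, calc, z_index = 3)
  expect_identical(ov$values, tm$data[, , 3])
  expect_equal(dim(ov$rgb), c(12, 12, 3))
  # outlined voxels are pure red
  expect_true(all(ov$rgb[, , 1][calc[, , 3] & !ov$rgb[, , 2]] == 1))

  # an empty calcification mask renders the plain thickness slice
  ov0 <- thickness_calc_overlay(tm, array(FALSE, dim(m)), 3)
  expect_equal(ov0$rgb[, , 1], ov0$rgb[, , 2])

  expect_error(thickness_calc_overlay(tm, calc, 99), "z_index")

  # float stack round trip preserves mm values
  dir <- withr::local_tempdir()
  write_thickness_stack(tm, dir)
  back <- read_thickness_stack(dir)
  expect_equal(back$data, tm$data, tolerance = 1e-6)
})
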