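cfg14 <- pipeline_config(voxel_size_um = 14)

test_that("corner-touching blocks are one particle under 26- but two under 6-connectivity", {
  m <- array(FALSE, c(6, 6, 6))
  m[2:3, 2:3, 2:3] <- TRUE
  m[4:5, 4:5, 4:5] <- TRUE  # touches the first block at one corner pair
  expect_equal(max(label_particles(m, 26)), 1L)
  expect_equal(max(label_particles(m, 6)), 2L)

  expect_equal(max(label_particles(array(FALSE, c(4, 4, 4)), 26)), 0L)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  lab <- label_particles(single, 26)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab > 0), 1)
})

test_that("labelling matches the brute-force flood-fill oracle", {
  set.seed(13)
  for (rep in 1:8) {
    m <- random_mask(max_dim = 18L)
    for (conn in c(6L, 26L)) {
      expect_identical(label_particles(m, conn), oracle_label(m, conn))
    }
  }
})

test_that("labelled voxel counts conserve the mask voxel count", {
  set.seed(14)
  for (rep in 1:4) {
    m <- random_blob_mask(c(20, 20, 12), smooth = 1, level = 0.65)
    lab <- label_particles(m, 26)
    expect_equal(sum(lab > 0), sum(m))
    filtered <- filter_small(lab, 10)
    k <- max(filtered)
    if (k > 0) {
      counts <- tabulate(filtered[filtered > 0], nbins = k)
      expect_true(all(counts > 10))
      expect_equal(sum(counts), sum(filtered > 0))
      expect_identical(sort(unique(as.vector(filtered[filtered > 0]))), seq_len(k))
    }
  }
})

test_that("the small-particle filter removes at 10 voxels and keeps at 11", {
  m <- array(FALSE, c(30, 6, 6))
  m[1:10, 2, 2] <- TRUE    # exactly 10 voxels
  m[15:25, 4, 4] <- TRUE   # 11 voxels
  lab <- filter_small(label_particles(m, 26), 10)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab > 0), 11)
  expect_true(all(which(lab == 1L) %in% which(m)))

  empty <- filter_small(label_particles(array(FALSE, c(3, 3, 3)), 26), 10)
  expect_equal(max(empty), 0L)
})

test_that("size classes respect the closed micro and macro boundaries", {
  # at 100 um, 1 voxel = 1e-3 mm^3 and 1000 voxels = 1 mm^3 exactly
  lab <- array(0L, c(40, 20, 20))
  lab[1, 1, 1] <- 1L                       # exactly 1e-3 mm^3
  lab[11:20, 1:10, 1:10] <- 2L             # exactly 1 mm^3
  lab[30:39, 1:5, 1:2] <- 3L               # 100 voxels = 0.1 mm^3
  cfg <- pipeline_config(voxel_size_um = 100, min_particle_voxels = 0L)
  pt <- particle_metrics(lab, cusp_volume_mm3 = 50, voxel_size_um = 100, config = cfg)
  expect_equal(as.character(pt$particles$size_class), c("micro", "macro", "meso"))
  expect_equal(pt$summary$n_micro, 1)
  expect_equal(pt$summary$n_meso, 1)
  expect_equal(pt$summary$n_macro, 1)

  # mixed volumes 5e-4 / 5e-2 / 2.0 mm^3 at 14 um
  vox14 <- (14 / 1000)^3
  n <- as.integer(round(c(5e-4, 5e-2, 2.0) / vox14))
  lab2 <- array(0L, c(800, 1000, 1))
  lab2[seq_len(n[1])] <- 1L
  lab2[n[1] + seq_len(n[2])] <- 2L
  lab2[n[1] + n[2] + seq_len(n[3])] <- 3L
  pt2 <- particle_metrics(lab2, 100, 14, cfg14)
  expect_equal(as.integer(table(pt2$particles$size_class)[c("micro", "meso", "macro")]),
               c(1L, 1L, 1L))

  # single particle: the largest fraction is 1
  lab3 <- array(0L, c(5, 5, 5)); lab3[1:20] <- 1L
  expect_equal(particle_metrics(lab3, 1, 14, cfg14)$summary$largest_fraction, 1)

  expect_error(particle_metrics(lab3, 0, 14, cfg14), "positive")
})

test_that("particle metrics are invariant under translation and rotation", {
  set.seed(15)
  m <- random_blob_mask(c(18, 18, 10), smooth = 1, level = 0.7)
  base <- particle_metrics(filter_small(label_particles(m, 26), 2), 10, 14, cfg14)
  tr <- particle_metrics(filter_small(label_particles(translate_mask(m), 26), 2),
                         10, 14, cfg14)
  expect_equal(tr$summary$n_particles, base$summary$n_particles)
  expect_equal(sort(tr$particles$voxel_count), sort(base$particles$voxel_count))
  for (rot in rotations_90) {
    mr <- rot(m)
    rr <- particle_metrics(filter_small(label_particles(mr, 26), 2), 10, 14, cfg14)
    expect_equal(rr$summary$n_particles, base$summary$n_particles)
    expect_equal(rr$summary$particles_per_mm3, base$summary$particles_per_mm3)
    expect_equal(sort(rr$particles$voxel_count), sort(base$particles$voxel_count))
  }
})
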