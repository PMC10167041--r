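test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(small_phantom_spec(seed = 101))
  b <- generate_phantom(small_phantom_spec(seed = 101))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$cusp_mask, b$truth$cusp_mask)
  c <- generate_phantom(small_phantom_spec(seed = 102))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("a phantom without inclusions yields zero calcification end to end", {
  sp <- small_phantom_spec(seed = 103, inclusions = default_inclusions()[0, ])
  ph <- generate_phantom(sp)
  expect_equal(ph$truth$calc_fraction, 0)
  res <- run_cusp_pipeline(ph$volume, pipeline_config(),
                           roi_mask = ph$truth$roi_mask,
                           anchor_masks = list(holder = ph$truth$holder_mask,
                                               bead = ph$truth$bead_mask),
                           ref_anchors = reference_anchors(20, 240))
  expect_equal(res$report$calc_volume_fraction, 0)
  expect_equal(res$report$particles$n_particles, 0)
})

test_that("an undegraded phantom reproduces its ground-truth masks voxel-exactly", {
  sp <- small_phantom_spec(seed = 104, psf_sigma_voxels = 0, noise_sigma = 0)
  ph <- generate_phantom(sp)
  g <- sp$gray
  v16 <- ph$volume$data
  lab <- ph$truth$inclusion_labels
  cls <- ph$truth$inclusions$class
  # thresholding at the rendered class gray levels recovers each stratum
  for (cl in c("ld", "md", "hd")) {
    lo <- g[[cl]] * 257L
    hi <- switch(cl, ld = g$md, md = g$hd, hd = 256) * 257L
    got <- (v16 >= lo) & (v16 < hi) & ph$truth$cusp_mask
    expect_identical(array(got, dim(v16)),
                     array(lab %in% which(cls == cl), dim(v16)))
  }
  # and the cusp itself
  cusp16 <- (v16 >= g$soft * 257L) & !(v16 >= g$bead * 257L)
  expect_identical(array(cusp16 & ph$truth$roi_mask, dim(v16)), ph$truth$cusp_mask)
})

test_that("ground truth conserves inclusion volumes", {
  ph <- generate_phantom(small_phantom_spec(seed = 105))
  tr <- ph$truth
  expect_equal(sum(tr$inclusions$volume_mm3), sum(tr$class_volumes_mm3))
  expect_equal(sum(tr$inclusions$voxel_count), sum(tr$inclusion_labels > 0))
  expect_equal(tr$calc_fraction,
               sum(tr$inclusions$voxel_count) / sum(tr$cusp_mask))
  # inclusion masks disjoint by construction and inside the cusp
  expect_true(all(tr$cusp_mask[tr$inclusion_labels > 0]))
})

test_that("invalid phantom specifications are rejected", {
  bad <- default_inclusions()
  bad$c_mm[1] <- 2.0  # thicker than the slab half-thickness
  expect_error(phantom_spec(inclusions = bad, seed = 1), "outside cusp")

  g <- list(background = 5, holder = 60, soft = 45, ld = 95, md = 165, hd = 220,
            bead = 240)
  expect_error(phantom_spec(gray = g, seed = 1), "background < holder")

  expect_error(phantom_spec(seed = NULL), "mandatory")
})

test_that("cohorts are reproducible and carry the configured group contrasts", {
  co1 <- sample_cohort(3, seed = 42)
  co2 <- sample_cohort(3, seed = 42)
  expect_identical(co1, co2)
  expect_error(sample_cohort(0, seed = 1), ">= 1")

  # Monte-Carlo: generated ground-truth thickness ordered as parameterized
  co <- sample_cohort(10, seed = 77)
  th <- vapply(co, function(x) x$spec$base_thickness_mm, numeric(1))
  gr <- vapply(co, function(x) x$group, character(1))
  expect_lt(mean(th[gr == "A"]), mean(th[gr == "B"]))
  # inclusion counts ordered as parameterized
  n_inc <- vapply(co, function(x) nrow(x$spec$inclusions), numeric(1))
  expect_lt(mean(n_inc[gr == "A"]), mean(n_inc[gr == "B"]))
  # every spec passes validation and stays inside the slab
  for (x in co) {
    expect_true(all(abs(x$spec$inclusions$z_offset_mm) + x$spec$inclusions$c_mm
                    <= x$spec$base_thickness_mm / 2))
  }
})
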