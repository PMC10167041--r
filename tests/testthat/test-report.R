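test_that("exact Mann-Whitney matches the base-R null distribution without ties", {
  set.seed(51)
  for (rep in 1:10) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    x <- sample(seq(1, 500), na)
    y <- sample(setdiff(seq(1, 500), x), nb)
    mine <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$method, "exact")
  }
})

test_that("complete separation of 3 vs 3 gives the enumerated two-sided p of 0.1", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(r$U, 0)
  r2 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$p, 0.1)
  expect_equal(r2$U, 9)
})

test_that("identical multisets give U = n^2/2 and p = 1 under midrank enumeration", {
  r <- mann_whitney(c(2, 5, 9), c(2, 5, 9))
  expect_equal(r$U, 4.5)
  expect_equal(r$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("swapping group labels preserves p and reflects U", {
  set.seed(52)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(4) + 0.5
    a <- mann_whitney(x, y)
    b <- mann_whitney(y, x)
    expect_equal(a$p, b$p)
    expect_equal(b$U, length(x) * length(y) - a$U)
  }
  # large samples switch to the tie-corrected normal approximation
  big <- mann_whitney(rnorm(15), rnorm(15))
  expect_equal(big$method, "normal_approx")
  expect_true(big$p >= 0 && big$p <= 1)
})

test_that("correlations report the requested coefficient with input validation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$estimate, 1)
  expect_equal(correlate(x, exp(x), "spearman")$estimate, 1)
  expect_error(correlate(x, x[1:3], "pearson"), "length")
  expect_error(correlate(c(1, 2), c(3, 4), "pearson"), "at least 3")
  expect_error(correlate(rep(1, 5), x, "pearson"), "zero variance")
})

test_that("valve aggregation pools cusp volumes", {
  mk <- function(id, cusp, calc) {
    structure(list(sample_id = id, valve_id = sub("\\.[^.]*$", "", id),
                   cusp_volume_mm3 = cusp, calc_volume_mm3 = calc,
                   calc_volume_fraction = calc / cusp),
              class = "cusp_report")
  }
  v <- aggregate_valve(list(mk("N1.1", 10, 1), mk("N1.2", 10, 3)))
  expect_equal(v$calc_volume_fraction, 0.2)
  expect_equal(v$calc_volume_mm3, 4)

  single <- aggregate_valve(list(mk("N2.1", 8, 2)))
  expect_equal(single$calc_volume_fraction, 0.25)
  expect_equal(single$n_cusps, 1)

  expect_error(aggregate_valve(list()), "no cusp reports")
  expect_error(aggregate_valve(list(mk("N1.1", 1, 0), mk("N2.1", 1, 0))),
               "different valves")

  # pooled fraction lies between the cusp fractions
  set.seed(53)
  for (rep in 1:5) {
    reps <- lapply(1:3, function(i) mk(paste0("V9.", i), runif(1, 5, 20), runif(1, 0, 5)))
    fr <- vapply(reps, function(r) r$calc_volume_fraction, numeric(1))
    pooled <- aggregate_valve(reps)$calc_volume_fraction
    expect_true(pooled >= min(fr) - 1e-12 && pooled <= max(fr) + 1e-12)
  }
})

test_that("significance stars follow the reporting convention", {
  expect_equal(p_stars(0.2), "ns")
  expect_equal(p_stars(0.03), "*")
  expect_equal(p_stars(0.004), "**")
  expect_equal(p_stars(4e-4), "***")
  expect_equal(p_stars(5e-5), "****")
})
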