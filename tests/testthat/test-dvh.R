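test_that("uniform ROI gives a step DVH with exact V/D metrics", {
  d <- uniform_grid(50, shape = c(10, 10, 5), spacing = c(2, 2, 2))
  m <- full_mask(c(10, 10, 5), spacing = c(2, 2, 2))  # 500 voxels = 4 cc
  dvh <- compute_dvh(d, m, edge_step = 0.1)
  expect_equal(dvh$total_volume, 4)
  expect_equal(volume_at_dose(dvh, 49.9), 1)
  expect_equal(volume_at_dose(dvh, 50.2), 0)

  mets <- dvh_to_metrics(dvh)
  v <- function(nm) mets$value[mets$metric == nm]
  expect_equal(v("V40pct"), 100)
  expect_equal(v("V55pct"), 0)
  expect_equal(v("D2cc"), 50, tolerance = 0.1)
  expect_equal(v("Dmean"), 50, tolerance = 0.1)
  expect_equal(v("Dmin"), 50, tolerance = 0.1)
  expect_equal(v("Dmax"), 50, tolerance = 0.1)
})

test_that("two-level ROI: counting, inverse lookup and Dmean conservation", {
  vals <- array(c(rep(40, 250), rep(60, 250)), c(10, 10, 5))
  d <- dose_grid(vals, spacing = c(2, 2, 2))
  m <- full_mask(c(10, 10, 5), spacing = c(2, 2, 2))  # 4 cc
  dvh <- compute_dvh(d, m, edge_step = 0.1)
  expect_equal(volume_at_dose(dvh, 50), 0.5)
  mets <- dvh_to_metrics(dvh)
  v <- function(nm) mets$value[mets$metric == nm]
  expect_equal(v("D2cc"), 60, tolerance = 0.1)     # hottest 2 cc all at 60
  expect_equal(v("D1pct"), 60, tolerance = 0.1)
  expect_equal(v("Dmean"), mean(vals), tolerance = 0.1)
})

test_that("DVH-implied mean matches the voxel mean within one edge step", {
  withr::with_seed(4, {
    vals <- array(runif(8^3, 20, 55), c(8, 8, 8))
  })
  d <- dose_grid(vals, spacing = c(2.5, 2.5, 2.5))
  m <- full_mask(c(8, 8, 8), spacing = c(2.5, 2.5, 2.5))
  for (step in c(0.1, 0.5)) {
    dvh <- compute_dvh(d, m, edge_step = step)
    dmean <- dvh_to_metrics(dvh)$value[dvh_to_metrics(dvh)$metric == "Dmean"]
    expect_equal(dmean, mean(vals), tolerance = step)
  }
})

test_that("Vx at 0 Gy is 100% and the Vx family is non-increasing", {
  withr::with_seed(14, {
    vals <- array(runif(6^3, 10, 55), c(6, 6, 6))
  })
  dvh <- compute_dvh(dose_grid(vals), full_mask())
  expect_equal(volume_at_dose(dvh, 0), 1)
  vx <- volume_at_dose(dvh, seq(0, 60, by = 5))
  expect_true(all(diff(vx) <= 1e-12))
  expect_true(all(diff(dvh$volume_fraction) <= 1e-12))
})

test_that("requesting more cc than the organ falls back to Dmin with warning", {
  d <- uniform_grid(50, c(4, 4, 4))
  m <- full_mask(c(4, 4, 4))  # 64 * 8 / 1000 = 0.512 cc
  dvh <- compute_dvh(d, m)
  expect_warning(mets <- dvh_to_metrics(dvh), "exceeds organ volume")
  v <- function(nm) mets$value[mets$metric == nm]
  expect_equal(v("D2cc"), v("Dmin"))
})

test_that("EQD2 closed forms, identity at 2 Gy/fraction, and monotonicity", {
  expect_equal(eqd2_convert(45, 25, 3), 43.2)
  expect_equal(eqd2_convert(21, 3, 3), 42.0)
  # any dose delivered at exactly 2 Gy/fraction is its own EQD2
  for (D in c(10, 36, 50)) {
    expect_equal(eqd2_convert(D, D / 2, 3), D)
    expect_equal(eqd2_convert(D, D / 2, 10), D)
  }
  # EQD2 increases with fraction size at fixed total dose
  e <- vapply(c(25, 20, 15, 10, 5), function(n) eqd2_convert(45, n, 3),
              numeric(1))
  expect_true(all(diff(e) > 0))
  # alpha/beta -> infinity recovers the physical dose
  expect_equal(eqd2_convert(45, 25, 1e9), 45, tolerance = 1e-6)
  expect_error(eqd2_convert(45, 25, 0), class = "dosiomics_invalid_argument")
  expect_error(eqd2_convert(-1, 25, 3), class = "dosiomics_invalid_argument")
})

test_that("hotspot-aligned summation adds doses at equal volume fraction", {
  # uniform + uniform
  a <- compute_dvh(uniform_grid(45, c(4, 4, 4)), full_mask(c(4, 4, 4)))
  b <- compute_dvh(uniform_grid(28, c(4, 4, 4)), full_mask(c(4, 4, 4)))
  s <- sum_dvh_hotspot_aligned(a, b)
  expect_equal(dose_at_fraction(s, 0.5), 73, tolerance = 0.2)
  expect_equal(volume_at_dose(s, 72.8), 1, tolerance = 1e-9)
  expect_equal(volume_at_dose(s, 73.2), 0, tolerance = 1e-9)

  # hand-computed two-level example: {50,40} + {20,10} -> {70,50}
  va <- array(c(rep(40, 32), rep(50, 32)), c(4, 4, 4))
  vb <- array(c(rep(10, 32), rep(20, 32)), c(4, 4, 4))
  # align hot halves in the same array positions
  vb <- vb[, , ]  # same layout: first half cold, second half hot
  da <- compute_dvh(dose_grid(va), full_mask(c(4, 4, 4)))
  db <- compute_dvh(dose_grid(vb), full_mask(c(4, 4, 4)))
  s2 <- sum_dvh_hotspot_aligned(da, db)
  expect_equal(dose_at_fraction(s2, 0.25), 70, tolerance = 0.2)
  expect_equal(dose_at_fraction(s2, 0.75), 50, tolerance = 0.2)
  expect_equal(volume_at_dose(s2, 60), 0.5, tolerance = 0.01)
})

test_that("summation is commutative and has the zero DVH as identity", {
  withr::with_seed(6, {
    va <- array(runif(5^3, 30, 55), c(5, 5, 5))
    vb <- array(runif(5^3, 0, 25), c(5, 5, 5))
  })
  a <- compute_dvh(dose_grid(va), full_mask(c(5, 5, 5)))
  b <- compute_dvh(dose_grid(vb), full_mask(c(5, 5, 5)))
  ab <- sum_dvh_hotspot_aligned(a, b)
  ba <- sum_dvh_hotspot_aligned(b, a)
  expect_equal(ab$dose_edges, ba$dose_edges, tolerance = 1e-9)
  expect_equal(ab$volume_fraction, ba$volume_fraction, tolerance = 1e-9)

  zero <- dvh_curve(c(0, 0.1), c(1, 0), total_volume = a$total_volume)
  az <- sum_dvh_hotspot_aligned(a, zero, n_points = 5000)
  u <- seq(0.05, 0.95, by = 0.05)
  expect_equal(dose_at_fraction(az, u), dose_at_fraction(a, u),
               tolerance = 0.3)

  expect_error(
    sum_dvh_hotspot_aligned(
      compute_dvh(uniform_grid(45), full_mask(organ = "rectum")),
      compute_dvh(uniform_grid(10), full_mask(organ = "bladder"))),
    class = "dosiomics_invalid_argument")
})

test_that("EQD2 DVH transform preserves volume fractions and scales edges", {
  a <- compute_dvh(uniform_grid(45, c(4, 4, 4)), full_mask(c(4, 4, 4)))
  e <- eqd2_dvh(a, n_fractions = 25, alpha_beta = 3)
  expect_equal(e$volume_fraction, a$volume_fraction)
  expect_equal(max(e$dose_edges[e$volume_fraction == 1]),
               eqd2_convert(45, 25, 3), tolerance = 0.15)
})
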