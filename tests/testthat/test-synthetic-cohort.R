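test_that("dose grid generator is seeded-deterministic with bounded values", {
  args <- list(shape = c(16, 16, 16), spacing = c(3, 3, 3),
               prescription = 45,
               hotspot_spec = list(list(center = c(24, 24, 24), radius = 10,
                                        peak = 50)),
               seed = 42)
  g1 <- do.call(gen_dose_grid, args)
  g2 <- do.call(gen_dose_grid, args)
  expect_identical(as.vector(g1), as.vector(g2))
  expect_gte(max(g1), 45)
  expect_lte(max(g1), 54)
  expect_true(all(g1 >= 0))
})

test_that("infinite smoothness with no hotspots gives a constant field", {
  g <- gen_dose_grid(c(8, 8, 8), c(2, 2, 2), 48, smoothness = Inf, seed = 1)
  expect_true(all(g == 48))
})

test_that("dose grid preconditions are enforced", {
  expect_error(gen_dose_grid(c(-4, 8, 8), c(2, 2, 2), 45),
               class = "dosiomics_invalid_argument")
  expect_error(gen_dose_grid(c(8, 8, 8), c(0, 2, 2), 45),
               class = "dosiomics_invalid_argument")
  expect_error(gen_dose_grid(c(8, 8, 8), c(2, 2, 2), 25),
               class = "dosiomics_invalid_argument")
  expect_error(
    gen_dose_grid(c(8, 8, 8), c(2, 2, 2), 45,
                  hotspot_spec = list(list(center = c(1, 1, 1), radius = 5,
                                           peak = 60))),
    class = "dosiomics_invalid_argument")
})

test_that("organ masks hit the target volume and stay connected across seeds", {
  # 50 cc target on a 64^3 grid of 2 mm voxels
  m <- gen_organ_mask(c(64, 64, 64), c(2, 2, 2), "rectum", 50, seed = 9)
  expect_gte(mask_volume_cc(m), 40)
  expect_lte(mask_volume_cc(m), 60)
  expect_identical(mask_components(m), 1L)

  m1 <- gen_organ_mask(c(24, 24, 24), c(3, 3, 3), "bladder", 60, seed = 3)
  m2 <- gen_organ_mask(c(24, 24, 24), c(3, 3, 3), "bladder", 60, seed = 3)
  expect_identical(as.vector(m1), as.vector(m2))

  for (seed in 1:25) {
    for (org in c("rectum", "bladder", "vagina")) {
      mk <- gen_organ_mask(c(20, 20, 20), c(3, 3, 3), org,
                           if (org == "bladder") 50 else 30, seed = seed)
      expect_identical(mask_components(mk), 1L)
      target <- if (org == "bladder") 50 else 30
      expect_lte(abs(mask_volume_cc(mk) - target) / target, 0.2)
    }
  }

  expect_error(gen_organ_mask(c(8, 8, 8), c(2, 2, 2), "bladder", 500),
               class = "dosiomics_invalid_argument")
})

test_that("organ archetypes differ: tubes are elongated, blobs compact", {
  tube <- gen_organ_mask(c(32, 32, 32), c(2.5, 2.5, 2.5), "rectum", 40,
                         seed = 7)
  blob <- gen_organ_mask(c(32, 32, 32), c(2.5, 2.5, 2.5), "bladder", 40,
                         seed = 7)
  elong <- function(m) diff(range(which(apply(m, 3, any)))) /
    diff(range(which(apply(m, 1, any))))
  expect_gt(elong(tube), 1.3)
  expect_gt(elong(tube), elong(blob) + 0.3)
})

test_that("BT DVH generator produces monotone curves with bounded dose scale", {
  for (seed in 1:20) {
    dvh <- gen_bt_dvh(7, 3, falloff_scale = 3, organ_volume = 50,
                      seed = seed)
    expect_true(all(diff(dvh$volume_fraction) <= 1e-12))
    expect_equal(dvh$volume_fraction[1], 1)
    expect_lte(max(dvh$dose_edges[dvh$volume_fraction > 0]), 3 * 7 * 1.5)
  }
  # degenerate falloff: a step DVH
  st <- gen_bt_dvh(7, 4, falloff_scale = 0, organ_volume = 50, seed = 2)
  expect_true(all(st$volume_fraction %in% c(0, 1)))
  expect_error(gen_bt_dvh(7, 5), class = "dosiomics_invalid_argument")
  expect_error(gen_bt_dvh(-1, 3), class = "dosiomics_invalid_argument")
})

test_that("cohorts are pure functions of their seed", {
  co1 <- gen_cohort(14, NULL, fast_config(), seed = 77, n_test = 5)
  co2 <- gen_cohort(14, NULL, fast_config(), seed = 77, n_test = 5)
  expect_identical(co1$table, co2$table)
  co3 <- gen_cohort(14, NULL, fast_config(), seed = 78, n_test = 5)
  expect_false(identical(co1$table, co3$table))
  expect_identical(anyDuplicated(co1$table$id), 0L)
  expect_identical(sum(co1$table$split == "testing"), 5L)
})

test_that("intercept-only endpoint prevalence converges to expit(intercept)", {
  cfg <- cohort_config(organs = character(0))
  pl <- planted_model("rectal_acute", qlogis(0.25))
  co <- gen_cohort(5000, pl, cfg, seed = 11, n_test = 0)
  prev <- mean(co$table$rectal_acute)
  sigma <- sqrt(0.25 * 0.75 / 5000)
  expect_lte(abs(prev - 0.25), 3 * sigma)
  # clinical covariates respect their invariants
  expect_true(all(co$table$age >= 18 & co$table$age <= 100))
  expect_true(all(co$table$baseline_symptoms %in% 0:1))
})

test_that("planted features must exist in the generated table", {
  pl <- planted_model("rectal_acute", 0, c(RA_rectum_not_a_feature = 1))
  expect_error(gen_cohort(12, pl, fast_config(), seed = 1, n_test = 0),
               class = "dosiomics_config_error")
})

test_that("a planted radiomic coefficient is recoverable by a direct refit", {
  pl <- planted_model("rectal_acute", qlogis(0.3),
                      c(RA_rectum_cooc_inv_diff_norm = 1.5))
  co <- gen_cohort(600, pl, fast_config(), seed = 19, n_test = 0)
  z <- scale(co$table$RA_rectum_cooc_inv_diff_norm)[, 1]
  fit <- glm(co$table$rectal_acute ~ z, family = binomial())
  ci <- suppressMessages(confint(fit, level = 0.95))["z", ]
  expect_gt(coef(fit)[["z"]], 0.8)
  expect_true(ci[1] <= 1.5 && 1.5 <= ci[2])
})
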