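# Programmatic fixtures shared across test files.

# A grey-level volume with prescribed integer levels (0 = outside ROI),
# built through the public discretization path so the object is genuine.
glv_from_levels <- function(levels) {
  levels <- as.array(levels)
  dose <- array(pmax(levels - 0.5, 0), dim(levels))
  mask <- array(levels > 0, dim(levels))
  discretize_fbw(dose_grid(dose), organ_mask(mask), bin_width = 1)
}

# Random small grey-level volume for oracle-equivalence sweeps.
random_glv <- function(shape = c(5, 5, 5), ng = 4, p_mask = 0.8, seed = 1) {
  withr::with_seed(seed, {
    lv <- array(sample.int(ng, prod(shape), replace = TRUE), shape)
    lv[array(runif(prod(shape)) >= p_mask, shape)] <- 0L
    if (all(lv == 0)) lv[1, 1, 1] <- 1L
    lv
  })
}

uniform_grid <- function(dose = 45, shape = c(6, 6, 6), spacing = c(2, 2, 2)) {
  dose_grid(array(dose, shape), spacing)
}

full_mask <- function(shape = c(6, 6, 6), spacing = c(2, 2, 2),
                      organ = "rectum") {
  organ_mask(array(TRUE, shape), spacing, organ_label = organ)
}

# small config that keeps cohort generation fast in tests
fast_config <- function(...) {
  cohort_config(shape = c(16, 16, 16), spacing = c(3, 3, 3),
                organs = "rectum", target_volumes = c(rectum = 25),
                include_dvh = FALSE, ...)
}
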