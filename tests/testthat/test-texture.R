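test_that("GLCM on a hand-enumerated row matches the worked example", {
  glv <- glv_from_levels(array(c(1L, 1L, 2L), c(3, 1, 1)))
  dir_x <- matrix(c(1L, 0L, 0L), 1)
  g <- glcm_features(glv, dir_x)
  # pairs (1,1) and (1,2), symmetric: P = [[.5,.25],[.25,0]]
  expect_equal(unname(g["cooc_inv_diff_norm"]), 0.5 + 2 * 0.25 / 1.5)
  expect_equal(unname(g["cooc_joint_max"]), 0.5)
  expect_equal(unname(g["cooc_contrast"]), 0.5)
})

test_that("GLCM degenerate cases: uniform ROI and isolated voxel", {
  glv <- glv_from_levels(array(2L, c(3, 3, 3)))
  g <- glcm_features(glv)
  expect_equal(unname(g["cooc_cluster_shade"]), 0)
  expect_equal(unname(g["cooc_inv_diff_norm"]), 1)
  expect_equal(unname(g["cooc_energy"]), 1)
  expect_equal(unname(g["cooc_correlation"]), 1)

  solo <- glv_from_levels(array(c(3L, rep(0L, 26)), c(3, 3, 3)))
  gs <- glcm_features(solo)
  expect_true(attr(gs, "degenerate"))
  expect_true(all(is.finite(gs)))
  expect_equal(unname(gs["cooc_energy"]), 1)
})

test_that("GLRLM hand example and run conservation hold", {
  glv <- glv_from_levels(array(c(1L, 1L, 2L), c(3, 1, 1)))
  dir_x <- matrix(c(1L, 0L, 0L), 1)
  r <- glrlm_features(glv, dir_x)
  # runs: (level 1, len 2), (level 2, len 1); SRLGE = (1/4 + 1/4)/2
  expect_equal(unname(r["rlm_srlge"]), 0.25)
  expect_equal(unname(r["rlm_sre"]), (1 / 4 + 1) / 2)

  # uniform row: a single run of length n
  u <- glv_from_levels(array(1L, c(5, 1, 1)))
  ru <- glrlm_features(u, dir_x)
  expect_equal(unname(ru["rlm_lre"]), 25)

  # runs partition the ROI per direction: sum r(i,j) * j = Nv * n_dirs
  lv <- random_glv(c(4, 4, 4), ng = 3, seed = 11)
  glv2 <- glv_from_levels(lv)
  runs <- oracle_runs(lv)
  expect_equal(sum(runs[, 2]), sum(lv > 0) * 13)
})

test_that("GLSZM hand example and zone partition hold", {
  glv <- glv_from_levels(array(c(1L, 1L, 2L), c(3, 1, 1)))
  s <- glszm_features(glv)
  expect_equal(unname(s["szm_zsnu"]), 1)
  expect_equal(unname(s["szm_hgze"]), 2.5)
  expect_equal(unname(s["szm_glnu"]), 1)

  # uniform connected ROI: a single zone
  u <- glv_from_levels(array(1L, c(4, 4, 4)))
  su <- glszm_features(u)
  expect_equal(unname(su["szm_zsnu"]), 1)
  expect_equal(unname(su["szm_glnu"]), 1)
  expect_equal(unname(su["szm_zone_pct"]), 1 / 64)

  # zones partition the ROI
  lv <- random_glv(c(5, 5, 5), ng = 4, seed = 3)
  z <- oracle_zones(lv)
  expect_equal(sum(z[, 2]), sum(lv > 0))
})

test_that("NGTDM: uniform ROI hits the coarseness cap, checkerboard does not", {
  u <- glv_from_levels(array(2L, c(4, 4, 4)))
  nu <- ngtdm_features(u)
  expect_equal(unname(nu["ngt_coarseness"]), 1e6)

  idx <- array(0L, c(4, 4, 4))
  for (k in 1:4) for (j in 1:4) for (i in 1:4) {
    idx[i, j, k] <- 1L + (i + j + k) %% 2L
  }
  nc <- ngtdm_features(glv_from_levels(idx))
  expect_lt(unname(nc["ngt_coarseness"]), 1e6)
  expect_gt(unname(nc["ngt_contrast"]), 0)

  # n_i sums to the number of voxels with at least one valid neighbour
  st <- dosiomics:::cpp_ngtdm_stats(idx, 2L)
  expect_equal(sum(st$n), sum(idx > 0))
})

test_that("all texture features match brute-force enumeration on random volumes", {
  for (seed in 1:6) {
    lv <- random_glv(c(5, 5, 5), ng = sample(2:5, 1), p_mask = 0.75,
                     seed = seed)
    glv <- glv_from_levels(lv)
    got <- c(glcm_features(glv), glrlm_features(glv), glszm_features(glv),
             ngtdm_features(glv))
    attributes(got) <- list(names = names(got))
    want <- oracle_texture_features(lv, glv$ng)
    expect_equal(got, want, tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("GLCM probabilities sum to one on arbitrary ROIs", {
  for (seed in c(2, 9)) {
    lv <- random_glv(c(6, 5, 4), ng = 5, seed = seed)
    glv <- glv_from_levels(lv)
    counts <- dosiomics:::cpp_glcm_counts(glv$levels, glv$ng,
                                          dosiomics:::texture_directions())
    if (sum(counts) > 0) {
      expect_equal(sum(counts / sum(counts)), 1)
    }
  }
})
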