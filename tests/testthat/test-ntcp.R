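sim_table <- function(n, seed, beta = 0, p0 = 0.3) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(qlogis(p0) + beta * x))
    noise <- matrix(rnorm(n * 3), n, 3)
    tibble::tibble(y = y, x = x, n1 = noise[, 1], n2 = noise[, 2],
                   n3 = noise[, 3], const = 1)
  })
}

test_that("univariate screen retains signal, skips constants, flags order", {
  tab <- sim_table(100, 1, beta = 3)
  scr <- univariate_screen(tab, "y")
  expect_true("x" %in% scr$feature[scr$retained])
  expect_false("const" %in% scr$feature)
  expect_identical(attr(scr, "skipped"), "const")
  expect_true(!is.unsorted(scr$p_value))

  # feature equal to outcome + tiny noise is retained (power by construction)
  tab2 <- withr::with_seed(2, {
    y <- rbinom(100, 1, 0.4)
    tibble::tibble(y = y, f = y + rnorm(100, 0, 0.05))
  })
  scr2 <- univariate_screen(tab2, "y")
  expect_true(scr2$retained[scr2$feature == "f"])
  expect_true(scr2$separation[scr2$feature == "f"])
})

test_that("Spearman filter keeps the smaller-p member of correlated groups", {
  withr::with_seed(3, {
    x <- rnorm(200)
    y <- rbinom(200, 1, plogis(1.2 * x))
    tab <- tibble::tibble(y = y, a = x, b = x, c = x + rnorm(200, 0, 0.05),
                          d = rnorm(200))
  })
  scr <- univariate_screen(tab, "y", c("a", "b", "c"), alpha = 1)
  red <- spearman_redundancy_filter(tab, scr, rho_max = 0.8)
  # a, b, c are mutually correlated (> 0.9): exactly one survives
  expect_identical(nrow(red), 1L)
  expect_identical(red$feature, scr$feature[which.min(scr$p_value)])

  # duplicated column: the smaller-p one survives
  scr_ab <- univariate_screen(tab, "y", c("a", "b"), alpha = 1)
  red_ab <- spearman_redundancy_filter(tab, scr_ab, rho_max = 0.8)
  expect_identical(nrow(red_ab), 1L)

  # independent features all survive
  withr::with_seed(4, {
    ind <- tibble::tibble(y = rbinom(300, 1, 0.5), u = rnorm(300),
                          v = rnorm(300), w = rnorm(300))
  })
  scr_i <- univariate_screen(ind, "y", c("u", "v", "w"), alpha = 1)
  red_i <- spearman_redundancy_filter(ind, scr_i, rho_max = 0.8)
  expect_identical(nrow(red_i), 3L)
})

test_that("backward elimination keeps a single significant feature unchanged", {
  tab <- sim_table(300, 5, beta = 1.5)
  uni <- glm(y ~ x, family = binomial(), data = tab)
  mod <- backward_elimination(tab, "y", "x")
  expect_identical(mod$features, "x")
  expect_equal(unname(mod$coefficients["x"]), unname(coef(uni)["x"]),
               tolerance = 1e-8)
  expect_equal(unname(mod$odds_ratio), exp(unname(coef(uni)["x"])),
               tolerance = 1e-8)
})

test_that("backward elimination drops noise but keeps planted signal", {
  tab <- sim_table(500, 6, beta = 1.2)
  mod <- backward_elimination(tab, "y", c("x", "n1", "n2", "n3"))
  expect_true("x" %in% mod$features)
  expect_true(all(mod$p_values[mod$features] < 0.05))
})

test_that("all-noise starting sets can reduce to intercept-only", {
  tab <- sim_table(400, 8, beta = 0)
  mod <- backward_elimination(tab, "y", c("n1", "n2", "n3"))
  # whatever survives must look significant; typically nothing does
  expect_true(length(mod$features) == 0 ||
              all(mod$p_values[mod$features] < 0.05))
  mod0 <- backward_elimination(tab, "y", character(0))
  expect_identical(length(mod0$features), 0L)
  expect_equal(unname(plogis(mod0$coefficients[["(Intercept)"]])),
               mean(tab$y))
})

test_that("AUC equals the worked example and brute-force concordance", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)),
               class = "dosiomics_invalid_argument")
  # brute-force equivalence with ties, n <= 50
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(8:50, 1)
      sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      lb <- rbinom(n, 1, 0.5)
      if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    })
    expect_equal(roc_auc(sc, lb)$auc, oracle_auc(sc, lb),
                 info = paste("seed", seed))
  }
})

test_that("Youden cutoff achieves the brute-force maximum J", {
  cut <- youden_cutoff(c(0.2, 0.9), c(0, 1))
  expect_equal(as.numeric(cut), 0.55)
  expect_equal(attr(cut, "J"), 1)
  for (seed in 1:30) {
    withr::with_seed(seed, {
      n <- sample(6:40, 1)
      sc <- round(runif(n), 2)
      lb <- rbinom(n, 1, 0.5)
      if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    })
    cut <- youden_cutoff(sc, lb)
    expect_equal(attr(cut, "J"), oracle_best_youden(sc, lb),
                 info = paste("seed", seed))
  }
  # degenerate: all scores equal
  dg <- youden_cutoff(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(as.numeric(dg), 0.4)
  expect_equal(attr(dg, "J"), 0)
  expect_true(attr(dg, "degenerate"))
})

test_that("balanced accuracy follows its definition", {
  expect_equal(balanced_accuracy(c(0, 0, 1, 1), c(0, 0, 1, 1))$bacc, 1)
  # sens 1, spec 0.5
  expect_equal(balanced_accuracy(c(1, 1, 1, 0), c(1, 1, 0, 0))$bacc, 0.75)
  # always-positive classifier: 0.5 regardless of prevalence
  expect_equal(balanced_accuracy(rep(1, 10),
                                 c(rep(1, 7), rep(0, 3)))$bacc, 0.5)
  expect_error(balanced_accuracy(c(1, 0), c(1, 1)),
               class = "dosiomics_invalid_argument")
})

test_that("DeLong comparison: identical scores give p = 1, separated beat noise", {
  withr::with_seed(10, {
    y <- rbinom(200, 1, 0.4)
    s <- rnorm(200)
  })
  same <- compare_auc(s, s, y)
  expect_equal(same$p_value, 1)
  # a perfect, b random
  withr::with_seed(11, {
    y2 <- rbinom(500, 1, 0.4)
    perfect <- y2 + rnorm(500, 0, 0.01)
    rand <- rnorm(500)
  })
  res <- compare_auc(perfect, rand, y2)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$auc_a, res$auc_b)
})

test_that("Firth fallback engages under complete separation", {
  tab <- tibble::tibble(y = c(rep(0, 15), rep(1, 15)),
                        x = c(rnorm(15, -3), rnorm(15, 3)))
  mod <- backward_elimination(tab, "y", "x")
  expect_true("firth_fallback" %in% mod$flags)
  expect_true(all(is.finite(mod$coefficients)))
  expect_true(all(is.finite(mod$odds_ratio)))
  expect_gt(mod$auc_train, 0.95)
})
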