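test_that("ml_twin_correlation handles degenerate and independent pairs", {
  x <- rnorm(20)
  expect_equal(ml_twin_correlation(x, x, ci = FALSE)$r, 1.0)
  set.seed(5)
  a <- rnorm(4000); b <- rnorm(4000)
  est <- ml_twin_correlation(a, b, ci = FALSE)
  expect_lt(abs(est$r), 0.05)  # ~3 MC SE at n = 4000
  expect_error(ml_twin_correlation(rnorm(2), rnorm(2)), "at least 3")
  expect_error(ml_twin_correlation(c(1, 2, 3), c(NA, NA, NA)),
               "unidentified")
})

test_that("ml_twin_correlation agrees with a grid-search likelihood oracle", {
  set.seed(101)
  r_true <- 0.6
  n <- 50
  z <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, r_true, r_true, 1), 2))
  x1 <- 0.3 + 0.8 * z[, 1]; x2 <- 0.3 + 0.8 * z[, 2]
  est <- ml_twin_correlation(x1, x2, ci = FALSE)

  # independent oracle: two-stage grid maximization of the constrained
  # bivariate-normal likelihood over (mean, sd, r)
  dev_grid <- function(mu, s, r) {
    z1 <- (x1 - mu) / s; z2 <- (x2 - mu) / s
    sum(2 * log(2 * pi) + 2 * log(s^2) + log(1 - r^2) +
        (z1^2 - 2 * r * z1 * z2 + z2^2) / (1 - r^2))
  }
  best <- c(mu = mean(c(x1, x2)), s = sd(c(x1, x2)), r = 0)
  span <- c(mu = 0.3, s = 0.3, r = 0.9)
  for (stage in 1:4) {
    grid <- expand.grid(
      mu = seq(best["mu"] - span["mu"], best["mu"] + span["mu"], len = 21),
      s = seq(max(best["s"] - span["s"], 0.05), best["s"] + span["s"],
              len = 21),
      r = seq(max(best["r"] - span["r"], -0.999),
              min(best["r"] + span["r"], 0.999), len = 21))
    dev <- mapply(dev_grid, grid$mu, grid$s, grid$r)
    best <- unlist(grid[which.min(dev), ])
    span <- span / 8
  }
  expect_equal(est$r, unname(best["r"]), tolerance = 5e-4)
})

test_that("profile intervals for twin correlations behave sensibly", {
  set.seed(77)
  n <- 400; r_true <- 0.5
  z <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, r_true, r_true, 1), 2))
  est95 <- ml_twin_correlation(z[, 1], z[, 2])
  est99 <- ml_twin_correlation(z[, 1], z[, 2], level = 0.99)
  expect_lt(est95$ci_low, est95$r)
  expect_gt(est95$ci_high, est95$r)
  expect_lt(est99$ci_low, est95$ci_low)   # nesting of levels
  expect_gt(est99$ci_high, est95$ci_high)
  expect_gt(est95$ci_low, 0.3)
  expect_lt(est95$ci_high, 0.7)
  # FIML with singletons still works and tightens nothing pathologically
  x1 <- z[, 1]; x2 <- z[, 2]
  x2[1:50] <- NA
  estm <- ml_twin_correlation(x1, x2, ci = FALSE)
  expect_equal(estm$r, est95$r, tolerance = 0.1)
  expect_equal(estm$n_pairs, n)
})

test_that("cross-twin cross-trait correlation matches generating values", {
  # large-group D+E world with the published component structure
  conf <- de_reference_config(group_sizes = c(MZm = 4000L, MZf = 4000L,
                                              DZm = 500L, DZf = 500L,
                                              DOS = 500L),
                              seed = 33, mean_effects = FALSE)
  d <- simulate_twins(conf)
  est <- cross_twin_cross_trait(d, "TE", "SE", "MZ")
  # generating MZ cross-twin cross-trait covariance = rd sqrt(d2_TE d2_SE)
  target <- -0.92 * sqrt(0.76 * 0.70)
  expect_equal(est$r, target, tolerance = 0.03)
  # reduction: trait_j == trait_i gives the plain twin correlation
  est_same <- cross_twin_cross_trait(d, "TE", "TE", "MZ", ci = FALSE)
  dm <- as.data.frame(d)[d$zyg %in% c("MZm", "MZf"), ]
  est_ref <- ml_twin_correlation(dm$TE_1, dm$TE_2, ci = FALSE)
  expect_equal(est_same$r, est_ref$r, tolerance = 1e-6)
})

test_that("independent E-only traits give near-zero cross correlations", {
  gs <- c(MZm = 2000L, MZf = 2000L, DZm = 200L, DZf = 200L, DOS = 200L)
  conf <- sim_config(gs, param_set(list(E = diag(2)),
                                   traits = c("X", "Y")), seed = 44)
  d <- simulate_twins(conf)
  expect_lt(abs(cross_twin_cross_trait(d, "X", "Y", "MZ")$r), 0.05)
  expect_lt(abs(ml_twin_correlation(d$X_1, d$X_2, ci = FALSE)$r), 0.05)
})

test_that("phenotypic correlations are consistent with the generating model", {
  conf <- de_reference_config(group_sizes = small_group_sizes(800),
                              seed = 55, mean_effects = FALSE)
  d <- simulate_twins(conf)
  r <- phenotypic_correlations(d)
  expect_equal(diag(r), c(TE = 1, SE = 1, SY = 1))
  expect_symmetric_psd(r)
  # implied r(TE,SE) = rd sqrt(d2 d2') + re sqrt(e2 e2')
  implied <- -0.92 * sqrt(0.76 * 0.70) + -0.62 * sqrt(0.24 * 0.30)
  expect_equal(r["TE", "SE"], implied, tolerance = 0.03)
  # constructed perfect anticorrelation
  d2 <- as.data.frame(d)
  d2$SY_1 <- -d2$TE_1; d2$SY_2 <- -d2$TE_2
  r2 <- phenotypic_correlations(twin_dataset(d2))
  expect_equal(r2["TE", "SY"], -1)
})

test_that("D+E generation shows the non-additivity correlation signature", {
  conf <- de_reference_config(group_sizes = small_group_sizes(700),
                              seed = 66, mean_effects = FALSE)
  d <- preprocess(simulate_twins(conf))$data
  tab <- twin_correlations(d, cross_trait = FALSE)
  wt <- tab[tab$kind == "within-trait", ]
  for (tr in c("TE", "SE", "SY")) {
    r_mz <- mean(wt$r[wt$trait_i == tr & wt$group %in% c("MZm", "MZf")])
    r_dz <- mean(wt$r[wt$trait_i == tr &
                      wt$group %in% c("DZm", "DZf", "DOS")])
    expect_gt(r_mz, r_dz)          # genetic influence
    expect_lt(r_dz, r_mz / 2 + 0.05)  # dominance signature (MC slack)
  }
})
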