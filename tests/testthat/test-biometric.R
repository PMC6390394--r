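test_that("component covariance equals brute-force summation", {
  expect_equal(component_covariance(diag(3)), diag(3))
  # rank-1 common factor: correlation 1 between the traits
  L <- matrix(c(0.7, 0, 0.7, 0), 2, 2, byrow = TRUE)
  S <- component_covariance(L)
  expect_equal(S[1, 2] / sqrt(S[1, 1] * S[2, 2]), 1)
  # random lower-triangular L vs elementwise sum_k L[i,k] L[j,k]
  set.seed(12)
  for (rep in 1:5) {
    L <- matrix(rnorm(16), 4, 4)
    L[upper.tri(L)] <- 0
    S <- component_covariance(L)
    O <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      O[i, j] <- O[i, j] + L[i, k] * L[j, k]
    expect_equal(S, O, tolerance = 1e-12)
  }
  expect_error(component_covariance(matrix(1, 2, 2)), "lower-triangular")
})

test_that("pair covariance reproduces closed-form univariate values", {
  p <- param_set(list(A = matrix(sqrt(0.4), 1, 1),
                      D = matrix(sqrt(0.3), 1, 1),
                      E = matrix(sqrt(0.3), 1, 1)), traits = "TE")
  mz <- pair_covariance(p, "MZf")
  dz <- pair_covariance(p, "DZm")
  expect_equal(mz[1, 2], 0.7)                     # a2 + d2
  expect_equal(dz[1, 2], 0.5 * 0.4 + 0.25 * 0.3)  # 0.275
  expect_equal(diag(mz), c(1, 1))
  # E-only: no cross-twin covariance anywhere
  pe <- param_set(list(E = diag(2)), traits = c("X", "Y"))
  for (g in c("MZm", "DZf", "DOS"))
    expect_equal(pair_covariance(pe, g)[1:2, 3:4], matrix(0, 2, 2))
})

test_that("pair covariance matches a generative simulation oracle", {
  # brute force: draw shared/unique component scores with the classical
  # cross-twin correlations, independently of pair_covariance internals
  set.seed(2024)
  L_D <- matrix(c(0.8, 0, 0, -0.3, 0.6, 0, 0.2, 0.1, 0.5), 3, 3,
                byrow = TRUE)
  L_E <- matrix(c(0.5, 0, 0, 0.1, 0.4, 0, -0.2, 0.2, 0.6), 3, 3,
                byrow = TRUE)
  p <- param_set(list(D = L_D, E = L_E))
  n <- 2e5
  draw <- function(alpha_d) {
    gs <- matrix(rnorm(3 * n), n)          # shared genetic factors
    g1 <- sqrt(alpha_d) * gs + sqrt(1 - alpha_d) * matrix(rnorm(3 * n), n)
    g2 <- sqrt(alpha_d) * gs + sqrt(1 - alpha_d) * matrix(rnorm(3 * n), n)
    x1 <- g1 %*% t(L_D) + matrix(rnorm(3 * n), n) %*% t(L_E)
    x2 <- g2 %*% t(L_D) + matrix(rnorm(3 * n), n) %*% t(L_E)
    cov(cbind(x1, x2))
  }
  expect_equal(draw(1), pair_covariance(p, "MZm"), tolerance = 0.03,
               ignore_attr = TRUE)
  expect_equal(draw(0.25), pair_covariance(p, "DZf"), tolerance = 0.03,
               ignore_attr = TRUE)
  for (g in c("MZm", "DZm", "DOS")) {
    expect_symmetric_psd(pair_covariance(p, g))
  }
})

test_that("FIML -2LL equals the analytic Gaussian likelihood", {
  conf <- de_reference_config(group_sizes = small_group_sizes(60), seed = 9,
                              mean_effects = FALSE)
  d <- simulate_twins(conf)
  spec <- model_spec(c("TE", "SE", "SY"), drop = list(A = "all"))
  params <- conf$params
  got <- fiml_minus2ll(d, params, spec)
  # independent oracle: per-pair multivariate-normal density
  oracle <- 0
  dd <- as.data.frame(d)
  cols <- c("TE_1", "SE_1", "SY_1", "TE_2", "SE_2", "SY_2")
  for (i in seq_len(nrow(dd))) {
    x <- as.numeric(dd[i, cols])
    Sig <- pair_covariance(params, dd$zyg[i])
    oracle <- oracle + 6 * log(2 * pi) + determinant(Sig)$modulus[1] +
      drop(x %*% solve(Sig, x))
  }
  expect_equal(got, oracle, tolerance = 1e-8)
  # additivity: duplicating every family doubles -2LL
  d2 <- twin_dataset(rbind(as.data.frame(d), as.data.frame(d)))
  expect_equal(fiml_minus2ll(d2, params, spec), 2 * got, tolerance = 1e-8)
})

test_that("a pair with one twin missing contributes its marginal likelihood", {
  conf <- de_reference_config(group_sizes = c(MZm = 10L), seed = 13,
                              mean_effects = FALSE)
  d <- as.data.frame(simulate_twins(conf))
  d[1, c("TE_2", "SE_2", "SY_2")] <- NA
  d <- twin_dataset(d)
  spec <- model_spec(c("TE", "SE", "SY"), drop = list(A = "all"))
  params <- conf$params
  got <- fiml_minus2ll(d, params, spec)
  # oracle: complete pairs by 6-variate density + row 1 by 3-variate marginal
  Sig <- pair_covariance(params, "MZm")
  cols <- c("TE_1", "SE_1", "SY_1", "TE_2", "SE_2", "SY_2")
  oracle <- 0
  for (i in 2:nrow(d)) {
    x <- as.numeric(as.data.frame(d)[i, cols])
    oracle <- oracle + 6 * log(2 * pi) + determinant(Sig)$modulus[1] +
      drop(x %*% solve(Sig, x))
  }
  S3 <- Sig[1:3, 1:3]
  x1 <- as.numeric(as.data.frame(d)[1, cols[1:3]])
  oracle <- oracle + 3 * log(2 * pi) + determinant(S3)$modulus[1] +
    drop(x1 %*% solve(S3, x1))
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("saturated exchangeable covariance attains the closed-form -2LL", {
  # univariate MZ-only data; the twin-order-symmetric MLE is the symmetrized
  # scatter, and the minimized -2LL is n (p log 2pi + log|S*| + p)
  set.seed(17)
  n <- 300
  z <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, .6, .6, 1), 2))
  d <- twin_dataset(data.frame(
    family_id = paste0("f", 1:n), zyg = "MZf", sex1 = "F", sex2 = "F",
    age = 20, TE_1 = z[, 1], TE_2 = z[, 2]))
  S <- crossprod(cbind(z[, 1], z[, 2])) / n
  v <- (S[1, 1] + S[2, 2]) / 2; cc <- S[1, 2]
  Sstar <- matrix(c(v, cc, cc, v), 2)
  # representable as A+E with a^2 = c, e^2 = v - c
  p <- param_set(list(A = matrix(sqrt(cc), 1, 1),
                      E = matrix(sqrt(v - cc), 1, 1)), traits = "TE")
  spec <- model_spec("TE", components = c("A", "E"))
  expect_equal(fiml_minus2ll(d, p, spec),
               n * (2 * log(2 * pi) + log(det(Sstar)) + 2),
               tolerance = 1e-8)
})

test_that("univariate fits recover generating components", {
  # pure D+E world at the reference trait-1 magnitude
  d <- simulate_twins(univ_config(0, 0.76, 0.24, 300, seed = 19))
  prep <- preprocess(d)$data
  f <- fit_twin_model(prep, model_spec("TE", components = c("D", "E")))
  expect_true(f$converged)
  d2 <- standardized_components(f)["D", 1]
  expect_equal(d2, 0.76, tolerance = 0.08)  # ~3 MC SE at 1500 pairs
  expect_equal(f$aic, f$minus2LL + 2 * f$n_params)

  # E-only world: genetic estimates collapse to the boundary
  de <- simulate_twins(univ_config(0, 0, 1, 300, seed = 23))
  prepe <- preprocess(de)$data
  fe_full <- fit_twin_model(prepe, model_spec("TE"))
  fe_null <- fit_twin_model(prepe, model_spec("TE",
                                              drop = list(A = "all",
                                                          D = "all")))
  props <- standardized_components(fe_full)
  expect_lt(props["genetic", 1], 0.1)
  cmp <- compare_models(fe_full, fe_null)
  expect_gt(cmp$p_value, 0.05)  # dropping absent genetics is retained
})

test_that("model comparison arithmetic and edge cases", {
  fake <- function(m2ll, k) structure(
    list(minus2LL = m2ll, n_params = k, aic = m2ll + 2 * k),
    class = "twin_fit")
  same <- compare_models(fake(100, 5), fake(100, 5))
  expect_equal(same$delta_minus2LL, 0)
  expect_equal(same$delta_df, 0L)
  expect_equal(same$p_value, 1)
  cmp <- compare_models(fake(100, 5), fake(103.84, 4))
  expect_equal(cmp$p_value, 0.05, tolerance = 0.001)
  expect_equal(cmp$delta_aic, 1.84, tolerance = 1e-10)
  expect_error(compare_models(fake(100, 4), fake(99, 5)), "more free")
})

test_that("profile deviance interval is exact for a Gaussian mean", {
  set.seed(29)
  n <- 100; sigma <- 2
  x <- rnorm(n, 1, sigma)
  obj <- function(th) sum((x - th[1])^2) / sigma^2  # known-variance deviance
  ci <- profile_ci_deviance(obj, mean(x), 1)
  se <- sigma / sqrt(n)
  expect_equal(as.numeric(ci),
               mean(x) + c(-1, 1) * qnorm(0.975) * se, tolerance = 1e-6)
  ci99 <- profile_ci_deviance(obj, mean(x), 1, level = 0.99)
  expect_lt(ci99[1], ci[1])
  expect_gt(ci99[2], ci[2])
})

test_that("profile_ci brackets a variance proportion in a univariate fit", {
  d <- simulate_twins(univ_config(0, 0.76, 0.24, 150, seed = 37))
  prep <- preprocess(d)$data
  f <- fit_twin_model(prep, model_spec("TE", components = c("D", "E")),
                      n_restarts = 1)
  ci <- profile_ci(f, target_proportion("D", 1), target_range = c(0, 1))
  expect_lt(ci[1], 0.76)
  expect_gt(ci[2], attr(ci, "estimate") )
  expect_true(ci[1] < attr(ci, "estimate"))
  expect_gt(ci[2] - ci[1], 0.01)
  expect_lt(ci[2] - ci[1], 0.3)
})

test_that("analytic FIML gradient matches numerical differentiation", {
  conf <- de_reference_config(group_sizes = small_group_sizes(40), seed = 41,
                              mean_effects = FALSE, missing_rate = 0.15)
  d <- simulate_twins(conf)
  for (sp in list(model_spec(c("TE", "SE", "SY")),
                  model_spec(c("TE", "SE", "SY"),
                             sex_limitation = "general"))) {
    stats <- twinkit:::pair_suffstats(d, sp$traits)
    layout <- twinkit:::spec_layout(sp)
    ob <- twinkit:::build_objective(stats, sp, layout)
    set.seed(43)
    th <- twinkit:::moment_start(stats, sp) + runif(nrow(layout), -.05, .05)
    th <- pmin(pmax(th, layout$lower + 0.02), layout$upper - 0.02)
    gn <- vapply(seq_along(th), function(i) {
      h <- 1e-6
      tp <- th; tp[i] <- th[i] + h
      tm <- th; tm[i] <- th[i] - h
      (ob$fn(tp) - ob$fn(tm)) / (2 * h)
    }, 0)
    expect_equal(ob$gr(th), gn, tolerance = 1e-5)
  }
})
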