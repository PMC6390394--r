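test_that("skewness matches the adjusted Fisher-Pearson formula", {
  # independent oracle: direct evaluation of G1 = sqrt(n(n-1))/(n-2) g1
  g1_oracle <- function(x) {
    n <- length(x); m <- mean(x)
    g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
    sqrt(n * (n - 1)) / (n - 2) * g1
  }
  expect_equal(skewness(c(-1, 0, 1)), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), g1_oracle(c(0, 0, 0, 1)))
  expect_equal(skewness(c(0, 0, 0, 1)), 2)  # exact for this sample
  set.seed(42)
  for (i in 1:5) {
    x <- rgamma(50, shape = 2)
    expect_equal(skewness(x), g1_oracle(x))
    expect_equal(skewness(-x), -skewness(x))  # antisymmetry
  }
  expect_error(skewness(rep(1, 10)), "constant")
  expect_error(skewness(c(1, 2)), "at least 3")
})

test_that("sqrt transform is monotone, bounded and reduces positive skew", {
  expect_equal(sqrt_transform(0.25), 0.5)
  expect_equal(sqrt_transform(c(0, 1)), c(0, 1))  # fixed points
  expect_error(sqrt_transform(-0.1), "non-negative")
  set.seed(7)
  x <- runif(400)^2  # right-skewed in [0,1]
  y <- sqrt_transform(x)
  expect_identical(order(x), order(y))  # exact rank preservation
  expect_lt(abs(skewness(y)), abs(skewness(x)))
})

test_that("residualize removes sex/age structure and is idempotent", {
  set.seed(31)
  n <- 600
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- runif(n, 11, 29)
  # known mean structure
  y <- 0.5 * (sex == "M") + 0.03 * age + rnorm(n)
  r <- residualize(y, sex, age)
  expect_equal(mean(r), 0, tolerance = 1e-10)
  expect_equal(sd(r), 1, tolerance = 1e-10)
  # orthogonality to all five design columns
  X <- cbind(1, sex == "M", age, (sex == "M") * age, age^2)
  expect_lt(max(abs(crossprod(X, r))) / n, 1e-10)
  # sex difference removed
  expect_lt(abs(mean(r[sex == "M"]) - mean(r[sex == "F"])), 1e-10)
  # idempotence
  r2 <- residualize(as.numeric(r), sex, age)
  expect_equal(as.numeric(r2), as.numeric(r), tolerance = 1e-8)
  # exact linear function of the design -> all-zero residuals
  r3 <- residualize(3 * age, sex, age, standardize = FALSE)
  expect_lt(max(abs(r3)), 1e-10)
  # trait independent of covariates: the mean model explains ~nothing
  y4 <- rnorm(n)
  r4 <- residualize(y4, sex, age, standardize = FALSE)
  fitted4 <- y4 - as.numeric(r4)
  expect_lt(var(fitted4) / var(y4), 0.03)
  expect_gt(cor(as.numeric(r4), y4 - mean(y4)), 0.98)
})

test_that("residualize flags collinear designs and missing covariates", {
  set.seed(8)
  y <- rnorm(30)
  expect_warning(residualize(y, rep("F", 30), rep(20, 30)), "collinear")
  expect_error(residualize(y, c(NA, rep("F", 29)), rep(20, 30)), "missing")
})

test_that("preprocess applies the transform where skewness demands it", {
  conf <- de_reference_config(group_sizes = small_group_sizes(250),
                              seed = 21, skew_transform = "square")
  d <- simulate_twins(conf)
  p <- preprocess(d)
  tb <- p$report$table
  # squared-CDF world: all three traits start clearly right-skewed
  expect_true(all(tb$skew_before > 0.5))
  expect_true(all(tb$transform == "sqrt"))
  expect_true(all(abs(tb$skew_after) < abs(tb$skew_before)))
  # residualized scores are standardized per trait
  for (tr in traits(p$data)) {
    v <- c(p$data[[paste0(tr, "_1")]], p$data[[paste0(tr, "_2")]])
    expect_equal(mean(v), 0, tolerance = 1e-8)
    expect_equal(sd(v), 1, tolerance = 1e-3)
  }
  # per-trait override wins over the threshold rule
  p2 <- preprocess(d, transform = list(TE = "none"))
  expect_equal(p2$report$table$transform[p2$report$table$trait == "TE"],
               "none")
  # Gaussian world: nothing is transformed
  d3 <- simulate_twins(de_reference_config(
    group_sizes = small_group_sizes(250), seed = 22))
  p3 <- preprocess(d3)
  expect_true(all(p3$report$table$transform == "none"))
})

test_that("preprocess report serializes to JSON", {
  d <- simulate_twins(univ_config(0.4, 0.3, 0.3, 40, seed = 3,
                                  mean_effects = TRUE))
  p <- preprocess(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocess_report(p$report, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$threshold, 0.5)
  expect_equal(parsed$traits$trait, "TE")
})
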