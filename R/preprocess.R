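# Trait preparation: skewness, square-root transform, sex/age adjustment.

#' Sample skewness (adjusted Fisher--Pearson)
#'
#' The bias-adjusted standardized third moment
#' \deqn{G_1 = \frac{\sqrt{n(n-1)}}{n-2}\, \frac{m_3}{m_2^{3/2}},}
#' where \eqn{m_k} is the k-th central sample moment — the default reported
#' by most statistics packages.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return Skewness (dimensionless).
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) validation_error("skewness needs at least 3 non-missing values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) validation_error("skewness undefined for a constant sample")
  m3 <- mean((x - m)^3)
  sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
}

#' Square-root transformation for positively skewed [0,1] scores
#'
#' @param x numeric vector in `[0, 1]` (NAs allowed).
#' @return `sqrt(x)`, elementwise; strictly order-preserving.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    validation_error("sqrt_transform requires non-negative input")
  sqrt(x)
}

#' Residualize a trait on sex and age
#'
#' Ordinary least-squares adjustment on the individual-level design
#' \{1, sex, age, sex x age, age^2\}, with residuals returned standardized
#' (mean 0, unit variance) so downstream variance components are directly
#' interpretable as proportions. Rows with a missing trait get `NA`
#' residuals; rows with a non-missing trait must have complete covariates.
#' A rank-deficient design (e.g. single-sex data) is reduced by `lm` with a
#' warning.
#'
#' @param y numeric trait values, one per individual.
#' @param sex `"M"`/`"F"` per individual.
#' @param age age in years (shared within a pair, repeated per individual).
#' @param standardize scale residuals to unit variance (default `TRUE`).
#' @return Numeric residuals with attribute `coefficients` (the fitted mean
#'   model).
#' @export
residualize <- function(y, sex, age, standardize = TRUE) {
  ok <- !is.na(y)
  if (any(is.na(sex[ok])) || any(is.na(age[ok])))
    validation_error("missing sex/age for rows with observed trait values")
  d <- data.frame(y = y, sex = factor(sex, levels = c("F", "M")), age = age)
  two_sexes <- length(unique(sex[ok])) > 1L
  age_varies <- stats::sd(age[ok]) > 0
  form <- if (two_sexes && age_varies) y ~ sex + age + sex:age + I(age^2)
    else if (age_varies) y ~ age + I(age^2)
    else if (two_sexes) y ~ sex
    else y ~ 1
  full_rank <- if (two_sexes && age_varies) 5L else if (age_varies) 3L
    else if (two_sexes) 2L else 1L
  fit <- stats::lm(form, data = d, na.action = stats::na.exclude)
  if (!(two_sexes && age_varies) || fit$rank < full_rank)
    warning("collinear sex/age design; reduced mean model used")
  r <- as.numeric(stats::residuals(fit))
  if (standardize) {
    s <- stats::sd(r, na.rm = TRUE)
    if (is.na(s) || s == 0) validation_error("residuals have zero variance")
    r <- (r - mean(r, na.rm = TRUE)) / s
  }
  attr(r, "coefficients") <- stats::coef(fit)
  r
}

#' Prepare a twin dataset for biometric model fitting
#'
#' Runs the standard preparation chain on each trait, pooling both members
#' of every pair: (1) assess skewness; (2) square-root transform traits whose
#' absolute skewness exceeds `threshold` (or as forced per trait via
#' `transform`); (3) regress out sex, age, sex x age and age^2; (4)
#' standardize. Twin non-independence is ignored in the mean regression —
#' only point estimates of the mean model are used, never its standard
#' errors.
#'
#' @param data a `twin_dataset`.
#' @param threshold absolute-skewness cutoff for the square-root transform
#'   (default 0.5).
#' @param transform optional named list/vector of per-trait overrides,
#'   `"sqrt"` or `"none"`.
#' @param standardize standardize residuals (default `TRUE`).
#' @return List with `data` (a new `twin_dataset` of residualized scores) and
#'   `report` (a `preprocess_report`: per-trait skewness before/after,
#'   transform applied, and mean-model coefficients).
#' @export
preprocess <- function(data, threshold = 0.5, transform = NULL,
                       standardize = TRUE) {
  trs <- traits(data)
  out <- as.data.frame(data)
  n <- nrow(out)
  rows <- list()
  coefs <- list()
  for (tr in trs) {
    c1 <- paste0(tr, "_1"); c2 <- paste0(tr, "_2")
    v <- c(out[[c1]], out[[c2]])
    sk_before <- skewness(v)
    forced <- if (!is.null(transform) && !is.null(transform[[tr]]))
      transform[[tr]] else NA
    apply_sqrt <- if (!is.na(forced)) identical(forced, "sqrt")
      else abs(sk_before) > threshold && sk_before > 0
    if (apply_sqrt) v <- sqrt_transform(v)
    sk_mid <- skewness(v)
    res <- residualize(v, sex = c(out$sex1, out$sex2),
                       age = rep(out$age, 2), standardize = standardize)
    coefs[[tr]] <- attr(res, "coefficients")
    out[[c1]] <- res[seq_len(n)]
    out[[c2]] <- res[n + seq_len(n)]
    rows[[tr]] <- data.frame(trait = tr,
                             transform = if (apply_sqrt) "sqrt" else "none",
                             skew_before = sk_before,
                             skew_after = sk_mid,
                             stringsAsFactors = FALSE)
  }
  report <- structure(list(table = do.call(rbind, rows),
                           coefficients = coefs,
                           threshold = threshold),
                      class = "preprocess_report")
  list(data = twin_dataset(out, traits = trs), report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocessing report (|skewness| threshold ", x$threshold, "):\n",
      sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Serialize a preprocessing report to JSON
#' @param report a `preprocess_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(
    list(threshold = report$threshold,
         traits = report$table,
         coefficients = lapply(report$coefficients, as.list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
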