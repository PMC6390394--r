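# Maximum-likelihood twin correlations and descriptive correlation layers.

correlation_estimate <- function(r, ci, n_pairs, method, minus2ll = NA_real_) {
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], n_pairs = n_pairs,
                 method = method, minus2LL = minus2ll),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("r = %.3f [%.3f, %.3f] (%s, %d pairs)\n",
              x$r, x$ci_low, x$ci_high, x$method, x$n_pairs))
  invisible(x)
}

# -2LL of paired data under a bivariate normal; vectorized over pairs.
# Pairs with one missing member contribute the univariate marginal.
bvn_minus2ll <- function(x1, x2, mu1, mu2, s1, s2, r) {
  both <- !is.na(x1) & !is.na(x2)
  only1 <- !is.na(x1) & is.na(x2)
  only2 <- is.na(x1) & !is.na(x2)
  z1 <- (x1[both] - mu1) / s1
  z2 <- (x2[both] - mu2) / s2
  ll2 <- sum(2 * log(2 * pi) + log(s1^2) + log(s2^2) + log1p(-r^2) +
             (z1^2 - 2 * r * z1 * z2 + z2^2) / (1 - r^2))
  u1 <- (x1[only1] - mu1) / s1
  u2 <- (x2[only2] - mu2) / s2
  ll2 + sum(log(2 * pi) + log(s1^2) + u1^2) +
    sum(log(2 * pi) + log(s2^2) + u2^2)
}

#' Maximum-likelihood twin correlation for one zygosity group
#'
#' Estimates the twin-pair correlation of one trait under a bivariate normal
#' model. For same-sex groups the means and variances are constrained equal
#' across twin order (`equal_moments = TRUE`), which makes the estimate
#' invariant to the arbitrary labelling of twins without double entry; for
#' opposite-sex pairs (male first by convention) moments are free per
#' position. Pairs with one missing member contribute their marginal
#' likelihood (FIML). The confidence interval is profile-likelihood based
#' (deviance increase of the chi-square(1) quantile), computed on the
#' Fisher-z scale internally.
#'
#' @param x1,x2 trait values of twin 1 and twin 2, one element per pair.
#' @param equal_moments constrain means/variances equal across twin order.
#' @param level confidence level (default 0.95).
#' @param ci compute the profile interval (default `TRUE`).
#' @return A `correlation_estimate`.
#' @export
ml_twin_correlation <- function(x1, x2, equal_moments = TRUE, level = 0.95,
                                ci = TRUE) {
  keep <- !(is.na(x1) & is.na(x2))
  x1 <- x1[keep]; x2 <- x2[keep]
  n_pairs <- length(x1)
  if (n_pairs < 3)
    validation_error("need at least 3 pairs with an observed member")
  both <- !is.na(x1) & !is.na(x2)
  if (!any(both))
    validation_error("correlation unidentified: no complete pairs")
  if (sum(both) >= 2 && stats::sd(x1[both] - x2[both]) == 0 &&
      stats::sd(x1[both]) > 0) {
    return(correlation_estimate(1, c(1, 1), n_pairs, "ml_constrained"))
  }
  pooled <- c(x1, x2)
  obj <- if (equal_moments) {
    function(th) bvn_minus2ll(x1, x2, th[1], th[1], exp(th[2]), exp(th[2]),
                              tanh(th[3]))
  } else {
    function(th) bvn_minus2ll(x1, x2, th[1], th[2], exp(th[3]), exp(th[4]),
                              tanh(th[5]))
  }
  r0 <- stats::cor(x1[both], x2[both])
  r0 <- max(min(r0, 0.95), -0.95)
  st <- if (equal_moments)
    c(mean(pooled, na.rm = TRUE), log(stats::sd(pooled, na.rm = TRUE)),
      atanh(r0))
  else c(mean(x1, na.rm = TRUE), mean(x2, na.rm = TRUE),
         log(stats::sd(x1, na.rm = TRUE)), log(stats::sd(x2, na.rm = TRUE)),
         atanh(r0))
  z_i <- length(st)
  fit <- stats::nlminb(st, obj, lower = c(rep(-Inf, z_i - 1), -8),
                       upper = c(rep(Inf, z_i - 1), 8),
                       control = list(rel.tol = 1e-12))
  r_hat <- tanh(fit$par[z_i])
  ci_r <- c(NA_real_, NA_real_)
  if (ci) {
    zci <- profile_ci_deviance(obj, fit$par, z_i, level = level,
                               lower = c(rep(-Inf, z_i - 1), -8),
                               upper = c(rep(Inf, z_i - 1), 8))
    ci_r <- tanh(zci)
  }
  correlation_estimate(r_hat, ci_r, n_pairs, "ml_constrained",
                       fit$objective)
}

#' Cross-twin cross-trait correlation
#'
#' Correlation between one twin's trait i and the cotwin's trait j within a
#' zygosity class, estimated under a 4-variate normal model constrained to be
#' invariant to twin order: means and variances equal across positions,
#' within-trait cross-twin covariances symmetric, and a single cross-twin
#' cross-trait covariance shared by both orderings. On complete data this
#' constrained MLE equals the twin-order-symmetrized sample covariance; with
#' missing cells it is obtained numerically by FIML. The MZ version of this
#' correlation, compared with its DZ counterpart, is the classical
#' descriptive signal of genetic trait overlap.
#'
#' @param data a `twin_dataset` (typically residualized).
#' @param trait_i,trait_j trait names; if equal, the estimate reduces to
#'   [ml_twin_correlation()] on the pooled class.
#' @param zygosity_class `"MZ"` (MZm + MZf) or `"DZ"` (DZm + DZf and, by
#'   default, DOS).
#' @param include_dos count opposite-sex pairs in the DZ class.
#' @param level,ci as in [ml_twin_correlation()]; the interval profiles the
#'   cross correlation with all other moments free.
#' @return A `correlation_estimate`.
#' @export
cross_twin_cross_trait <- function(data, trait_i, trait_j,
                                   zygosity_class = c("MZ", "DZ"),
                                   include_dos = TRUE, level = 0.95,
                                   ci = FALSE) {
  zygosity_class <- match.arg(zygosity_class)
  groups <- if (zygosity_class == "MZ") c("MZm", "MZf")
    else c("DZm", "DZf", if (include_dos) "DOS")
  d <- as.data.frame(data)[data$zyg %in% groups, , drop = FALSE]
  if (identical(trait_i, trait_j)) {
    return(ml_twin_correlation(d[[paste0(trait_i, "_1")]],
                               d[[paste0(trait_i, "_2")]],
                               level = level, ci = ci))
  }
  Y <- cbind(d[[paste0(trait_i, "_1")]], d[[paste0(trait_j, "_1")]],
             d[[paste0(trait_i, "_2")]], d[[paste0(trait_j, "_2")]])
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  n_pairs <- nrow(Y)
  if (n_pairs < 3) validation_error("need at least 3 usable pairs")

  # theta = (mu_i, mu_j, log v_i, log v_j, c_p, c_i, c_j, z_x)
  sigma_of <- function(th) {
    vi <- exp(th[3]); vj <- exp(th[4])
    cx <- tanh(th[8]) * sqrt(vi * vj)
    m <- matrix(c(vi, th[5], th[6], cx,
                  th[5], vj, cx, th[7],
                  th[6], cx, vi, th[5],
                  cx, th[7], th[5], vj), 4, 4)
    m
  }
  obs <- !is.na(Y)
  pat_key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  pats <- lapply(unique(pat_key), function(k) {
    rows <- which(pat_key == k)
    idx <- which(obs[rows[1], ])
    Yi <- Y[rows, idx, drop = FALSE]
    list(idx = idx, n = length(rows), s = colSums(Yi), S = crossprod(Yi))
  })
  obj <- function(th) {
    Sig <- sigma_of(th)
    mu <- c(th[1], th[2], th[1], th[2])
    ll2 <- 0
    for (p in pats) {
      S <- Sig[p$idx, p$idx, drop = FALSE]
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) return(FIML_PENALTY)
      m <- mu[p$idx]
      Q <- p$S - tcrossprod(p$s, m) - tcrossprod(m, p$s) +
        p$n * tcrossprod(m)
      ll2 <- ll2 + p$n * (length(p$idx) * log(2 * pi) +
                          2 * sum(log(diag(ch)))) +
        sum(chol2inv(ch) * Q)
    }
    ll2
  }
  # start: twin-order-symmetrized pairwise moments
  mu_i <- mean(c(Y[, 1], Y[, 3]), na.rm = TRUE)
  mu_j <- mean(c(Y[, 2], Y[, 4]), na.rm = TRUE)
  vi <- stats::var(c(Y[, 1], Y[, 3]), na.rm = TRUE)
  vj <- stats::var(c(Y[, 2], Y[, 4]), na.rm = TRUE)
  cv <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) 0 else stats::cov(a[ok], b[ok])
  }
  c_p <- (cv(Y[, 1], Y[, 2]) + cv(Y[, 3], Y[, 4])) / 2
  c_i <- cv(Y[, 1], Y[, 3]); c_j <- cv(Y[, 2], Y[, 4])
  c_x <- (cv(Y[, 1], Y[, 4]) + cv(Y[, 2], Y[, 3])) / 2
  r_x0 <- max(min(c_x / sqrt(vi * vj), 0.95), -0.95)
  st <- c(mu_i, mu_j, log(vi), log(vj), 0.9 * c_p, 0.9 * c_i, 0.9 * c_j,
          atanh(r_x0))
  lowerb <- c(rep(-Inf, 7), -8); upperb <- c(rep(Inf, 7), 8)
  fit <- stats::nlminb(st, obj, lower = lowerb, upper = upperb,
                       control = list(rel.tol = 1e-12, eval.max = 3000L))
  r_hat <- tanh(fit$par[8])
  ci_r <- c(NA_real_, NA_real_)
  if (ci) {
    zci <- profile_ci_deviance(obj, fit$par, 8L, level = level,
                               lower = lowerb, upper = upperb)
    ci_r <- tanh(zci)
  }
  correlation_estimate(r_hat, ci_r, n_pairs, "ml_constrained",
                       fit$objective)
}

#' Phenotypic correlations across pooled individuals
#'
#' Pearson correlations between traits over all individuals (both members of
#' every pair, all zygosity groups), pairwise-complete. The descriptive
#' phenotypic layer of a multivariate twin analysis.
#'
#' @param data a `twin_dataset`.
#' @return T x T symmetric correlation matrix with unit diagonal.
#' @export
phenotypic_correlations <- function(data) {
  trs <- traits(data)
  d <- as.data.frame(data)
  M <- sapply(trs, function(tr) c(d[[paste0(tr, "_1")]],
                                  d[[paste0(tr, "_2")]]))
  r <- stats::cor(M, use = "pairwise.complete.obs")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Tidy table of twin correlations per group and trait
#'
#' Runs [ml_twin_correlation()] for every zygosity group x trait cell and,
#' optionally, [cross_twin_cross_trait()] for every trait pair within the MZ
#' and DZ classes, returning a long data frame suitable for export.
#'
#' @param data a `twin_dataset` (typically residualized).
#' @param cross_trait include cross-twin cross-trait rows.
#' @param ci compute profile intervals (slower).
#' @param level confidence level.
#' @return Data frame: `group`, `trait_i`, `trait_j`, `kind`, `r`, `ci_low`,
#'   `ci_high`, `n_pairs`.
#' @export
twin_correlations <- function(data, cross_trait = TRUE, ci = FALSE,
                              level = 0.95) {
  trs <- traits(data)
  d <- as.data.frame(data)
  rows <- list()
  add <- function(group, ti, tj, kind, est) {
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, trait_i = ti, trait_j = tj, kind = kind,
      r = est$r, ci_low = est$ci_low, ci_high = est$ci_high,
      n_pairs = est$n_pairs, stringsAsFactors = FALSE)
  }
  for (g in ZYG_LEVELS) {
    dg <- d[d$zyg == g, , drop = FALSE]
    if (nrow(dg) < 3) next
    for (tr in trs) {
      est <- ml_twin_correlation(dg[[paste0(tr, "_1")]],
                                 dg[[paste0(tr, "_2")]],
                                 equal_moments = g != "DOS",
                                 level = level, ci = ci)
      add(g, tr, tr, "within-trait", est)
    }
  }
  if (cross_trait && length(trs) > 1) {
    for (cls in c("MZ", "DZ")) {
      for (i in seq_along(trs)) for (j in seq_along(trs)) {
        if (i >= j) next
        est <- cross_twin_cross_trait(data, trs[i], trs[j], cls,
                                      level = level, ci = ci)
        add(cls, trs[i], trs[j], "cross-trait", est)
      }
    }
  }
  rp <- phenotypic_correlations(data)
  n_ind <- 2L * nrow(d)
  for (i in seq_along(trs)) for (j in seq_along(trs)) {
    if (i >= j) next
    add("all", trs[i], trs[j], "phenotypic",
        correlation_estimate(rp[i, j], c(NA, NA), n_ind, "pearson_pooled"))
  }
  do.call(rbind, rows)
}
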