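# Standardized variance components and component correlations.

#' Standardized variance proportions per trait
#'
#' For each trait, the fraction of total model-implied variance attributable
#' to each active component, `prop_X(t) = Sigma_X[t,t] / Sigma_total[t,t]`,
#' plus the total genetic share (A + D, broad heritability). Proportions sum
#' to one by construction.
#'
#' @param x a `twin_fit` or a `param_set`.
#' @param sex loading set: `"b"` without sex limitation, else `"m"`/`"f"`.
#' @return Matrix with one row per component (plus `"genetic"`) and one
#'   column per trait.
#' @export
standardized_components <- function(x, sex = "b") {
  params <- if (inherits(x, "twin_fit")) x$params else x
  comps <- names(params$L)
  t_n <- nrow(params$L[[1]][[1]])
  sig <- lapply(comps, function(k)
    diag(tcrossprod(param_loading(params, k, sex)))[seq_len(t_n)])
  names(sig) <- comps
  total <- Reduce(`+`, sig)
  if (any(total <= 0)) validation_error("zero total variance for a trait")
  out <- do.call(rbind, lapply(sig, function(v) v / total))
  gen <- colSums(out[rownames(out) %in% c("A", "D"), , drop = FALSE])
  out <- rbind(out, genetic = gen)
  colnames(out) <- params$traits %||% paste0("T", seq_len(t_n))
  out
}

#' Component correlation matrix
#'
#' Rescales a component covariance to a correlation matrix,
#' `r_X[i,j] = Sigma_X[i,j] / sqrt(Sigma_X[i,i] Sigma_X[j,j])` — the genetic
#' (or environmental) correlation between traits within that component. A
#' value of 1 means the two traits share all of that component's factors.
#' Traits whose component variance is at (or numerically indistinguishable
#' from) the zero boundary have no defined correlation; their rows/columns
#' are returned as `NA` and flagged, rather than silently reported as zero.
#'
#' @param sigma component covariance matrix (e.g. from
#'   [component_covariance()]).
#' @param tol variance threshold below which the correlation is undefined.
#' @return Correlation matrix with unit diagonal (where defined) and an
#'   `undefined_traits` attribute.
#' @export
component_correlation <- function(sigma, tol = 1e-8) {
  d <- diag(sigma)
  bad <- d < tol
  r <- matrix(NA_real_, nrow(sigma), ncol(sigma),
              dimnames = dimnames(sigma))
  if (any(!bad)) {
    s <- sqrt(d[!bad])
    r[!bad, !bad] <- sigma[!bad, !bad, drop = FALSE] / tcrossprod(s)
  }
  if (any(bad)) structure(r, undefined_traits = which(bad)) else r
}

#' Derived statistics of a fitted twin model
#'
#' Packages the quantities usually reported from a multivariate twin
#' analysis: per-trait standardized variance proportions (including total
#' genetic) and the component correlation matrices (r_g for A, r_d for D,
#' r_c for C, r_e for E). With `ci = TRUE`, profile-likelihood intervals are
#' attached for every defined proportion and off-diagonal correlation
#' (computationally heavy: one constrained reoptimization sweep per bound).
#'
#' @param fit a converged `twin_fit`.
#' @param sex loading set under sex limitation (`"b"`, `"m"` or `"f"`).
#' @param ci compute profile-likelihood intervals (default `FALSE`).
#' @param level confidence level for the intervals.
#' @return A `derived_stats` object: `proportions`, `correlations` (named
#'   list by component), optional `ci`.
#' @export
derived_stats <- function(fit, sex = "b", ci = FALSE, level = 0.95) {
  params <- fit$params
  props <- standardized_components(params, sex = sex)
  cors <- lapply(names(params$L), function(k) {
    S <- tcrossprod(param_loading(params, k, sex))
    dimnames(S) <- list(params$traits, params$traits)
    component_correlation(S)
  })
  names(cors) <- names(params$L)
  out <- list(proportions = props, correlations = cors,
              traits = params$traits, sex = sex)
  if (ci) {
    t_n <- length(params$traits)
    ci_list <- list()
    for (tt in seq_len(t_n)) {
      key <- paste0("genetic_", params$traits[tt])
      ci_list[[key]] <- profile_ci(fit, target_proportion("genetic", tt, sex),
                                   level = level, target_range = c(0, 1))
    }
    for (k in names(cors)) {
      for (i in seq_len(t_n - 1)) for (j in (i + 1):t_n) {
        if (is.na(cors[[k]][i, j])) next
        key <- sprintf("r_%s_%s_%s", tolower(k), params$traits[i],
                       params$traits[j])
        ci_list[[key]] <- profile_ci(
          fit, target_component_correlation(k, i, j, sex),
          level = level, target_range = c(-1, 1))
      }
    }
    out$ci <- ci_list
    out$level <- level
  }
  structure(out, class = "derived_stats")
}

#' @export
print.derived_stats <- function(x, digits = 3, ...) {
  cat("standardized variance proportions",
      if (x$sex != "b") paste0(" (sex ", x$sex, ")"), ":\n", sep = "")
  print(round(x$proportions, digits))
  for (k in names(x$correlations)) {
    cat(sprintf("r_%s:\n", tolower(k)))
    print(round(x$correlations[[k]], digits))
  }
  if (!is.null(x$ci)) {
    cat(sprintf("%g%% profile-likelihood intervals:\n", 100 * x$level))
    for (k in names(x$ci))
      cat(sprintf("  %s: [%.3f, %.3f]\n", k, x$ci[[k]][1], x$ci[[k]][2]))
  }
  invisible(x)
}

#' Phenotypic correlations implied by derived statistics
#'
#' Consistency check between the descriptive and model layers: the implied
#' phenotypic correlation sums each component's correlation weighted by the
#' geometric mean of its variance shares,
#' \eqn{r_P[i,j] = \sum_X r_X[i,j] \sqrt{p_X[i] p_X[j]}}. Undefined
#' component correlations (zero component variance) contribute nothing.
#'
#' @param derived a `derived_stats` object.
#' @return T x T correlation matrix.
#' @export
implied_phenotypic_correlation <- function(derived) {
  t_n <- length(derived$traits)
  out <- diag(t_n)
  dimnames(out) <- list(derived$traits, derived$traits)
  for (i in seq_len(t_n)) for (j in seq_len(t_n)) {
    if (i == j) next
    acc <- 0
    for (k in names(derived$correlations)) {
      r <- derived$correlations[[k]][i, j]
      if (is.na(r)) next
      acc <- acc + r * sqrt(derived$proportions[k, i] *
                            derived$proportions[k, j])
    }
    out[i, j] <- acc
  }
  out
}
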