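# Numerical maximum-likelihood fitting, model comparison, profile intervals.

# Moment-based starting values: solve the component covariances from pooled
# MZ / DZ-class cross-twin blocks, project to PSD, and take Cholesky factors.
# Falls back to an equal-variance-split start when the data are too sparse.
moment_start <- function(stats, spec) {
  t_n <- stats$t_n
  full_k <- 2L * t_n
  pool <- function(groups) {
    S <- matrix(0, full_k, full_k); n <- 0
    for (cell in stats$cells) {
      if (cell$group %in% groups && cell$k == full_k) {
        S <- S + cell$S; n <- n + cell$n
      }
    }
    if (n < 3) return(NULL)
    S / n
  }
  C_mz <- pool(c("MZm", "MZf"))
  C_dz <- pool(c("DZm", "DZf", "DOS"))
  blocks <- function(C) {
    i1 <- seq_len(t_n); i2 <- t_n + i1
    W <- (C[i1, i1] + C[i2, i2]) / 2
    B <- (C[i1, i2] + t(C[i1, i2])) / 2
    list(W = (W + t(W)) / 2, B = B)
  }
  gen <- setdiff(spec$components, "E")
  gen <- gen[!vapply(gen, comp_dropped, TRUE, spec = spec)]
  Sig <- list()
  ok <- !is.null(C_mz) && !is.null(C_dz)
  if (ok) {
    mz <- blocks(C_mz); dz <- blocks(C_dz)
    W <- (mz$W + dz$W) / 2
    if (setequal(gen, c("A", "D"))) {
      Sig$A <- 4 * dz$B - mz$B
      Sig$D <- 2 * mz$B - 4 * dz$B
    } else if (setequal(gen, c("A", "C"))) {
      Sig$A <- 2 * (mz$B - dz$B)
      Sig$C <- 2 * dz$B - mz$B
    } else if (setequal(gen, "A")) {
      Sig$A <- (mz$B + 0.5 * dz$B) / 1.25
    } else if (setequal(gen, "D")) {
      Sig$D <- (mz$B + 0.25 * dz$B) / 1.0625
    } else if (setequal(gen, "C")) {
      Sig$C <- (mz$B + dz$B) / 2
    } else if (length(gen)) {
      ok <- FALSE
    }
    if (ok) Sig$E <- W - Reduce(`+`, Sig, matrix(0, t_n, t_n))
  }
  layout <- spec_layout(spec)
  theta <- numeric(nrow(layout))
  m_active <- length(gen) + 1L
  for (k in seq_len(nrow(layout))) {
    if (layout$what[k] == "rg_dos") {
      theta[k] <- 0.8 * layout$upper[k]
    } else if (layout$row[k] == layout$col[k]) {
      theta[k] <- sqrt(1 / m_active)
    }
  }
  if (ok) {
    for (comp in names(Sig)) {
      if (comp_dropped(spec, comp)) next
      floor_ev <- if (comp == "E") 0.05 else 0.01
      M <- psd_project(Sig[[comp]], floor_ev)
      L <- if (comp_diag_only(spec, comp))
        diag(sqrt(pmax(diag(M), floor_ev)), t_n)
      else t(chol(M))
      for (sx in spec_sexsets(spec)) {
        sel <- layout$what == "loading" & layout$comp == comp &
          layout$sex == sx
        theta[sel] <- L[cbind(layout$row[sel], layout$col[sel])]
      }
    }
  }
  pmin(pmax(theta, layout$lower), layout$upper)
}

psd_project <- function(M, floor_ev = 0) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  v <- pmax(e$values, floor_ev)
  (e$vectors %*% (v * t(e$vectors)) + t(e$vectors %*% (v * t(e$vectors)))) / 2
}

# deterministic jitter pattern for restart k (no RNG state involved)
jitter_theta <- function(theta, layout, k) {
  j <- sin(seq_along(theta) * 7.13 + 3.7 * k)
  diag_el <- layout$what == "loading" & layout$row == layout$col
  th <- theta
  th[diag_el] <- th[diag_el] * (1 + 0.5 * j[diag_el])
  th[!diag_el] <- th[!diag_el] + 0.25 * j[!diag_el]
  pmin(pmax(th, layout$lower + 1e-6), layout$upper - 1e-6)
}

#' Fit a biometric twin model by FIML
#'
#' Minimizes the raw-data -2 log-likelihood over Cholesky loadings with a
#' bounded quasi-Newton optimizer (`nlminb`), restarting from a moment-based
#' start plus deterministically jittered alternatives and keeping the best
#' solution. Twin likelihoods can be multimodal near variance boundaries, so
#' restarts are cheap insurance. Diagonal loadings within `1e-6` of zero are
#' reported as exact zeros and flagged as boundary solutions.
#'
#' @param data a `twin_dataset` of residualized, standardized scores (see
#'   [preprocess()]).
#' @param spec a `model_spec`.
#' @param n_restarts optimizer restarts (default 3: one moment-based start
#'   plus two jittered).
#' @param free_means additionally estimate one mean per trait (shared across
#'   groups and twins) instead of fixing means at zero; a sensitivity switch.
#' @param group_floor warn when any present group has fewer pairs (default
#'   30).
#' @param control passed to [stats::nlminb()] (merged over tight defaults).
#' @return A `twin_fit`: estimates (`params`), `minus2LL`, `n_params`, `aic`,
#'   `converged`, `gradient_norm`, boundary flags, and the sufficient
#'   statistics needed to profile the likelihood later.
#' @export
fit_twin_model <- function(data, spec, n_restarts = 3L, free_means = FALSE,
                           group_floor = 30L, control = list()) {
  stats <- pair_suffstats(data, spec$traits)
  counts <- group_counts(data)
  low <- counts[counts > 0 & counts < group_floor]
  if (length(low))
    warning("small zygosity groups (possible weak identification): ",
            paste(names(low), low, sep = "=", collapse = ", "))
  layout <- spec_layout(spec)
  t_n <- length(spec$traits)
  n_free <- nrow(layout) + if (free_means) t_n else 0L
  lower <- c(layout$lower, if (free_means) rep(-10, t_n))
  upper <- c(layout$upper, if (free_means) rep(10, t_n))

  obj <- build_objective(stats, spec, layout, free_means)

  ctrl <- utils::modifyList(
    list(eval.max = 5000L, iter.max = 2000L, rel.tol = 1e-10), control)
  base_start <- c(moment_start(stats, spec), if (free_means) rep(0, t_n))
  best <- NULL
  used <- 0L
  for (k in seq_len(max(1L, n_restarts))) {
    st <- if (k == 1L) base_start else
      c(jitter_theta(base_start[seq_len(nrow(layout))], layout, k - 1L),
        if (free_means) rep(0, t_n))
    res <- tryCatch(
      stats::nlminb(st, obj$fn, gradient = obj$gr, lower = lower,
                    upper = upper, control = ctrl),
      error = function(e) NULL)
    # restarting nlminb from its own endpoint resets the Hessian
    # approximation, which unsticks slow crawls along flat A/D ridges
    polish <- 0L
    while (!is.null(res) && res$convergence != 0 &&
           !grepl("singular convergence", res$message %||% "") &&
           polish < 2L) {
      res2 <- tryCatch(
        stats::nlminb(res$par, obj$fn, gradient = obj$gr, lower = lower,
                      upper = upper, control = ctrl),
        error = function(e) NULL)
      if (is.null(res2)) break
      res <- res2
      polish <- polish + 1L
    }
    used <- used + 1L
    if (!is.null(res) &&
        (is.null(best) || res$objective < best$objective)) best <- res
  }
  if (is.null(best))
    twinkit_error("no optimizer restart produced a solution",
                  "twinkit_convergence_error")

  th <- best$par
  pin <- seq_len(nrow(layout))[layout$lower == 0 &
                               abs(th[seq_len(nrow(layout))]) < 1e-6]
  boundary <- layout$name[pin]
  th[pin] <- 0
  minus2ll <- obj$fn(th)
  if (minus2ll > best$objective + 1e-6) {  # pinning hurt; keep raw optimum
    th <- best$par
    minus2ll <- best$objective
  }
  grad <- num_gradient(obj$fn, th, lower, upper)
  params <- unpack_params(th[seq_len(nrow(layout))], spec, layout)
  params$traits <- spec$traits
  structure(list(
    spec = spec, layout = layout, theta = th, params = params,
    mu = if (free_means) th[nrow(layout) + seq_len(t_n)],
    minus2LL = minus2ll, n_params = n_free,
    aic = minus2ll + 2 * n_free,
    converged = (best$convergence == 0 ||
                 grepl("singular convergence", best$message %||% "")) &&
      minus2ll < FIML_PENALTY,
    n_restarts_used = used,
    gradient_norm = sqrt(sum(grad^2)),
    boundary = boundary,
    n_pairs = sum(counts), stats = stats, free_means = free_means),
    class = "twin_fit")
}

num_gradient <- function(f, x, lower, upper) {
  g <- numeric(length(x))
  f0 <- f(x)
  for (i in seq_along(x)) {
    if (x[i] - lower[i] < 1e-7 || upper[i] - x[i] < 1e-7) next
    h <- 1e-6 * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

#' @export
print.twin_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("-2LL = %.3f on %d free parameters; AIC = %.3f%s\n",
              x$minus2LL, x$n_params, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$boundary))
    cat("boundary estimates at zero:", paste(x$boundary, collapse = ", "),
        "\n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' The difference in -2 log-likelihood between a model and a constrained
#' submodel is referred to a chi-square distribution on the difference in
#' free parameters; a significant change (conventionally p < .05) rejects
#' the submodel. Boundary constraints (variances fixed at zero) make the
#' naive chi-square conservative; the naive reference is used deliberately,
#' matching long-standing twin-modelling practice.
#'
#' @param full fitted parent model (`twin_fit`).
#' @param nested fitted constrained submodel (`twin_fit`); structural
#'   nesting is the caller's responsibility, the parameter counts are
#'   checked.
#' @return List with `delta_minus2LL`, `delta_df`, `p_value`, `delta_aic`.
#' @export
compare_models <- function(full, nested) {
  if (nested$n_params > full$n_params)
    validation_error("`nested` has more free parameters than `full`")
  delta <- nested$minus2LL - full$minus2LL
  if (delta < 0) {
    if (delta < -1e-3)
      warning("nested model fit better than full (", round(delta, 4),
              "); check convergence")
    delta <- 0
  }
  df <- full$n_params - nested$n_params
  p <- if (df == 0L) as.numeric(delta <= 1e-8)
    else stats::pchisq(delta, df, lower.tail = FALSE)
  structure(list(delta_minus2LL = delta, delta_df = df, p_value = p,
                 delta_aic = nested$aic - full$aic),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "LRT: delta(-2LL) = %.3f on %d df, p = %.4g; delta(AIC) = %.3f\n",
    x$delta_minus2LL, x$delta_df, x$p_value, x$delta_aic))
  invisible(x)
}

#' Profile-likelihood interval for one coordinate of a deviance function
#'
#' Low-level engine: for a deviance (-2 log-likelihood) `objective` over a
#' parameter vector, the `level` interval for coordinate `index` collects all
#' values whose profiled deviance (other coordinates re-minimized) lies
#' within the chi-square(1) quantile of the minimum. For a quadratic
#' deviance this reproduces the Wald interval exactly.
#'
#' @param objective function of the full parameter vector returning -2LL.
#' @param theta minimizer of `objective`.
#' @param index coordinate to profile.
#' @param level confidence level (default 0.95).
#' @param lower,upper box bounds for all coordinates (recycled).
#' @param step initial bracketing step (default from the profile curvature).
#' @return `c(low, high)` with attribute `at_boundary` (logical length 2).
#' @export
profile_ci_deviance <- function(objective, theta, index, level = 0.95,
                                lower = -Inf, upper = Inf, step = NULL) {
  p <- length(theta)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  crit <- stats::qchisq(level, 1)
  free <- setdiff(seq_len(p), index)
  prof <- function(t0) {
    if (!length(free)) return(objective(replace(theta, index, t0)))
    fn <- function(v) {
      th <- theta; th[free] <- v; th[index] <- t0
      objective(th)
    }
    stats::nlminb(theta[free], fn, lower = lower[free], upper = upper[free],
                  control = list(rel.tol = 1e-12))$objective
  }
  dev_min <- prof(theta[index])
  if (is.null(step)) {
    h <- 1e-3 * (1 + abs(theta[index]))
    curv <- max((prof(theta[index] + h) + prof(theta[index] - h) -
                 2 * dev_min) / h^2, 1e-8)
    step <- sqrt(2 * crit / curv) / 4
  }
  bound1 <- function(dir) {
    lim <- if (dir > 0) upper[index] else lower[index]
    t_prev <- theta[index]
    t_cur <- theta[index] + dir * step
    for (i in 1:40) {
      if ((dir > 0 && t_cur >= lim) || (dir < 0 && t_cur <= lim)) {
        if (prof(lim) - dev_min < crit) return(c(lim, TRUE))
        t_cur <- lim
        break
      }
      if (prof(t_cur) - dev_min >= crit) break
      t_prev <- t_cur
      t_cur <- t_cur + dir * step * 2^i
    }
    root <- stats::uniroot(function(t0) prof(t0) - dev_min - crit,
                           lower = min(t_prev, t_cur),
                           upper = max(t_prev, t_cur),
                           tol = step / 1e4)$root
    c(root, FALSE)
  }
  lo <- bound1(-1); hi <- bound1(+1)
  structure(c(lo[1], hi[1]),
            at_boundary = c(lo[2] > 0.5, hi[2] > 0.5))
}

#' Profile-likelihood confidence interval for a fitted-model quantity
#'
#' Likelihood-based interval for a scalar function of the parameters of a
#' fitted twin model — a raw loading, a standardized variance proportion, or
#' a component correlation — obtained by constrained re-optimization: the
#' bound is where the -2LL minimized subject to `target(params) = t` rises
#' by the chi-square(1) quantile. The constraint is enforced by a two-stage
#' quadratic penalty with warm starts, which is accurate to well below the
#' interval widths of interest and remains valid near parameter-space
#' boundaries (where delta-method intervals break down). A bound that runs
#' into the natural range of the target (e.g. a correlation hitting 1) is
#' reported at that limit and flagged via the `at_boundary` attribute.
#'
#' @param fit a converged `twin_fit`.
#' @param target function of a `param_set` returning a scalar; see
#'   [target_component_correlation()] and [target_proportion()].
#' @param level confidence level (default 0.95).
#' @param target_range natural range of the target (default unbounded).
#' @param step initial bracketing step for the bound search.
#' @return `c(low, high)` with attribute `at_boundary`.
#' @export
profile_ci <- function(fit, target, level = 0.95,
                       target_range = c(-Inf, Inf), step = 0.02) {
  if (!fit$converged)
    twinkit_error("profile_ci requires a converged fit",
                  "twinkit_convergence_error")
  spec <- fit$spec; layout <- fit$layout; stats <- fit$stats
  t_n <- length(spec$traits)
  n_lay <- nrow(layout)
  lower <- c(layout$lower, if (fit$free_means) rep(-10, t_n))
  upper <- c(layout$upper, if (fit$free_means) rep(10, t_n))
  ob <- build_objective(stats, spec, layout, fit$free_means)
  obj0 <- ob$fn
  gval <- function(th) target(unpack_params(th[seq_len(n_lay)], spec, layout))
  gval_grad <- function(th) {
    g <- numeric(length(th))
    for (i in seq_len(n_lay)) {
      h <- 1e-6 * (1 + abs(th[i]))
      tp <- th; tp[i] <- th[i] + h
      tm <- th; tm[i] <- th[i] - h
      g[i] <- (gval(tp) - gval(tm)) / (2 * h)
    }
    g
  }
  crit <- stats::qchisq(level, 1)
  dev_min <- fit$minus2LL
  t_hat <- gval(fit$theta)
  cache <- new.env(parent = emptyenv())
  cache$th <- fit$theta
  prof <- function(t0) {
    th <- cache$th
    for (lambda in c(1e4, 1e7)) {
      pen <- function(v) obj0(v) + lambda * (gval(v) - t0)^2
      pen_gr <- function(v)
        ob$gr(v) + 2 * lambda * (gval(v) - t0) * gval_grad(v)
      th <- stats::nlminb(th, pen, gradient = pen_gr,
                          lower = lower, upper = upper,
                          control = list(rel.tol = 1e-11,
                                         eval.max = 3000L,
                                         iter.max = 1000L))$par
    }
    cache$th <- th
    obj0(th)
  }
  bound1 <- function(dir) {
    cache$th <- fit$theta
    lim <- if (dir > 0) target_range[2] else target_range[1]
    t_prev <- t_hat
    t_cur <- t_hat + dir * step
    hit <- FALSE
    for (i in 1:40) {
      if (is.finite(lim) &&
          ((dir > 0 && t_cur >= lim) || (dir < 0 && t_cur <= lim))) {
        if (prof(lim) - dev_min < crit) return(c(lim, TRUE))
        t_cur <- lim
        break
      }
      if (prof(t_cur) - dev_min >= crit) break
      t_prev <- t_cur
      t_cur <- t_cur + dir * step * 2^i
    }
    root <- stats::uniroot(function(t0) prof(t0) - dev_min - crit,
                           lower = min(t_prev, t_cur),
                           upper = max(t_prev, t_cur),
                           tol = max(step / 100, 1e-5))$root
    c(root, FALSE)
  }
  lo <- bound1(-1); hi <- bound1(+1)
  structure(c(lo[1], hi[1]),
            at_boundary = c(lo[2] > 0.5, hi[2] > 0.5),
            estimate = t_hat)
}

#' Target helpers for [profile_ci()]
#'
#' `target_component_correlation(comp, i, j)` extracts the component
#' correlation \eqn{\Sigma_X[i,j]/\sqrt{\Sigma_X[i,i]\Sigma_X[j,j]}};
#' `target_proportion(comp, trait)` the standardized variance proportion
#' (use `comp = "genetic"` for A + D). `sex` selects the loading set under
#' sex limitation.
#'
#' @param comp component letter, or `"genetic"` (proportions only).
#' @param i,j trait indices (or names).
#' @param trait trait index (or name).
#' @param sex `"b"` (no sex limitation), `"m"` or `"f"`.
#' @return A function of a `param_set`, for use as `target`.
#' @export
target_component_correlation <- function(comp, i, j, sex = "b") {
  force(comp); force(i); force(j); force(sex)
  function(params) {
    ii <- trait_index(params, i); jj <- trait_index(params, j)
    S <- tcrossprod(param_loading(params, comp, sex))
    S[ii, jj] / sqrt(S[ii, ii] * S[jj, jj])
  }
}

#' @rdname target_component_correlation
#' @export
target_proportion <- function(comp, trait, sex = "b") {
  force(comp); force(trait); force(sex)
  function(params) {
    tt <- trait_index(params, trait)
    tot <- 0; num <- 0
    for (k in names(params$L)) {
      v <- tcrossprod(param_loading(params, k, sex))[tt, tt]
      tot <- tot + v
      if (k == comp || (comp == "genetic" && k %in% c("A", "D")))
        num <- num + v
    }
    num / tot
  }
}

trait_index <- function(params, i) {
  if (is.character(i)) match(i, params$traits) else as.integer(i)
}
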