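# Full-information maximum likelihood over raw twin pairs.
#
# The Gaussian -2 log-likelihood of mean-zero pair data decomposes over
# (zygosity group x missingness pattern) cells. Each cell is summarized once
# by its count, sum vector and raw scatter matrix, after which every
# likelihood evaluation reduces to one Cholesky factorization per cell —
# this is what makes repeated fitting and profiling cheap in pure R.

FIML_PENALTY <- 1e10

pair_suffstats <- function(data, traits = NULL) {
  traits <- traits %||% attr(data, "traits")
  cols <- c(paste0(traits, "_1"), paste0(traits, "_2"))
  out <- list()
  for (g in ZYG_LEVELS) {
    X <- as.matrix(as.data.frame(data)[data$zyg == g, cols, drop = FALSE])
    if (!nrow(X)) next
    obs <- !is.na(X)
    keep <- rowSums(obs) > 0
    X <- X[keep, , drop = FALSE]
    obs <- obs[keep, , drop = FALSE]
    if (!nrow(X)) next
    key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
    for (k in unique(key)) {
      rows <- which(key == k)
      idx <- which(obs[rows[1], ])
      Xi <- X[rows, idx, drop = FALSE]
      out[[length(out) + 1L]] <- list(
        group = g, idx = idx, k = length(idx), n = length(rows),
        s = colSums(Xi), S = crossprod(Xi))
    }
  }
  structure(list(cells = out, traits = traits, t_n = length(traits)),
            class = "pair_suffstats")
}

# -2LL given per-group 2T x 2T covariances and an optional per-trait mean
# vector (applied to both twins). Returns a large penalty when any observed
# submatrix is not positive definite.
neg2ll_cells <- function(stats, sigma_by_group, mu = NULL) {
  ll2 <- 0
  mu_full <- if (!is.null(mu)) rep(mu, 2) else NULL
  for (cell in stats$cells) {
    Sg <- sigma_by_group[[cell$group]]
    Sig <- Sg[cell$idx, cell$idx, drop = FALSE]
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(FIML_PENALTY)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    Sc <- cell$S
    if (!is.null(mu_full)) {
      m <- mu_full[cell$idx]
      Sc <- Sc - tcrossprod(cell$s, m) - tcrossprod(m, cell$s) +
        cell$n * tcrossprod(m)
    }
    ll2 <- ll2 + cell$n * (cell$k * log(2 * pi) + logdet) + sum(Sinv * Sc)
  }
  ll2
}

sigma_by_group <- function(params, spec, groups = ZYG_LEVELS) {
  out <- list()
  for (g in groups) out[[g]] <- pair_covariance(params, g, spec)
  out
}

# Compiled FIML objective: precomputes theta -> loading-matrix index maps
# and collapses zygosity groups whose implied covariance is identical (all
# MZ groups; all DZ-coefficient groups when loadings are not sex-specific
# and rg_dos is fixed), so each evaluation costs a handful of small matrix
# products and Cholesky factorizations.
build_objective <- function(stats, spec, layout, free_means = FALSE) {
  t_n <- stats$t_n
  n_lay <- nrow(layout)
  sexsets <- spec_sexsets(spec)
  comps <- intersect(COMP_ORDER, unique(layout$comp[layout$what == "loading"]))
  fill <- list()
  L0 <- list()
  for (comp in comps) {
    L0[[comp]] <- list()
    for (sx in sexsets) {
      sel <- which(layout$what == "loading" & layout$comp == comp &
                   layout$sex == sx)
      L0[[comp]][[sx]] <- matrix(0, t_n, t_n)
      fill[[length(fill) + 1L]] <- list(
        comp = comp, sx = sx, th_idx = sel,
        pos = cbind(layout$row[sel], layout$col[sel]))
    }
  }
  rg_idx <- which(layout$what == "rg_dos")
  rg_comp <- if (length(rg_idx)) layout$comp[rg_idx] else ""
  groups <- unique(vapply(stats$cells, `[[`, "", "group"))
  simple <- identical(sexsets, "b") && !length(rg_idx)
  gkey <- vapply(groups, function(g) {
    if (simple) (if (g %in% c("MZm", "MZf")) "MZ" else "DZ") else g
  }, "")
  keys <- unique(gkey)
  gsex <- function(g) {
    if (identical(sexsets, "b")) c("b", "b")
    else switch(g, MZm = c("m", "m"), DZm = c("m", "m"),
                MZf = c("f", "f"), DZf = c("f", "f"), DOS = c("m", "f"))
  }
  keyinfo <- lapply(keys, function(k) {
    g <- groups[match(k, gkey)]
    list(sexes = gsex(g),
         alpha = zygosity_coefficients(g),
         dos = g == "DOS")
  })
  names(keyinfo) <- keys
  cells <- lapply(stats$cells, function(cell) {
    cell$key <- gkey[[cell$group]]
    cell$const <- cell$n * cell$k * log(2 * pi)
    cell
  })
  genetic <- setdiff(comps, "E")
  i1 <- seq_len(t_n); i2 <- t_n + i1

  forward <- function(th) {
    L <- L0
    for (f in fill) L[[f$comp]][[f$sx]][f$pos] <- th[f$th_idx]
    W <- lapply(sexsets, function(sx) {
      Reduce(`+`, lapply(comps, function(cp) tcrossprod(L[[cp]][[sx]])))
    })
    names(W) <- sexsets
    sig <- lapply(keyinfo, function(ki) {
      B <- matrix(0, t_n, t_n)
      for (cp in genetic) {
        a <- unname(ki$alpha[cp])
        if (ki$dos && length(rg_idx) && cp == rg_comp) a <- th[rg_idx]
        B <- B + a * (L[[cp]][[ki$sexes[1]]] %*% t(L[[cp]][[ki$sexes[2]]]))
      }
      rbind(cbind(W[[ki$sexes[1]]], B), cbind(t(B), W[[ki$sexes[2]]]))
    })
    list(L = L, sig = sig,
         mu_full = if (free_means) rep(th[n_lay + seq_len(t_n)], 2))
  }

  fn <- function(th) {
    fw <- forward(th)
    total <- 0
    for (cell in cells) {
      Sig <- fw$sig[[cell$key]][cell$idx, cell$idx, drop = FALSE]
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(FIML_PENALTY)
      Sc <- cell$S
      if (!is.null(fw$mu_full)) {
        m <- fw$mu_full[cell$idx]
        Sc <- Sc - tcrossprod(cell$s, m) - tcrossprod(m, cell$s) +
          cell$n * tcrossprod(m)
      }
      total <- total + cell$const + cell$n * 2 * sum(log(diag(ch))) +
        sum(chol2inv(ch) * Sc)
    }
    total
  }

  # Analytic gradient. With G = n * Sigma^-1 - Sigma^-1 Sc Sigma^-1
  # accumulated per covariance key (scattered over missingness patterns),
  # the chain rule through Sigma = [[W1, B], [B', W2]] gives, per component
  # loading L: 2 G11 L1 (+ 2 a G12 L2) for the twin-1 set and
  # 2 G22 L2 (+ 2 a G12' L1) for the twin-2 set; d/da = 2 sum(G12 * L1 L2').
  gr <- function(th) {
    fw <- forward(th)
    G <- lapply(keys, function(k) matrix(0, 2 * t_n, 2 * t_n))
    names(G) <- keys
    gmu <- if (free_means) numeric(2 * t_n)
    for (cell in cells) {
      Sig <- fw$sig[[cell$key]][cell$idx, cell$idx, drop = FALSE]
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(numeric(length(th)))
      Sinv <- chol2inv(ch)
      Sc <- cell$S
      if (!is.null(fw$mu_full)) {
        m <- fw$mu_full[cell$idx]
        Sc <- Sc - tcrossprod(cell$s, m) - tcrossprod(m, cell$s) +
          cell$n * tcrossprod(m)
        gmu[cell$idx] <- gmu[cell$idx] +
          2 * (Sinv %*% (cell$n * m - cell$s))
      }
      Gc <- cell$n * Sinv - Sinv %*% Sc %*% Sinv
      G[[cell$key]][cell$idx, cell$idx] <-
        G[[cell$key]][cell$idx, cell$idx] + Gc
    }
    acc <- lapply(comps, function(cp) {
      out <- lapply(sexsets, function(sx) matrix(0, t_n, t_n))
      names(out) <- sexsets
      out
    })
    names(acc) <- comps
    g_rg <- 0
    for (k in keys) {
      ki <- keyinfo[[k]]
      G11 <- G[[k]][i1, i1]; G22 <- G[[k]][i2, i2]; G12 <- G[[k]][i1, i2]
      s1 <- ki$sexes[1]; s2 <- ki$sexes[2]
      for (cp in comps) {
        L1 <- fw$L[[cp]][[s1]]; L2 <- fw$L[[cp]][[s2]]
        c1 <- 2 * (G11 %*% L1)
        c2 <- 2 * (G22 %*% L2)
        if (cp != "E") {
          a <- unname(ki$alpha[cp])
          if (ki$dos && length(rg_idx) && cp == rg_comp) {
            a <- th[rg_idx]
            g_rg <- g_rg + 2 * sum(G12 * (L1 %*% t(L2)))
          }
          c1 <- c1 + 2 * a * (G12 %*% L2)
          c2 <- c2 + 2 * a * (t(G12) %*% L1)
        }
        acc[[cp]][[s1]] <- acc[[cp]][[s1]] + c1
        acc[[cp]][[s2]] <- acc[[cp]][[s2]] + c2
      }
    }
    g <- numeric(length(th))
    for (f in fill) g[f$th_idx] <- acc[[f$comp]][[f$sx]][f$pos]
    if (length(rg_idx)) g[rg_idx] <- g_rg
    if (free_means)
      g[n_lay + seq_len(t_n)] <- gmu[i1] + gmu[i2]
    g
  }

  list(fn = fn, gr = gr)
}

#' FIML -2 log-likelihood of a twin dataset under a biometric model
#'
#' Sums the multivariate-normal -2 log-likelihood over pairs, restricting
#' each pair's contribution to its observed cells (raw-data / full-information
#' likelihood); a pair with one twin entirely missing contributes the
#' marginal likelihood of the observed twin. Means are fixed at zero, as
#' appropriate for residualized, standardized scores, unless `mu` is given.
#'
#' @param data a `twin_dataset` (residualized scores).
#' @param params a `param_set` consistent with `spec`.
#' @param spec a `model_spec`.
#' @param mu optional per-trait mean vector.
#' @param stats precomputed sufficient statistics (internal reuse).
#' @return -2LL (a large penalized value, flagged by a warning, when the
#'   implied covariance is not positive definite).
#' @export
fiml_minus2ll <- function(data, params, spec, mu = NULL, stats = NULL) {
  stats <- stats %||% pair_suffstats(data, spec$traits)
  groups <- unique(vapply(stats$cells, `[[`, "", "group"))
  val <- neg2ll_cells(stats, sigma_by_group(params, spec, groups), mu)
  if (val >= FIML_PENALTY)
    warning("model-implied covariance not positive definite; ",
            "penalized likelihood returned")
  val
}
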