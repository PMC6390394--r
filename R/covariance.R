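# Model-implied covariance matrices.

#' Component covariance from a Cholesky loading matrix
#'
#' \eqn{\Sigma_X = L_X L_X^\top}: symmetric and positive semi-definite by
#' construction, the standard guarantee of the Cholesky parameterization of
#' multivariate variance-component models.
#'
#' @param L lower-triangular loading matrix.
#' @return T x T covariance matrix.
#' @export
component_covariance <- function(L) {
  tcrossprod(check_lower_tri(L))
}

#' Model-implied covariance of a twin pair
#'
#' Builds the 2T x 2T covariance of the stacked trait vectors of twin 1 and
#' twin 2 for one zygosity group. Within-twin blocks are the sum of the
#' active component covariances (sex-appropriate under sex limitation); the
#' cross-twin block weights each component by its zygosity coefficient
#' (see [zygosity_coefficients()]). For opposite-sex pairs with sex-specific
#' loadings the cross block is \eqn{\alpha_X L_X^{(m)} L_X^{(f)\top}}, and a
#' free `rg_dos` replaces the genetic weight.
#'
#' @param params a `param_set`.
#' @param group zygosity group label.
#' @param spec optional `model_spec` (used for the `rg_dos` attachment rule);
#'   inferred from `params` when omitted.
#' @return 2T x 2T symmetric positive semi-definite matrix, twin 1 traits
#'   first.
#' @export
pair_covariance <- function(params, group, spec = NULL) {
  group <- match.arg(group, ZYG_LEVELS)
  comps <- names(params$L)
  t_n <- nrow(params$L[[1]][[1]])
  sexes <- switch(group,
                  MZm = c("m", "m"), DZm = c("m", "m"),
                  MZf = c("f", "f"), DZf = c("f", "f"),
                  DOS = c("m", "f"))
  alpha <- zygosity_coefficients(group)
  rg_comp <- NULL
  if (!is.null(params$rg_dos)) {
    rg_comp <- if ("A" %in% comps) "A" else if ("D" %in% comps) "D" else NULL
    if (!is.null(spec) && spec$dos_rg_free) {
      lay <- spec_layout(spec)
      rg_comp <- lay$comp[lay$what == "rg_dos"]
    }
  }
  W1 <- W2 <- B <- matrix(0, t_n, t_n)
  for (comp in comps) {
    L1 <- param_loading(params, comp, sexes[1])
    L2 <- param_loading(params, comp, sexes[2])
    W1 <- W1 + tcrossprod(L1)
    W2 <- W2 + tcrossprod(L2)
    if (comp == "E") next
    a <- unname(alpha[comp])
    if (group == "DOS" && identical(comp, rg_comp)) a <- params$rg_dos
    B <- B + a * (L1 %*% t(L2))
  }
  rbind(cbind(W1, B), cbind(t(B), W2))
}
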