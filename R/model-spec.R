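# Model specification and Cholesky-loading parameter sets.

COMP_ORDER <- c("A", "C", "D", "E")

#' Specify a biometric twin model
#'
#' Defines which variance components are estimated, whether loadings differ
#' by sex, and which Cholesky paths are constrained to zero. Components are
#' drawn from A (additive genetic), C (shared environment), D (non-additive
#' genetic) and E (individual-specific environment + error). E is always
#' present; C and D are never fitted jointly, since the classical twin design
#' cannot separate them.
#'
#' Sex limitation: `"none"` uses one loading matrix per component;
#' `"common_effects"` frees separate male and female loadings (quantitative
#' sex differences) with the standard opposite-sex genetic weight; `"general"`
#' additionally frees the opposite-sex genetic correlation `rg_dos`
#' (qualitative sex differences), attached to A on \[0, 0.5\] or, when A is
#' absent, to D on \[0, 0.25\].
#'
#' @param traits character vector of trait names, in model order.
#' @param components subset of `c("A","C","D","E")`; must include `"E"`.
#' @param sex_limitation `"none"`, `"common_effects"` or `"general"`.
#' @param drop named list constraining components: `"cov"` fixes a
#'   component's off-diagonal (cross-trait) loadings to zero, `"all"` removes
#'   the component entirely (e.g. `drop = list(A = "all")` turns ADE into
#'   DE).
#' @param dos_rg_free free opposite-sex genetic correlation; defaults to
#'   `TRUE` only under `"general"` sex limitation.
#' @return A `model_spec`.
#' @examples
#' model_spec(c("TE", "SE", "SY"), components = c("A", "D", "E"))
#' @export
model_spec <- function(traits,
                       components = c("A", "D", "E"),
                       sex_limitation = c("none", "common_effects", "general"),
                       drop = list(),
                       dos_rg_free = NULL) {
  sex_limitation <- match.arg(sex_limitation)
  traits <- as.character(traits)
  if (!length(traits)) validation_error("at least one trait required")
  components <- unique(match.arg(components, COMP_ORDER, several.ok = TRUE))
  if (!"E" %in% components) validation_error("component E is always present")
  if (all(c("C", "D") %in% components))
    validation_error("C and D cannot be fitted jointly in the twin design")
  if (length(drop)) {
    if (is.null(names(drop)) || any(!names(drop) %in% components))
      validation_error("`drop` must be named by active components")
    bad <- !unlist(drop) %in% c("cov", "all")
    if (any(bad)) validation_error("`drop` values must be \"cov\" or \"all\"")
    if (identical(drop[["E"]], "all"))
      validation_error("E cannot be dropped entirely")
  }
  if (is.null(dos_rg_free)) dos_rg_free <- sex_limitation == "general"
  active_genetic <- setdiff(components, "E")
  active_genetic <- active_genetic[
    !vapply(active_genetic, function(k) identical(drop[[k]], "all"), TRUE)]
  if (dos_rg_free && !length(setdiff(active_genetic, "C")))
    validation_error("dos_rg_free requires an active genetic component")
  structure(list(traits = traits,
                 components = COMP_ORDER[COMP_ORDER %in% components],
                 sex_limitation = sex_limitation,
                 drop = drop,
                 dos_rg_free = dos_rg_free),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  dr <- if (length(x$drop))
    paste0(" [drop ", paste(names(x$drop), unlist(x$drop), sep = ":",
                            collapse = ", "), "]") else ""
  cat(sprintf("%s Cholesky model for (%s), sex limitation: %s%s%s\n",
              paste(x$components, collapse = ""),
              paste(x$traits, collapse = ", "),
              x$sex_limitation, dr,
              if (x$dos_rg_free) ", free rg(DOS)" else ""))
  invisible(x)
}

spec_sexsets <- function(spec) {
  if (spec$sex_limitation == "none") "b" else c("m", "f")
}

comp_dropped <- function(spec, comp) identical(spec$drop[[comp]], "all")

comp_diag_only <- function(spec, comp) identical(spec$drop[[comp]], "cov")

# Free-parameter layout: one row per scalar parameter, with box bounds.
# Diagonal loadings are bounded below at 0 (sign convention); the E diagonal
# is kept strictly positive so the implied pair covariance stays PD.
spec_layout <- function(spec) {
  t_n <- length(spec$traits)
  rows <- list()
  for (comp in spec$components) {
    if (comp_dropped(spec, comp)) next
    for (sx in spec_sexsets(spec)) {
      for (j in seq_len(t_n)) {
        for (i in j:t_n) {
          if (i != j && (comp_diag_only(spec, comp))) next
          diag_el <- i == j
          rows[[length(rows) + 1L]] <- data.frame(
            what = "loading", comp = comp, sex = sx, row = i, col = j,
            lower = if (!diag_el) -10 else if (comp == "E") 1e-4 else 0,
            upper = 10, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (spec$dos_rg_free) {
    comp <- if ("A" %in% spec$components && !comp_dropped(spec, "A"))
      "A" else "D"
    rows[[length(rows) + 1L]] <- data.frame(
      what = "rg_dos", comp = comp, sex = "b", row = 0L, col = 0L,
      lower = 0, upper = unname(zygosity_coefficients("DOS")[comp]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$name <- ifelse(out$what == "rg_dos", "rg_dos",
                     sprintf("%s_%s[%d,%d]", out$comp, out$sex,
                             out$row, out$col))
  out
}

#' Number of free parameters of a model specification
#' @param spec a `model_spec`.
#' @return Integer count.
#' @export
n_params <- function(spec) nrow(spec_layout(spec))

#' Assemble a parameter set from loading matrices
#'
#' A `param_set` bundles one lower-triangular Cholesky loading matrix per
#' active component (and per sex under sex limitation) plus, optionally, a
#' free opposite-sex genetic correlation. The component covariance is
#' `L %*% t(L)`, positive semi-definite by construction.
#'
#' @param loadings named list over components; each element either a single
#'   lower-triangular matrix or a list `list(m = , f = )` of per-sex
#'   matrices.
#' @param traits trait names (defaults to `L1`, ... for a T x T matrix).
#' @param rg_dos optional opposite-sex genetic correlation.
#' @return A `param_set`.
#' @export
param_set <- function(loadings, traits = NULL, rg_dos = NULL) {
  if (!length(loadings) || is.null(names(loadings)))
    validation_error("`loadings` must be a named list over components")
  loadings <- lapply(loadings, function(L) {
    if (is.matrix(L)) list(b = check_lower_tri(L))
    else lapply(L, check_lower_tri)
  })
  t_n <- nrow(loadings[[1]][[1]])
  if (is.null(traits)) traits <- paste0("T", seq_len(t_n))
  structure(list(L = loadings[order(match(names(loadings), COMP_ORDER))],
                 traits = traits, rg_dos = rg_dos),
            class = "param_set")
}

check_lower_tri <- function(L) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L) || any(abs(L[upper.tri(L)]) > 1e-12))
    validation_error("loading matrix must be square lower-triangular")
  L
}

unpack_params <- function(theta, spec, layout = spec_layout(spec)) {
  t_n <- length(spec$traits)
  L <- list()
  for (comp in spec$components) {
    if (comp_dropped(spec, comp)) next
    L[[comp]] <- list()
    for (sx in spec_sexsets(spec)) {
      M <- matrix(0, t_n, t_n)
      sel <- layout$what == "loading" & layout$comp == comp & layout$sex == sx
      M[cbind(layout$row[sel], layout$col[sel])] <- theta[sel]
      L[[comp]][[sx]] <- M
    }
  }
  rg <- if (spec$dos_rg_free) theta[layout$what == "rg_dos"] else NULL
  structure(list(L = L, traits = spec$traits, rg_dos = rg),
            class = "param_set")
}

pack_params <- function(params, spec, layout = spec_layout(spec)) {
  theta <- numeric(nrow(layout))
  for (k in seq_len(nrow(layout))) {
    if (layout$what[k] == "rg_dos") {
      theta[k] <- params$rg_dos
    } else {
      M <- param_loading(params, layout$comp[k], layout$sex[k])
      theta[k] <- M[layout$row[k], layout$col[k]]
    }
  }
  theta
}

# loading matrix for a component/sex, falling back to the common set
param_loading <- function(params, comp, sex) {
  Ls <- params$L[[comp]]
  if (is.null(Ls)) return(NULL)
  Ls[[sex]] %||% Ls[["b"]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.param_set <- function(x, ...) {
  cat("param_set over components:", paste(names(x$L), collapse = ", "), "\n")
  for (comp in names(x$L)) for (sx in names(x$L[[comp]])) {
    cat(sprintf("L_%s%s:\n", comp,
                if (sx == "b") "" else paste0(" (", sx, ")")))
    print(round(x$L[[comp]][[sx]], 4))
  }
  if (!is.null(x$rg_dos)) cat("rg_dos:", round(x$rg_dos, 4), "\n")
  invisible(x)
}
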