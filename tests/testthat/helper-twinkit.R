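# Shared fixture builders (everything generated in code; no stored data).

toy_twin_df <- function() {
  data.frame(
    family_id = c("f1", "f2"),
    zyg = c("MZm", "DOS"),
    sex1 = c("M", "M"), sex2 = c("M", "F"),
    age = c(17, 21),
    TE_1 = c(0.40, 0.50), TE_2 = c(0.42, 0.31),
    SE_1 = c(0.30, NA),   SE_2 = c(0.28, 0.35),
    stringsAsFactors = FALSE)
}

# univariate generating world: a2/d2/e2 across all five zygosity groups
univ_config <- function(a2, d2, e2, n_per_group, seed = NULL,
                        mean_effects = FALSE) {
  stopifnot(abs(a2 + d2 + e2 - 1) < 1e-8)
  comps <- list()
  if (a2 > 0) comps$A <- matrix(sqrt(a2), 1, 1)
  if (d2 > 0) comps$D <- matrix(sqrt(d2), 1, 1)
  comps$E <- matrix(sqrt(e2), 1, 1)
  gs <- stats::setNames(rep(n_per_group, 5),
                        c("MZm", "DZm", "MZf", "DZf", "DOS"))
  mm <- if (mean_effects)
    list(TE = c(intercept = 0, sex = 0.25, age = 0.02, age_sex = 0,
                age2 = 0))
  sim_config(gs, param_set(comps, traits = "TE"), mean_model = mm,
             seed = seed)
}

small_group_sizes <- function(n = 120L) {
  stats::setNames(rep(as.integer(n), 5), c("MZm", "DZm", "MZf", "DZf", "DOS"))
}

expect_symmetric_psd <- function(m, tol = 1e-8) {
  expect_equal(m, t(m), tolerance = 1e-10, ignore_attr = TRUE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol)
}
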