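# End-to-end workflow: preprocess -> correlations -> univariate fits ->
# multivariate Cholesky ladder -> model comparison -> derived statistics.

#' Configure an analysis pipeline
#'
#' @param input path to a twin CSV, a `twin_dataset`, or a `sim_config`
#'   (simulated on the fly).
#' @param out_dir output directory (created if needed).
#' @param traits trait names (inferred when possible).
#' @param threshold skewness threshold for the square-root transform.
#' @param ladder multivariate model roster; default mirrors the classical
#'   comparison ladder: full ACE, full ADE, then ADE submodels dropping all
#'   A paths, the D cross-trait covariances, and the E cross-trait
#'   covariances. Each entry is `list(name=, components=, drop=, parent=)`;
#'   nested entries name their parent.
#' @param univariate fit per-trait sex-limitation ACE/ADE models.
#' @param ci compute profile-likelihood intervals for the best model's
#'   derived statistics (slow; default `FALSE`).
#' @param level confidence level.
#' @param seed integer seed applied to simulation input.
#' @param n_restarts optimizer restarts per fit.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir, traits = NULL, threshold = 0.5,
                            ladder = default_ladder(), univariate = TRUE,
                            ci = FALSE, level = 0.95, seed = NULL,
                            n_restarts = 3L) {
  if (!length(ladder)) validation_error("model ladder must be nonempty")
  for (m in ladder) {
    if (!is.null(m$parent) &&
        !m$parent %in% vapply(ladder, `[[`, "", "name"))
      validation_error(paste0("ladder entry ", m$name,
                              " names unknown parent ", m$parent))
  }
  structure(list(input = input, out_dir = out_dir, traits = traits,
                 threshold = threshold, ladder = ladder,
                 univariate = univariate, ci = ci, level = level,
                 seed = seed, n_restarts = n_restarts),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_ladder <- function() {
  list(
    list(name = "ACE_full", components = c("A", "C", "E"), drop = list(),
         parent = NULL),
    list(name = "ADE_full", components = c("A", "D", "E"), drop = list(),
         parent = NULL),
    list(name = "ADE_dropA", components = c("A", "D", "E"),
         drop = list(A = "all"), parent = "ADE_full"),
    list(name = "ADE_dropDcov", components = c("A", "D", "E"),
         drop = list(D = "cov"), parent = "ADE_full"),
    list(name = "ADE_dropEcov", components = c("A", "D", "E"),
         drop = list(E = "cov"), parent = "ADE_full"))
}

log_line <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full twin-analysis pipeline
#'
#' Executes, in order: data loading or simulation, preprocessing
#' (skewness-gated square-root transform, sex/age residualization),
#' descriptive correlations, optional univariate sex-limitation ACE/ADE fits
#' per trait, the multivariate Cholesky model ladder with likelihood-ratio
#' and AIC comparisons, and derived statistics of the best-fitting model
#' (lowest AIC among models not rejected against their parent at p < .05).
#' All artifacts (CSV tables, JSON fit summaries, a JSON-lines run log
#' recording the seed and per-stage timings) are written under `out_dir`;
#' a stage failure aborts with a stage-tagged error, retaining partial
#' outputs.
#'
#' @param config a `pipeline_config`.
#' @return Invisibly, a list with the loaded data, preprocessing report,
#'   correlation table, fit objects, the comparison table, the best model
#'   name and its `derived_stats`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logc <- file(file.path(config$out_dir, "run_log.jsonl"), open = "a")
  on.exit(close(logc), add = TRUE)
  result <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      twinkit_error(paste0("stage ", name, " failed: ", conditionMessage(e)),
                    "twinkit_stage_error"))
    log_line(logc, name, seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }
  log_line(logc, "start", seed = config$seed %||% NA)

  data <- stage("load", {
    inp <- config$input
    if (inherits(inp, "sim_config")) simulate_twins(inp, seed = config$seed)
    else if (inherits(inp, "twin_dataset")) inp
    else read_twin_csv(inp, traits = config$traits)
  })
  result$raw <- data

  prep <- stage("preprocess", preprocess(data, threshold = config$threshold))
  result$preprocess <- prep$report
  result$data <- prep$data
  write_twin_csv(prep$data, file.path(config$out_dir, "residualized.csv"))
  write_preprocess_report(prep$report,
                          file.path(config$out_dir, "preprocess.json"))

  cors <- stage("correlations",
                twin_correlations(prep$data, ci = FALSE))
  result$correlations <- cors
  utils::write.csv(cors, file.path(config$out_dir, "correlations.csv"),
                   row.names = FALSE)

  trs <- traits(prep$data)
  if (config$univariate) {
    result$univariate <- stage("univariate", {
      rows <- list(); fits <- list()
      for (tr in trs) {
        sub <- structure(as.data.frame(prep$data), traits = tr,
                         class = class(prep$data))
        for (comps in list(c("A", "C", "E"), c("A", "D", "E"))) {
          sp <- model_spec(tr, components = comps,
                           sex_limitation = "general")
          f <- fit_twin_model(sub, sp, n_restarts = config$n_restarts)
          nm <- paste0(tr, "_", paste(comps, collapse = ""))
          fits[[nm]] <- f
          rows[[nm]] <- data.frame(
            trait = tr, model = paste(comps, collapse = ""),
            minus2LL = f$minus2LL, n_params = f$n_params, aic = f$aic,
            genetic_m = standardized_components(f, "m")["genetic", 1],
            genetic_f = standardized_components(f, "f")["genetic", 1],
            stringsAsFactors = FALSE)
        }
      }
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(config$out_dir, "univariate.csv"),
                       row.names = FALSE)
      list(table = tab, fits = fits)
    })
  }

  multi <- stage("multivariate", {
    fits <- list()
    rows <- list()
    for (m in config$ladder) {
      sp <- model_spec(trs, components = m$components, drop = m$drop)
      f <- fit_twin_model(prep$data, sp, n_restarts = config$n_restarts)
      fits[[m$name]] <- f
      cmpr <- if (!is.null(m$parent))
        compare_models(fits[[m$parent]], f) else NULL
      rows[[m$name]] <- data.frame(
        model = m$name, parent = m$parent %||% "",
        minus2LL = f$minus2LL, n_params = f$n_params, aic = f$aic,
        delta_chisq = cmpr$delta_minus2LL %||% NA_real_,
        delta_df = cmpr$delta_df %||% NA_integer_,
        p_value = cmpr$p_value %||% NA_real_,
        converged = f$converged, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(config$out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    list(fits = fits, table = tab)
  })
  result$multivariate <- multi

  result$best <- stage("best_model", {
    tab <- multi$table
    # candidate set: the AIC-preferred full model plus every submodel
    # transitively retained (p >= .05 against a retained parent)
    fulls <- tab[tab$parent == "", , drop = FALSE]
    best_full <- fulls$model[which.min(fulls$aic)]
    retained <- best_full
    for (i in seq_len(nrow(tab))) {
      if (tab$parent[i] %in% retained && !is.na(tab$p_value[i]) &&
          tab$p_value[i] >= 0.05)
        retained <- c(retained, tab$model[i])
    }
    cand <- tab[tab$model %in% retained, , drop = FALSE]
    best_name <- cand$model[which.min(cand$aic)]
    fit <- multi$fits[[best_name]]
    ds <- derived_stats(fit, ci = config$ci, level = config$level)
    jsonlite::write_json(
      list(model = best_name, minus2LL = fit$minus2LL, aic = fit$aic,
           proportions = as.data.frame(ds$proportions),
           correlations = lapply(ds$correlations, unclass),
           ci = ds$ci),
      file.path(config$out_dir, "best_model.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    list(name = best_name, fit = fit, derived = ds)
  })

  stage("report", write_markdown_report(result, config))
  log_line(logc, "done")
  invisible(structure(result, class = "pipeline_result"))
}

write_markdown_report <- function(result, config) {
  path <- file.path(config$out_dir, "report.md")
  con <- file(path, open = "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Twin analysis report\n")
  w("Pairs per group: %s\n",
    paste(names(group_counts(result$raw)), group_counts(result$raw),
          sep = "=", collapse = ", "))
  w("## Preprocessing\n")
  tb <- result$preprocess$table
  w("| trait | transform | skew before | skew after |")
  w("|---|---|---|---|")
  for (i in seq_len(nrow(tb)))
    w("| %s | %s | %.3f | %.3f |", tb$trait[i], tb$transform[i],
      tb$skew_before[i], tb$skew_after[i])
  w("\n## Model comparison\n")
  tb <- result$multivariate$table
  w("| model | parent | -2LL | k | AIC | dChi2 | ddf | p |")
  w("|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tb)))
    w("| %s | %s | %.2f | %d | %.2f | %s | %s | %s |",
      tb$model[i], tb$parent[i], tb$minus2LL[i], tb$n_params[i], tb$aic[i],
      ifelse(is.na(tb$delta_chisq[i]), "", sprintf("%.2f",
                                                   tb$delta_chisq[i])),
      ifelse(is.na(tb$delta_df[i]), "", sprintf("%d", tb$delta_df[i])),
      ifelse(is.na(tb$p_value[i]), "", sprintf("%.4f", tb$p_value[i])))
  w("\nBest model: **%s**\n", result$best$name)
  props <- result$best$derived$proportions
  w("## Standardized variance proportions (best model)\n")
  w("| component | %s |", paste(colnames(props), collapse = " | "))
  w("|%s|", paste(rep("---", ncol(props) + 1), collapse = "|"))
  for (k in rownames(props))
    w("| %s | %s |", k,
      paste(sprintf("%.3f", props[k, ]), collapse = " | "))
  invisible(path)
}
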