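#' Pooled misclassification table from a discriminant CMV
#'
#' Rows are true classes, columns predicted classes, entries row
#' percentages pooled over every test-set prediction of every model, so
#' each row sums to 100.
#'
#' @param cmv_result A discriminant-mode `cmv_result`.
#' @return 2x2 numeric matrix of percentages.
#' @export
misclassification_table <- function(cmv_result) {
  stopifnot(inherits(cmv_result, "cmv_result"))
  if (cmv_result$mode != "discriminant")
    stop("misclassification table requires a discriminant-mode result")
  classes <- cmv_result$classes
  lv <- c(0, 1)
  tab <- table(factor(cmv_result$pooled_true, levels = lv),
               factor(cmv_result$pooled_pred, levels = lv))
  pct <- 100 * sweep(tab, 1, pmax(rowSums(tab), 1), "/")
  out <- matrix(as.numeric(pct), 2, 2,
                dimnames = list(true = classes, predicted = classes))
  # present with the class coded 1 (H) first, matching convention
  out[2:1, 2:1]
}

#' Run the full differential-abundance pipeline
#'
#' Sequences every stage on a metabolome panel: per-block zero filtering,
#' random-forest imputation and alr transformation; column-join;
#' cross-model-validated PLS-DA (line) and PLS (IMF) with embedded variable
#' selection; one permuted run per mode as the chance reference;
#' selection-frequency consensus; and Gibbs-sampled Bayesian line contrasts
#' for the consensus metabolites.
#'
#' @param panel A [metabolome_panel()] (or a path stem readable by
#'   [read_panel()]).
#' @param config A [cmv_config()]; its `seed` drives every stage through
#'   [derive_seed()].
#' @param max_zero_frac Zero-filter threshold.
#' @param n_permutations Permuted CMV runs per mode.
#' @param n_draws,burn_in Gibbs chain settings.
#' @return A list of class `pipeline_run` with the processed panel, both
#'   `cmv_result`s, permuted results, consensus set, posterior summary
#'   table, misclassification tables, and the config snapshot.
#' @export
run_pipeline <- function(panel, config = cmv_config(), max_zero_frac = 0.10,
                         n_permutations = 1L, n_draws = 50000L,
                         burn_in = 10000L) {
  if (is.character(panel)) panel <- read_panel(panel)
  stopifnot(inherits(panel, "metabolome_panel"))

  processed <- process_blocks(panel, max_zero_frac = max_zero_frac,
                              seed = derive_seed(config$seed, .stage[["impute"]]))
  X <- processed$transformed
  meta <- processed$meta

  cfg_da <- config; cfg_da$seed <- derive_seed(config$seed, .stage[["cmv_da"]])
  cmv_da <- run_cmv(X, meta$line, "discriminant", cfg_da)

  cfg_pls <- config; cfg_pls$seed <- derive_seed(config$seed, .stage[["cmv_pls"]])
  cmv_pls <- run_cmv(X, meta$imf, "regression", cfg_pls, strata = meta$line)

  cfg_pda <- config; cfg_pda$seed <- derive_seed(config$seed, .stage[["perm_da"]])
  perm_da <- permutation_cmv(X, meta$line, "discriminant", cfg_pda,
                             n_permutations)
  cfg_ppls <- config; cfg_ppls$seed <- derive_seed(config$seed, .stage[["perm_pls"]])
  perm_pls <- permutation_cmv(X, meta$imf, "regression", cfg_ppls,
                              n_permutations)

  consensus <- consensus_selection(cmv_da, cmv_pls, config)

  posterior <- if (length(consensus)) {
    fit_all_selected(X, meta, consensus, n_draws = n_draws,
                     burn_in = burn_in,
                     seed = derive_seed(config$seed, .stage[["bayes"]]))
  } else {
    data.frame(metabolite_id = character(0), d_hl_median = numeric(0),
               hpd_low = numeric(0), hpd_high = numeric(0), p0 = numeric(0),
               d_sd_units = numeric(0), geweke_z = numeric(0))
  }

  structure(
    list(
      processed = processed,
      cmv_da = cmv_da, cmv_pls = cmv_pls,
      perm_da = perm_da, perm_pls = perm_pls,
      consensus = consensus, posterior = posterior,
      misclassification = misclassification_table(cmv_da),
      misclassification_permuted = misclassification_table(perm_da[[1]]),
      q2_true = cmv_pls$q2_distribution,
      q2_permuted = perm_pls[[1]]$q2_distribution,
      config = config, seed = config$seed
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  cat(sprintf("  metabolites after processing: %d\n",
              ncol(x$processed$transformed)))
  cat(sprintf("  PLS-DA pooled misclassification: %.1f%% (permuted %.1f%%)\n",
              x$cmv_da$average_misclassification,
              x$perm_da[[1]]$average_misclassification))
  cat(sprintf("  PLS mean test Q2: %.2f (permuted %.2f)\n",
              mean(x$q2_true), mean(x$q2_permuted)))
  cat(sprintf("  consensus metabolites: %d\n", length(x$consensus)))
  invisible(x)
}

#' Write pipeline outputs as plain-text tables
#'
#' Writes the selection tally, per-model metrics, posterior summary table,
#' and a JSON overview under `dir`.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tal <- data.frame(
    metabolite_id = names(run$cmv_da$tally),
    tally_da = as.integer(run$cmv_da$tally),
    tally_pls = as.integer(run$cmv_pls$tally[names(run$cmv_da$tally)]),
    selected = names(run$cmv_da$tally) %in% run$consensus
  )
  f1 <- file.path(dir, "tally.csv")
  utils::write.csv(tal, f1, row.names = FALSE)
  f2 <- file.path(dir, "posterior.csv")
  utils::write.csv(run$posterior, f2, row.names = FALSE)
  f3 <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(
      n_metabolites = ncol(run$processed$transformed),
      n_models = run$cmv_da$n_models,
      misclassification_true = run$cmv_da$average_misclassification,
      misclassification_permuted = run$perm_da[[1]]$average_misclassification,
      mean_q2_true = mean(run$q2_true),
      mean_q2_permuted = mean(run$q2_permuted),
      n_q2_excluded = length(run$cmv_pls$excluded_models),
      n_consensus = length(run$consensus),
      seed = run$seed
    ),
    f3, auto_unbox = TRUE, digits = NA
  )
  invisible(c(f1, f2, f3))
}
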