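#' Configuration for cross model validation
#'
#' Defaults follow the study design: 8-fold outer CV repeated over 20
#' reshuffled iterations (160 models per mode), 7-fold inner CV for model
#' optimization and jackknifing, variable selection at VIP >= 0.8 with a 95%
#' coefficient CI excluding 0, consensus at > 80% of models, and exclusion
#' of regression models with test Q-squared below 0.4 from the tally.
#'
#' @param outer_folds Outer CV folds (test-set partitions).
#' @param inner_folds Inner CV folds (optimization + jackknife segments).
#' @param iterations Number of outer-CV reshuffles.
#' @param vip_threshold VIP cutoff for variable selection.
#' @param ci_level Confidence level of the coefficient interval.
#' @param selection_frequency Consensus fraction of models (strict `>`).
#' @param q2_exclusion Test Q-squared below which a regression model is
#'   excluded from the selection tally (it still counts in `n_models`).
#' @param max_components Cap on latent components considered.
#' @param standardize `"global"` (standardize the full matrix once, the
#'   study's approach), `"fold"` (leakage-safe per-training-fold), or
#'   `"none"` (input already standardized).
#' @param seed Integer seed.
#' @return A list of class `cmv_config`.
#' @export
cmv_config <- function(outer_folds = 8L, inner_folds = 7L, iterations = 20L,
                       vip_threshold = 0.8, ci_level = 0.95,
                       selection_frequency = 0.8, q2_exclusion = 0.4,
                       max_components = 10L, standardize = "global",
                       seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, iterations >= 1,
            vip_threshold >= 0, ci_level > 0, ci_level < 1,
            selection_frequency >= 0, selection_frequency <= 1,
            max_components >= 1)
  standardize <- match.arg(standardize, c("global", "fold", "none"))
  structure(
    list(outer_folds = as.integer(outer_folds),
         inner_folds = as.integer(inner_folds),
         iterations = as.integer(iterations),
         vip_threshold = vip_threshold, ci_level = ci_level,
         selection_frequency = selection_frequency,
         q2_exclusion = q2_exclusion,
         max_components = as.integer(max_components),
         standardize = standardize, seed = as.integer(seed)),
    class = "cmv_config"
  )
}

# Stratified fold assignment: within each stratum, shuffled members are dealt
# round-robin across folds so fold sizes differ by at most 1 overall and each
# stratum is spread as evenly as possible. Fold numbering is rotated per
# stratum so no fold systematically collects the remainders.
make_folds <- function(n, k, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, n)
  fold <- integer(n)
  offset <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

# Coefficients and intercept of a fitted NIPALS path truncated at a
# components; used to reuse one path fit across candidate component counts.
coef_at <- function(model, a) {
  a <- min(a, model$n_components)
  W <- model$x_weights[, seq_len(a), drop = FALSE]
  P <- model$x_loadings[, seq_len(a), drop = FALSE]
  Q <- model$y_loadings[seq_len(a)]
  drop(W %*% solve(crossprod(P, W), Q))
}

predict_at <- function(model, newdata, a) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, model$center, "-"),
              2, model$scale, "/")
  drop(Xs %*% coef_at(model, a)) + model$intercept
}

# One CMV model: inner-CV component choice (one-SE rule), VIP + jackknife-CI
# variable selection, refit on the selected variables, prediction of the
# held-out test fold. Returns the per-model record.
fit_cmv_model <- function(Xtr, ytr, Xte, yte, mode, config, strata_tr = NULL) {
  n_tr <- nrow(Xtr)
  amax <- min(config$max_components, ncol(Xtr), n_tr - 2L)
  seg_id <- make_folds(n_tr, config$inner_folds, strata_tr)
  segments <- split(seq_len(n_tr), seg_id)
  g <- length(segments)

  seg_fits <- vector("list", g)
  err <- matrix(NA_real_, g, amax)
  for (m in seq_len(g)) {
    idx <- segments[[m]]
    fit <- fit_pls(Xtr[-idx, , drop = FALSE], ytr[-idx], amax,
                   center = TRUE, scale = FALSE)
    seg_fits[[m]] <- fit
    for (a in seq_len(amax)) {
      pr <- predict_at(fit, Xtr[idx, , drop = FALSE], a)
      err[m, a] <- if (mode == "discriminant") {
        mean((pr >= 0.5) != (ytr[idx] == 1))
      } else {
        mean((ytr[idx] - pr)^2)
      }
    }
  }
  mean_err <- colMeans(err)
  se_err <- apply(err, 2, stats::sd) / sqrt(g)
  best <- which.min(mean_err)
  ncomp <- which(mean_err <= mean_err[best] + se_err[best])[1]

  full <- fit_pls(Xtr, ytr, ncomp, center = TRUE, scale = FALSE)
  vip <- vip_scores(full)

  # Martens' jackknife from the inner-segment path fits at ncomp
  bfull <- coef_at(full, min(ncomp, full$n_components))
  bmat <- vapply(seg_fits, function(f) coef_at(f, ncomp), numeric(ncol(Xtr)))
  se <- sqrt((g - 1) / g * rowSums((bmat - bfull)^2))
  tq <- stats::qt(1 - (1 - config$ci_level) / 2, df = g - 1)
  ci_excludes_zero <- abs(bfull) > tq * se

  selected <- colnames(Xtr)[vip >= config$vip_threshold & ci_excludes_zero]

  if (length(selected) == 0) {
    # degenerate fold: no variable survives; fall back to the training
    # mean (regression) or majority class (discriminant, ties -> code 0)
    pred <- if (mode == "discriminant") {
      rep(as.numeric(mean(ytr == 1) > 0.5), nrow(Xte))
    } else {
      rep(mean(ytr), nrow(Xte))
    }
  } else {
    ncomp2 <- min(ncomp, length(selected))
    refit <- fit_pls(Xtr[, selected, drop = FALSE], ytr, ncomp2,
                     center = TRUE, scale = FALSE)
    pred <- predict(refit, Xte[, selected, drop = FALSE])
  }

  rec <- list(
    selected = selected, n_components = ncomp,
    y_test = yte, y_pred = pred, y_train_mean = mean(ytr)
  )
  if (mode == "discriminant") {
    rec$pred_class <- as.numeric(pred >= 0.5)
    rec$misclassification <- mean(rec$pred_class != yte)
  } else {
    rec$q2 <- q2_statistic(yte, pred, mean(ytr))
  }
  rec
}

#' Run cross model validation
#'
#' Nested cross-validation with embedded variable selection: in each of
#' `iterations` reshuffles, samples are partitioned into `outer_folds` test
#' folds (stratified by `strata`, typically the line, so folds stay
#' balanced). Per fold, the training samples are subjected to an inner CV
#' that picks the number of latent components (smallest within one standard
#' error of the best) and supplies the jackknife segments; variables with
#' VIP >= `vip_threshold` whose jackknife CI excludes 0 are selected, the
#' model is refitted on them, and the held-out fold is predicted. Selections
#' are tallied across all models; in regression mode only models with test
#' Q-squared >= `q2_exclusion` contribute to the tally (all models count in
#' `n_models`).
#'
#' @param X Predictor matrix (samples x metabolites).
#' @param response Class labels (discriminant) or numeric vector
#'   (regression).
#' @param mode `"discriminant"` or `"regression"`.
#' @param config A [cmv_config()].
#' @param strata Optional stratification labels for fold construction
#'   (defaults to the response in discriminant mode).
#' @return A list of class `cmv_result`: `models` (per-model records),
#'   `tally` (named selection counts), `n_models`, `excluded_models`
#'   (regression only), `q2_distribution` or `misclassification` summaries,
#'   `mode`, `config`.
#' @export
run_cmv <- function(X, response, mode = c("discriminant", "regression"),
                    config = cmv_config(), strata = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n / config$outer_folds < 2) stop("outer folds would have < 2 samples")

  if (mode == "discriminant") {
    labs <- as.character(response)
    u <- sort(unique(labs))
    if (length(u) != 2) stop("discriminant mode needs exactly two classes")
    if (setequal(u, c("H", "L"))) u <- c("L", "H")
    y <- as.numeric(labs == u[2])
    if (is.null(strata)) strata <- labs
    classes <- u
  } else {
    y <- as.numeric(response)
    if (stats::var(y) == 0) stop("zero-variance response")
    classes <- NULL
  }

  if (config$standardize == "global") X <- standardize(X)

  set.seed(config$seed)
  models <- vector("list", config$iterations * config$outer_folds)
  mi <- 0L
  for (it in seq_len(config$iterations)) {
    fold_id <- make_folds(n, config$outer_folds, strata)
    for (f in seq_len(config$outer_folds)) {
      te <- which(fold_id == f)
      tr <- which(fold_id != f)
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (config$standardize == "fold") {
        Xtr <- standardize(Xtr)
        Xte <- standardize(X[te, , drop = FALSE],
                           center = attr(Xtr, "center"),
                           scale = attr(Xtr, "scale"))
      }
      rec <- fit_cmv_model(Xtr, y[tr], Xte, y[te], mode, config,
                           strata_tr = if (!is.null(strata)) strata[tr])
      rec$iteration <- it; rec$fold <- f; rec$test_idx <- te
      mi <- mi + 1L
      models[[mi]] <- rec
    }
  }

  n_models <- length(models)
  tally <- stats::setNames(integer(ncol(X)), colnames(X))
  excluded <- integer(0)
  for (i in seq_len(n_models)) {
    rec <- models[[i]]
    if (mode == "regression" && rec$q2 < config$q2_exclusion) {
      excluded <- c(excluded, i)
      next
    }
    if (length(rec$selected))
      tally[rec$selected] <- tally[rec$selected] + 1L
  }

  out <- list(models = models, tally = tally, n_models = n_models,
              excluded_models = excluded, mode = mode, config = config,
              classes = classes)
  if (mode == "discriminant") {
    yt <- unlist(lapply(models, `[[`, "y_test"))
    yp <- unlist(lapply(models, `[[`, "pred_class"))
    out$pooled_true <- yt
    out$pooled_pred <- yp
    out$average_misclassification <- 100 * mean(yt != yp)
  } else {
    out$q2_distribution <- vapply(models, `[[`, numeric(1), "q2")
  }
  structure(out, class = "cmv_result")
}

#' @export
print.cmv_result <- function(x, ...) {
  cat(sprintf("<cmv_result> %s mode: %d models (%d iterations x %d folds)\n",
              x$mode, x$n_models, x$config$iterations, x$config$outer_folds))
  if (x$mode == "discriminant") {
    cat(sprintf("  pooled misclassification: %.1f%%\n",
                x$average_misclassification))
  } else {
    cat(sprintf("  mean test Q2: %.3f (%d models excluded at Q2 < %.2f)\n",
                mean(x$q2_distribution), length(x$excluded_models),
                x$config$q2_exclusion))
  }
  cat(sprintf("  metabolites ever selected: %d\n", sum(x$tally > 0)))
  invisible(x)
}

#' Consensus selection across the discriminant and regression tallies
#'
#' A metabolite enters the consensus set when it was selected in strictly
#' more than `selection_frequency * n_models` models in *both* the
#' discriminant and the regression CMV (e.g. > 128 of 160 models each).
#'
#' @param tally_da,tally_pls `cmv_result` objects, or named count vectors
#'   with an `n_models` attribute.
#' @param config A [cmv_config()] supplying `selection_frequency`.
#' @return Character vector of consensus metabolite ids.
#' @export
consensus_selection <- function(tally_da, tally_pls, config = cmv_config()) {
  get_tally <- function(x) {
    if (inherits(x, "cmv_result")) {
      t <- x$tally; attr(t, "n_models") <- x$n_models; t
    } else x
  }
  ta <- get_tally(tally_da); tp <- get_tally(tally_pls)
  if (!setequal(names(ta), names(tp)))
    stop("tallies must cover the same metabolite universe")
  na <- attr(ta, "n_models"); np <- attr(tp, "n_models")
  if (is.null(na) || is.null(np)) stop("tallies must carry n_models")
  tp <- tp[names(ta)]
  sel <- names(ta)[ta > config$selection_frequency * na &
                     tp > config$selection_frequency * np]
  sel
}

#' Permutation-null cross model validation
#'
#' Permutes the response uniformly at random (a fresh permutation per run)
#' and executes the full CMV, returning one `cmv_result` per permutation.
#' Used to show that the true-label models outperform chance; no tally-based
#' selection is interpreted from permuted runs.
#'
#' @param X Predictor matrix.
#' @param response Response vector / class labels.
#' @param mode `"discriminant"` or `"regression"`.
#' @param config A [cmv_config()].
#' @param n_permutations Number of permuted runs (default 1).
#' @return List of `cmv_result`, one per permutation.
#' @export
permutation_cmv <- function(X, response, mode = c("discriminant", "regression"),
                            config = cmv_config(), n_permutations = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_permutations >= 1)
  lapply(seq_len(n_permutations), function(k) {
    set.seed(derive_seed(config$seed, 100L + k))
    perm <- sample(response)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 200L + k)
    run_cmv(X, perm, mode, cfg)
  })
}
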