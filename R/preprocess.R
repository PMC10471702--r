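#' Filter metabolites by per-line zero fraction
#'
#' A metabolite is kept iff it has strictly less than `max_zero_frac` zeros
#' in at least one line, i.e. `min(frac_zero_H, frac_zero_L) < max_zero_frac`.
#' Zeros in kept metabolites are left in place for imputation.
#'
#' @param panel A [metabolome_panel()].
#' @param max_zero_frac Zero-fraction threshold (default 0.10, strict `<`).
#' @return A list with `panel` (filtered) and `report`, a `filter_report`
#'   holding `kept`, `removed`, and the per-line zero fractions.
#' @export
filter_by_missingness <- function(panel, max_zero_frac = 0.10) {
  stopifnot(inherits(panel, "metabolome_panel"))
  if (max_zero_frac <= 0 || max_zero_frac > 1)
    stop("max_zero_frac must be in (0,1]")
  line <- panel$meta$line
  if (!all(c("H", "L") %in% line)) stop("both lines must have samples")
  ab <- panel$abundance
  frac_h <- colMeans(ab[line == "H", , drop = FALSE] == 0)
  frac_l <- colMeans(ab[line == "L", , drop = FALSE] == 0)
  keep <- pmin(frac_h, frac_l) < max_zero_frac
  report <- structure(
    list(
      kept = colnames(ab)[keep],
      removed = colnames(ab)[!keep],
      zero_frac_by_line = data.frame(
        metabolite_id = colnames(ab), frac_H = frac_h, frac_L = frac_l,
        row.names = NULL
      )
    ),
    class = "filter_report"
  )
  list(panel = subset_metabolites(panel, report$kept), report = report)
}

#' Impute zeros by iterative random forest
#'
#' missForest-style chained imputation: zeros are treated as missing,
#' initialized at each metabolite's observed median, then metabolites are
#' cycled in increasing-missingness order, each regressed on all others with
#' a random forest and its missing cells replaced by predictions. Iteration
#' stops when the normalized change in imputed values increases (the
#' previous iterate is returned) or after `max_iter` sweeps. Imputed values
#' are floored at half the metabolite's minimum observed value so the log
#' step downstream stays defined; observed values are never touched.
#'
#' @param panel A [metabolome_panel()].
#' @param seed Integer seed for the forest.
#' @param max_iter Maximum sweeps (default 10).
#' @param num_trees Trees per forest (default 100).
#' @return The panel with all zeros replaced by strictly positive values.
#' @export
impute_random_forest <- function(panel, seed = 1L, max_iter = 10L,
                                 num_trees = 100L) {
  stopifnot(inherits(panel, "metabolome_panel"))
  ab <- panel$abundance
  miss <- ab == 0
  if (any(colSums(!miss) == 0))
    stop("metabolite with no observed values; filter first")
  if (!any(miss)) return(panel)
  set.seed(derive_seed(seed, .stage[["impute"]]))

  floor_val <- apply(ab, 2, function(v) min(v[v > 0]) / 2)
  x <- ab
  for (j in which(colSums(miss) > 0)) {
    x[miss[, j], j] <- stats::median(ab[!miss[, j], j])
  }
  order_j <- order(colSums(miss))
  order_j <- order_j[colSums(miss)[order_j] > 0]

  prev_change <- Inf
  x_prev <- x
  for (it in seq_len(max_iter)) {
    for (j in order_j) {
      obs <- !miss[, j]
      df <- data.frame(.y = x[obs, j], x[obs, -j, drop = FALSE],
                       check.names = FALSE)
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = num_trees, seed = sample.int(.Machine$integer.max, 1)
      )
      newdat <- data.frame(x[!obs, -j, drop = FALSE], check.names = FALSE)
      pred <- stats::predict(fit, data = newdat)$predictions
      x[!obs, j] <- pmax(pred, floor_val[j])
    }
    num <- sum((x[miss] - x_prev[miss])^2)
    den <- sum(x[miss]^2)
    change <- if (den > 0) num / den else 0
    if (change >= prev_change) {
      x <- x_prev  # stopping criterion: change rose, keep previous iterate
      break
    }
    if (change < 1e-8) break
    x_prev <- x
    prev_change <- change
  }
  if (it == max_iter && change < prev_change && change >= 1e-8)
    warning("imputation reached max_iter without the stopping criterion")
  out <- metabolome_panel(x, panel$block, panel$meta, panel$truth)
  attr(out$abundance, "original") <- attr(panel$abundance, "original")
  out
}

#' Process acquisition blocks and join
#'
#' Runs the per-block chain — zero filtering, random-forest imputation,
#' reference selection and additive log-ratio transformation — separately on
#' each block, then column-concatenates the transformed blocks into one
#' samples x (J_b - 1 per block) matrix.
#'
#' @param panels Named list of per-block [metabolome_panel()]s sharing an
#'   identical sample set (e.g. from [split_blocks()]), or a single panel
#'   which is split by its block labels first.
#' @param max_zero_frac Passed to [filter_by_missingness()].
#' @param seed Seed for imputation.
#' @param screen_quantile Passed to [select_alr_reference()].
#' @param impute Logical; set `FALSE` when the input has no zeros.
#' @return A list of class `processed_panel` with elements `transformed`
#'   (joined matrix), `block` (per-column provenance), `meta`,
#'   `filter_reports`, and `alr_results` (one per block, including the chosen
#'   reference and its diagnostics).
#' @export
process_blocks <- function(panels, max_zero_frac = 0.10, seed = 1L,
                           screen_quantile = 0.5, impute = TRUE) {
  if (inherits(panels, "metabolome_panel")) panels <- split_blocks(panels)
  stopifnot(is.list(panels), length(panels) >= 1)
  ids <- lapply(panels, function(p) rownames(p$abundance))
  if (!all(vapply(ids, function(x) identical(sort(x), sort(ids[[1]])),
                  logical(1))))
    stop("blocks must share identical sample sets")
  sample_order <- ids[[1]]

  filter_reports <- list(); alr_results <- list(); mats <- list()
  blk <- character(0)
  for (b in names(panels)) {
    pb <- panels[[b]]
    pb <- metabolome_panel(pb$abundance[sample_order, , drop = FALSE],
                           pb$block, pb$meta, pb$truth)
    fl <- filter_by_missingness(pb, max_zero_frac)
    filter_reports[[b]] <- fl$report
    pb <- fl$panel
    if (impute && any(pb$abundance == 0))
      pb <- impute_random_forest(pb, seed = derive_seed(seed, match(b, names(panels))))
    ar <- select_alr_reference(pb$abundance, screen_quantile = screen_quantile)
    alr_results[[b]] <- ar
    mats[[b]] <- ar$transformed
    blk <- c(blk, rep(b, ncol(ar$transformed)))
  }
  transformed <- do.call(cbind, mats)
  names(blk) <- colnames(transformed)
  structure(
    list(
      transformed = transformed, block = blk,
      meta = panels[[1]]$meta[match(sample_order, panels[[1]]$meta$sample_id), ],
      filter_reports = filter_reports, alr_results = alr_results
    ),
    class = "processed_panel"
  )
}
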