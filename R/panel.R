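#' Metabolome panel container
#'
#' Bundles a non-negative abundance matrix (samples x metabolites) with its
#' annotations: acquisition block per metabolite, line / sex / intramuscular
#' fat (IMF, g per 100 g fresh muscle) per sample, and, for synthetic data,
#' the planted per-metabolite line effect in SD units.
#'
#' @param abundance Non-negative numeric matrix, samples in rows (rownames =
#'   sample ids), metabolites in columns (colnames = metabolite ids).
#' @param block Character vector, one of `"positive-early"`,
#'   `"positive-late"`, `"negative"`, `"polar"` per metabolite (named by
#'   metabolite id).
#' @param meta Data frame with columns `sample_id`, `line` (`"H"`/`"L"`),
#'   `sex` (`"M"`/`"F"`), `imf` (numeric).
#' @param truth Optional numeric vector of planted effects (SD units) per
#'   metabolite; 0 for unaffected metabolites.
#' @return An object of class `metabolome_panel`.
#' @export
metabolome_panel <- function(abundance, block, meta, truth = NULL) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundance must be non-negative")
  if (is.null(rownames(abundance)) ||
      (ncol(abundance) > 0 && is.null(colnames(abundance))))
    stop("abundance needs sample rownames and metabolite colnames")
  if (ncol(abundance) == 0 && is.null(colnames(abundance)))
    colnames(abundance) <- character(0)
  if (!setequal(names(block), colnames(abundance)))
    stop("block must name every metabolite exactly once")
  block <- block[colnames(abundance)]
  valid_blocks <- c("positive-early", "positive-late", "negative", "polar")
  if (!all(block %in% valid_blocks))
    stop("unknown acquisition block label")
  req <- c("sample_id", "line", "sex", "imf")
  if (!all(req %in% names(meta))) stop("meta must have sample_id, line, sex, imf")
  if (!setequal(meta$sample_id, rownames(abundance)))
    stop("meta rows must match abundance samples")
  meta <- meta[match(rownames(abundance), meta$sample_id), , drop = FALSE]
  if (!all(meta$line %in% c("H", "L"))) stop("line must be H or L")
  if (anyNA(meta$imf)) stop("every sample needs an IMF value")
  if (!is.null(truth)) {
    if (!setequal(names(truth), colnames(abundance)))
      stop("truth must name every metabolite")
    truth <- truth[colnames(abundance)]
  }
  structure(
    list(abundance = abundance, block = block, meta = meta, truth = truth),
    class = "metabolome_panel"
  )
}

#' @export
print.metabolome_panel <- function(x, ...) {
  cat(sprintf(
    "<metabolome_panel> %d samples x %d metabolites\n",
    nrow(x$abundance), ncol(x$abundance)
  ))
  cat("  blocks: ", paste(sprintf("%s=%d", names(table(x$block)),
                                  table(x$block)), collapse = ", "), "\n")
  cat("  lines:  ", paste(sprintf("%s=%d", names(table(x$meta$line)),
                                  table(x$meta$line)), collapse = ", "), "\n")
  if (!is.null(x$truth))
    cat(sprintf("  planted effects: %d nonzero\n", sum(x$truth != 0)))
  invisible(x)
}

#' Subset a panel to a set of metabolites
#'
#' @param panel A `metabolome_panel`.
#' @param metabolites Character vector of metabolite ids to keep.
#' @return A `metabolome_panel` restricted to those columns.
#' @export
subset_metabolites <- function(panel, metabolites) {
  stopifnot(inherits(panel, "metabolome_panel"))
  if (!all(metabolites %in% colnames(panel$abundance)))
    stop("unknown metabolite id")
  metabolome_panel(
    panel$abundance[, metabolites, drop = FALSE],
    panel$block[metabolites],
    panel$meta,
    if (!is.null(panel$truth)) panel$truth[metabolites]
  )
}

#' Split a panel by acquisition block
#'
#' @param panel A `metabolome_panel`.
#' @return Named list of `metabolome_panel`, one per block present.
#' @export
split_blocks <- function(panel) {
  stopifnot(inherits(panel, "metabolome_panel"))
  lapply(split(names(panel$block), panel$block), function(ids)
    subset_metabolites(panel, ids))
}

#' Write a panel to plain-text files
#'
#' Writes `<stem>_abundance.csv` (samples x metabolites, sample ids in the
#' first column), `<stem>_metadata.csv` (`sample_id,line,sex,imf` plus a
#' `block` mapping file column-wise), and `<stem>_truth.json` when planted
#' effects exist.
#'
#' @param panel A `metabolome_panel`.
#' @param stem Path stem for output files.
#' @return Invisibly, the vector of files written.
#' @export
write_panel <- function(panel, stem) {
  stopifnot(inherits(panel, "metabolome_panel"))
  ab <- data.frame(sample_id = rownames(panel$abundance),
                   panel$abundance, check.names = FALSE)
  f1 <- paste0(stem, "_abundance.csv")
  utils::write.csv(ab, f1, row.names = FALSE)
  f2 <- paste0(stem, "_metadata.csv")
  utils::write.csv(panel$meta, f2, row.names = FALSE)
  f3 <- paste0(stem, "_blocks.csv")
  utils::write.csv(
    data.frame(metabolite_id = names(panel$block), block = unname(panel$block)),
    f3, row.names = FALSE
  )
  files <- c(f1, f2, f3)
  if (!is.null(panel$truth)) {
    f4 <- paste0(stem, "_truth.json")
    jsonlite::write_json(as.list(panel$truth), f4, auto_unbox = TRUE, digits = NA)
    files <- c(files, f4)
  }
  invisible(files)
}

#' Read a panel previously written by [write_panel()]
#'
#' @param stem Path stem used when writing.
#' @return A `metabolome_panel`.
#' @export
read_panel <- function(stem) {
  ab <- utils::read.csv(paste0(stem, "_abundance.csv"), check.names = FALSE)
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab$sample_id
  meta <- utils::read.csv(paste0(stem, "_metadata.csv"))
  blk <- utils::read.csv(paste0(stem, "_blocks.csv"))
  block <- stats::setNames(blk$block, blk$metabolite_id)
  truth_file <- paste0(stem, "_truth.json")
  truth <- NULL
  if (file.exists(truth_file)) {
    tl <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
    truth <- stats::setNames(as.numeric(tl), names(tl))
  }
  metabolome_panel(m, block, meta, truth)
}
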