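#' Additive log-ratio transformation
#'
#' Maps a strictly positive composition to `ln(x_j) - ln(x_ref)` for every
#' metabolite except the reference, removing the arbitrary per-sample total
#' (compositional closure): rescaling any sample row leaves the output
#' unchanged.
#'
#' @param x Strictly positive matrix (samples x metabolites) with column
#'   names.
#' @param reference_id Column name of the reference metabolite.
#' @return Matrix of log-ratios with `J - 1` columns (reference dropped).
#' @export
alr_transform <- function(x, reference_id) {
  x <- as.matrix(x)
  if (any(x <= 0)) stop("alr requires strictly positive entries")
  if (!reference_id %in% colnames(x)) stop("unknown reference metabolite")
  lx <- log(x)
  out <- lx[, setdiff(colnames(x), reference_id), drop = FALSE] -
    lx[, reference_id]
  out
}

# Centered log-ratio matrix; the sample geometry of the full set of pairwise
# log-ratios equals the clr geometry up to rotation and uniform scaling, so
# clr stands in for "all J(J-1)/2 log-ratios" in Procrustes comparisons.
clr_matrix <- function(x) {
  lx <- log(as.matrix(x))
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Procrustes correlation between two sample configurations
#'
#' Measures how well one multivariate sample configuration reproduces
#' another after optimal translation, rotation/reflection, and uniform
#' scaling. Computed from the singular values of the cross-covariance of the
#' column-centered configurations:
#' `corr = sum(sv) / sqrt(||Xc||_F^2 * ||Yc||_F^2)`, the square root of
#' 1 minus the minimized Procrustes statistic m^2. Lies in `[0, 1]`.
#'
#' @param full_geometry,alr_geometry Numeric matrices with the same samples
#'   in rows (columns may differ).
#' @return Procrustes correlation in `[0, 1]`.
#' @export
procrustes_correlation <- function(full_geometry, alr_geometry) {
  x <- as.matrix(full_geometry); y <- as.matrix(alr_geometry)
  if (nrow(x) != nrow(y)) stop("configurations must share samples")
  if (nrow(x) < 3) stop("need at least 3 samples")
  xc <- sweep(x, 2, colMeans(x), "-")
  yc <- sweep(y, 2, colMeans(y), "-")
  ssx <- sum(xc^2); ssy <- sum(yc^2)
  if (ssx == 0 || ssy == 0) stop("degenerate (zero-variance) configuration")
  # reduce each configuration to its score representation (n x r); the
  # singular values of crossprod(scores) equal those of crossprod(xc, yc)
  sx <- svd(xc, nu = min(dim(xc)), nv = 0)
  sy <- svd(yc, nu = min(dim(yc)), nv = 0)
  kx <- sum(sx$d > max(dim(xc)) * .Machine$double.eps * sx$d[1])
  ky <- sum(sy$d > max(dim(yc)) * .Machine$double.eps * sy$d[1])
  a <- sx$u[, seq_len(kx), drop = FALSE] %*% diag(sx$d[seq_len(kx)], kx)
  b <- sy$u[, seq_len(ky), drop = FALSE] %*% diag(sy$d[seq_len(ky)], ky)
  sv <- svd(crossprod(a, b), nu = 0, nv = 0)$d
  min(1, sum(sv) / sqrt(ssx * ssy))
}

#' Select the additive log-ratio reference metabolite
#'
#' Evaluates every metabolite as candidate reference: the alr configuration
#' it induces is compared to the full log-ratio geometry (clr configuration)
#' by Procrustes correlation, and its log-abundance variance is recorded.
#' Among candidates whose log variance falls below the panel's
#' `screen_quantile` quantile (default the median), the one with the highest
#' Procrustes correlation wins; ties break toward lower variance, then
#' lexicographic id. A low-variance reference keeps the ratio variation
#' dominated by the numerator.
#'
#' @param x Strictly positive matrix (>= 3 samples, >= 2 metabolites).
#' @param screen_quantile Quantile of log variance used as the screen.
#' @return A list of class `alr_result`: `reference_id`, `procrustes_corr`,
#'   `reference_log_variance`, `transformed` (samples x J-1), and
#'   `diagnostics` (per-candidate correlation and variance).
#' @export
select_alr_reference <- function(x, screen_quantile = 0.5) {
  x <- as.matrix(x)
  if (any(x <= 0)) stop("requires strictly positive entries")
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (ncol(x) < 2) stop("need at least 2 metabolites")
  lx <- log(x)
  lvar <- apply(lx, 2, stats::var)
  full <- clr_matrix(x)
  ids <- colnames(x)
  corr <- vapply(ids, function(ref) {
    cand <- lx[, setdiff(ids, ref), drop = FALSE] - lx[, ref]
    procrustes_correlation(full, cand)
  }, numeric(1))
  diag_df <- data.frame(
    metabolite_id = ids, procrustes_corr = unname(corr),
    log_variance = unname(lvar), row.names = NULL
  )
  screen <- lvar < stats::quantile(lvar, screen_quantile)
  if (!any(screen)) screen <- lvar <= stats::quantile(lvar, screen_quantile)
  pool <- diag_df[screen, ]
  pool <- pool[order(-pool$procrustes_corr, pool$log_variance,
                     pool$metabolite_id), ]
  ref <- pool$metabolite_id[1]
  structure(
    list(
      reference_id = ref,
      procrustes_corr = corr[[ref]],
      reference_log_variance = lvar[[ref]],
      transformed = alr_transform(x, ref),
      diagnostics = diag_df
    ),
    class = "alr_result"
  )
}
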