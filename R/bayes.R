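#' Specify the per-metabolite linear model
#'
#' `y = Xb + e`, `e ~ N(0, I sigma2_e)`, with fixed effects for intercept,
#' line, and sex. Line is coded H = +1/2, L = -1/2 (and sex M = +1/2,
#' F = -1/2) so the line coefficient is directly the H-minus-L difference.
#' Flat priors are placed on the fixed effects and the residual variance.
#'
#' @param y Response vector (typically an alr-transformed abundance).
#' @param line Character vector of `"H"`/`"L"` per sample.
#' @param sex Optional character vector of `"M"`/`"F"` per sample.
#' @return List of class `linear_model_spec` with `y`, `design`, and the
#'   index of the line contrast column.
#' @export
linear_model_spec <- function(y, line, sex = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (length(line) != n) stop("line must match y")
  X <- cbind(intercept = rep(1, n),
             line = ifelse(line == "H", 0.5, -0.5))
  if (!is.null(sex)) {
    if (length(sex) != n) stop("sex must match y")
    if (length(unique(sex)) > 1)
      X <- cbind(X, sex = ifelse(sex == "M", 0.5, -0.5))
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  if (n <= ncol(X)) stop("need more samples than fixed effects")
  structure(list(y = y, design = X, line_col = 2L),
            class = "linear_model_spec")
}

#' Gibbs sampler for the flat-prior linear model
#'
#' Alternates the full conditionals
#' `b | sigma2, y ~ N(b_hat, sigma2 (X'X)^-1)` (with `b_hat` the
#' least-squares solution) and
#' `sigma2 | b, y ~ RSS(b) / chisq(n - 2)` — the scaled inverse chi-square
#' implied by a flat prior on the variance (a chi-square with n degrees of
#' freedom would correspond to the Jeffreys prior instead). Draws after
#' `burn_in` are returned; the chain is reproducible for a fixed seed.
#'
#' @param spec A [linear_model_spec()].
#' @param n_draws Total Gibbs sweeps (default 50000).
#' @param burn_in Discarded initial sweeps (default 10000).
#' @param seed Integer seed.
#' @return Matrix of retained draws, one column per fixed effect plus
#'   `sigma2`.
#' @export
gibbs_sample <- function(spec, n_draws = 50000L, burn_in = 10000L, seed = 1L) {
  stopifnot(inherits(spec, "linear_model_spec"),
            n_draws > burn_in, burn_in >= 0)
  X <- spec$design; y <- spec$y
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X)
  b_hat <- drop(solve(XtX, crossprod(X, y)))
  # upper Cholesky of (X'X)^-1: b = b_hat + sqrt(sigma2) * R^-1 z
  Rinv <- backsolve(chol(XtX), diag(p))
  set.seed(seed)
  keep <- n_draws - burn_in
  out <- matrix(NA_real_, keep, p + 1L,
                dimnames = list(NULL, c(colnames(X), "sigma2")))
  sigma2 <- sum((y - drop(X %*% b_hat))^2) / max(n - p, 1)
  for (s in seq_len(n_draws)) {
    b <- b_hat + sqrt(sigma2) * drop(Rinv %*% stats::rnorm(p))
    rss <- sum((y - X %*% b)^2)
    sigma2 <- rss / stats::rchisq(1, df = n - 2)
    if (s > burn_in) out[s - burn_in, ] <- c(b, sigma2)
  }
  out
}

# Geweke convergence z-score comparing the first 10% and last 50% of a chain.
geweke_z <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  n <- length(chain)
  a <- chain[seq_len(floor(frac1 * n))]
  b <- chain[seq.int(n - floor(frac2 * n) + 1L, n)]
  (mean(a) - mean(b)) / sqrt(stats::var(a) / length(a) +
                               stats::var(b) / length(b))
}

#' Shortest (highest posterior density) interval of a draw vector
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Interval mass (default 0.95).
#' @return Length-2 vector `c(low, high)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  s <- sort(draws)
  n <- length(s)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[seq.int(m + 1L, n)] - s[seq.int(1L, n - m)]
  i <- which.min(widths)
  c(s[i], s[i + m])
}

#' Summarize the posterior of a line difference
#'
#' Reports the posterior median of the H-minus-L difference, its shortest
#' 95% interval (HPD95), the probability `P0` that the difference lies on
#' the same side of zero as its median, and the difference expressed in
#' units of the metabolite's standard deviation.
#'
#' @param draws Posterior draws of the line contrast.
#' @param metabolite_sd Phenotypic SD used for standardization (> 0).
#' @param prob HPD mass (default 0.95).
#' @return List of class `posterior_summary`: `d_hl_median`, `hpd95`, `p0`,
#'   `d_sd_units`, `n_draws`.
#' @export
summarize_difference <- function(draws, metabolite_sd, prob = 0.95) {
  if (length(draws) == 0) stop("empty draws")
  if (metabolite_sd <= 0) stop("metabolite_sd must be positive")
  med <- stats::median(draws)
  p0 <- if (med > 0) mean(draws > 0) else if (med < 0) mean(draws < 0) else 0.5
  structure(
    list(d_hl_median = med, hpd95 = hpd_interval(draws, prob),
         p0 = p0, d_sd_units = med / metabolite_sd,
         n_draws = length(draws)),
    class = "posterior_summary"
  )
}

#' Fit the Bayesian line-difference model to every selected metabolite
#'
#' For each selected metabolite, fits `y = Xb + e` by Gibbs sampling (y =
#' the metabolite's alr-transformed abundance; fixed effects intercept,
#' line, sex) and summarizes the line contrast. The standardizing SD is the
#' pooled across-line sample SD of the trait. Seeds are drawn from a
#' documented per-metabolite stream so rows are reproducible independently.
#'
#' @param transformed Samples x metabolites matrix of alr-transformed
#'   abundances (column names = metabolite ids).
#' @param meta Sample metadata with `line` and `sex` columns, rows aligned
#'   with `transformed`.
#' @param selected Character vector of metabolite ids to fit (nonempty).
#' @param n_draws,burn_in Chain settings (defaults 50000 / 10000).
#' @param seed Integer seed.
#' @param geweke_warn |z| beyond which a convergence warning is emitted.
#' @return Data frame with one row per metabolite: `metabolite_id`,
#'   `d_hl_median`, `hpd_low`, `hpd_high`, `p0`, `d_sd_units`, `geweke_z`.
#' @export
fit_all_selected <- function(transformed, meta, selected,
                             n_draws = 50000L, burn_in = 10000L, seed = 1L,
                             geweke_warn = 4) {
  if (length(selected) == 0) stop("empty selection")
  if (!all(selected %in% colnames(transformed)))
    stop("selected metabolites absent from panel")
  rows <- lapply(seq_along(selected), function(i) {
    id <- selected[i]
    y <- transformed[, id]
    spec <- linear_model_spec(y, meta$line, meta$sex)
    draws <- gibbs_sample(spec, n_draws, burn_in,
                          seed = derive_seed(seed, .stage[["bayes"]] * 1000L + i))
    d <- draws[, "line"]
    gz <- geweke_z(d)
    if (abs(gz) > geweke_warn)
      warning(sprintf("Geweke |z| = %.1f for %s: chain may not have converged",
                      gz, id))
    s <- summarize_difference(d, pooled_sd(y, meta$line))
    data.frame(metabolite_id = id, d_hl_median = s$d_hl_median,
               hpd_low = s$hpd95[1], hpd_high = s$hpd95[2], p0 = s$p0,
               d_sd_units = s$d_sd_units, geweke_z = gz)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
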