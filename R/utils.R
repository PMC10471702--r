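#' Derive a stage-specific seed from a global seed
#'
#' A single user-facing seed drives every stochastic stage. Each stage draws
#' its own seed from a fixed affine-modular scheme so stages can be re-run
#' independently and in any order without perturbing one another's streams.
#'
#' @param seed Global integer seed.
#' @param stage Integer stage index (>= 0); each named stage in the pipeline
#'   owns a distinct index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  as.integer((abs(seed) %% m * 48271 + stage * 7919 + 1) %% m)
}

#' Column-standardize a matrix
#'
#' Subtract each column's mean and divide by its standard deviation,
#' retaining the vectors used so new samples can be projected consistently.
#'
#' @param x Numeric matrix (samples x variables).
#' @param center,scale Optional pre-computed vectors; computed from `x` when
#'   `NULL`.
#' @return Matrix with attributes `"center"` and `"scale"`.
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, stats::sd)
  if (any(scale <= 0 | !is.finite(scale)))
    stop("zero-variance column cannot be standardized")
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Pooled across-group standard deviation
#'
#' @param x Numeric vector.
#' @param group Factor-like with two or more levels.
#' @return Pooled sample SD.
#' @export
pooled_sd <- function(x, group) {
  group <- as.factor(group)
  ss <- tapply(x, group, function(v) sum((v - mean(v))^2))
  df <- tapply(x, group, length) - 1
  sqrt(sum(ss) / sum(df))
}

# Stage indices for derive_seed(); internal registry.
.stage <- c(
  synth = 1L, missing = 2L, impute = 3L, cmv_da = 4L, cmv_pls = 5L,
  perm_da = 6L, perm_pls = 7L, bayes = 8L
)
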