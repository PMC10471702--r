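#' Configuration for the synthetic metabolome generator
#'
#' Defaults emulate a two-line divergent selection design: 24 sex-balanced
#' rabbits per line, four acquisition blocks of 242/168/399/111 metabolites,
#' 35% of metabolites carrying a line effect drawn uniformly from 0.23-6.04
#' SD (random sign), and an IMF phenotype (g fat / 100 g fresh muscle) whose
#' line gap is 0.45 with residual SD 0.145, so the gap is ~3.1 trait SD and
#' the overall mean ~1.06.
#'
#' @param n_per_line Samples per line; must be even so sexes balance.
#' @param n_metabolites_per_block Integer vector of 4 block sizes
#'   (positive-early, positive-late, negative, polar).
#' @param frac_affected Proportion of metabolites with a planted line effect.
#' @param effect_size_range Length-2 range (SD units) for |planted effect|.
#' @param zero_rate_range Length-2 range of per-metabolite zero rates.
#' @param imf_base Baseline IMF of the L line (g/100 g).
#' @param imf_line_gap IMF difference H minus L (g/100 g).
#' @param imf_noise_sd Residual IMF SD (g/100 g).
#' @param log_mean_range Range for per-metabolite log-abundance means.
#' @param log_sd_range Range for per-metabolite log-abundance SDs.
#' @param corr_rank Optional low-rank shared-factor count inducing
#'   inter-metabolite correlation; 0 (default) means independent metabolites.
#' @param corr_weight Loading SD of the shared factors when `corr_rank > 0`,
#'   as a fraction of each metabolite's own SD.
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_per_line = 24L,
                         n_metabolites_per_block = c(242L, 168L, 399L, 111L),
                         frac_affected = 0.35,
                         effect_size_range = c(0.23, 6.04),
                         zero_rate_range = c(0, 0.08),
                         imf_base = 0.835,
                         imf_line_gap = 0.45,
                         imf_noise_sd = 0.145,
                         log_mean_range = c(8, 14),
                         log_sd_range = c(0.3, 1.0),
                         corr_rank = 0L,
                         corr_weight = 0.3,
                         seed = 1L) {
  if (n_per_line <= 0 || any(n_metabolites_per_block <= 0))
    stop("counts must be positive")
  if (n_per_line %% 2 != 0) stop("n_per_line must be even (sex-balanced)")
  if (length(n_metabolites_per_block) != 4)
    stop("need 4 block sizes")
  if (frac_affected < 0 || frac_affected > 1) stop("frac_affected in [0,1]")
  if (diff(effect_size_range) < 0) stop("effect_size_range inverted")
  if (any(zero_rate_range < 0 | zero_rate_range > 1))
    stop("zero rates must be in [0,1]")
  structure(
    list(
      n_per_line = as.integer(n_per_line),
      n_metabolites_per_block = as.integer(n_metabolites_per_block),
      frac_affected = frac_affected,
      effect_size_range = effect_size_range,
      zero_rate_range = zero_rate_range,
      imf_base = imf_base, imf_line_gap = imf_line_gap,
      imf_noise_sd = imf_noise_sd,
      log_mean_range = log_mean_range, log_sd_range = log_sd_range,
      corr_rank = as.integer(corr_rank), corr_weight = corr_weight,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic metabolome panel
#'
#' Abundances are log-normal per metabolite: a Gaussian on the log scale with
#' a planted mean shift between lines equal to the planted effect times the
#' metabolite's log SD, so the effect is expressed in SD units of the
#' (log-scale) trait, which downstream Bayesian standardization can recover.
#' Zeros are injected per metabolite at a Bernoulli rate drawn from
#' `zero_rate_range`, independently per line. IMF is
#' `imf_base + (line == H) * imf_line_gap + N(0, imf_noise_sd)`.
#'
#' @param config A [synth_config()].
#' @return A [metabolome_panel()] with a `truth` vector of planted SD-unit
#'   effects (0 where unaffected).
#' @export
generate_panel <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, .stage[["synth"]]))
  n <- 2L * config$n_per_line
  sizes <- config$n_metabolites_per_block
  p <- sum(sizes)
  blocks <- c("positive-early", "positive-late", "negative", "polar")
  block <- rep(blocks, sizes)
  met_ids <- sprintf("met_%04d", seq_len(p))
  names(block) <- met_ids
  sample_ids <- sprintf("S%02d", seq_len(n))
  line <- rep(c("H", "L"), each = config$n_per_line)
  sex <- rep(rep(c("M", "F"), each = config$n_per_line / 2L), 2L)

  mu <- stats::runif(p, config$log_mean_range[1], config$log_mean_range[2])
  sdev <- stats::runif(p, config$log_sd_range[1], config$log_sd_range[2])
  n_aff <- round(config$frac_affected * p)
  affected <- sort(sample.int(p, n_aff))
  truth <- numeric(p)
  if (n_aff > 0) {
    truth[affected] <- stats::runif(
      n_aff, config$effect_size_range[1], config$effect_size_range[2]
    ) * sample(c(-1, 1), n_aff, replace = TRUE)
  }
  names(truth) <- met_ids

  # log-scale data; line shift is +effect/2 for H, -effect/2 for L (in units
  # of the metabolite's own log SD), so mean_H - mean_L = effect * sd.
  shift <- outer(ifelse(line == "H", 0.5, -0.5), truth * sdev)
  logx <- matrix(stats::rnorm(n * p), n, p)
  if (config$corr_rank > 0) {
    fac <- matrix(stats::rnorm(n * config$corr_rank), n, config$corr_rank)
    load <- matrix(stats::rnorm(config$corr_rank * p, sd = config$corr_weight),
                   config$corr_rank, p)
    logx <- sqrt(1 / (1 + config$corr_weight^2 * config$corr_rank)) *
      (logx + fac %*% load)
  }
  logx <- sweep(logx, 2, sdev, "*")
  logx <- sweep(logx, 2, mu, "+") + shift
  ab <- exp(logx)
  dimnames(ab) <- list(sample_ids, met_ids)

  # per-metabolite, per-line zero rates
  rate_h <- stats::runif(p, config$zero_rate_range[1], config$zero_rate_range[2])
  rate_l <- stats::runif(p, config$zero_rate_range[1], config$zero_rate_range[2])
  zmask <- matrix(FALSE, n, p)
  hrows <- which(line == "H"); lrows <- which(line == "L")
  zmask[hrows, ] <- matrix(stats::runif(length(hrows) * p), length(hrows), p) <
    matrix(rate_h, length(hrows), p, byrow = TRUE)
  zmask[lrows, ] <- matrix(stats::runif(length(lrows) * p), length(lrows), p) <
    matrix(rate_l, length(lrows), p, byrow = TRUE)
  ab[zmask] <- 0

  imf <- config$imf_base + (line == "H") * config$imf_line_gap +
    stats::rnorm(n, 0, config$imf_noise_sd)
  meta <- data.frame(sample_id = sample_ids, line = line, sex = sex, imf = imf)
  metabolome_panel(ab, block, meta, truth)
}

#' Inject additional missingness (zeros) into a panel
#'
#' Places zeros by independent Bernoulli draws per cell. The pre-injection
#' abundances are stored in attribute `"original"` of the returned panel's
#' abundance matrix so imputation accuracy can be benchmarked against them.
#'
#' @param panel A [metabolome_panel()].
#' @param rates Scalar or per-metabolite vector of zero probabilities in
#'   `[0,1]`.
#' @param seed Integer seed.
#' @return The panel with zeros injected.
#' @export
inject_missingness <- function(panel, rates, seed = 1L) {
  stopifnot(inherits(panel, "metabolome_panel"))
  p <- ncol(panel$abundance)
  rates <- rep_len(rates, p)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]")
  set.seed(derive_seed(seed, .stage[["missing"]]))
  n <- nrow(panel$abundance)
  mask <- matrix(stats::runif(n * p), n, p) <
    matrix(rates, n, p, byrow = TRUE)
  original <- panel$abundance
  ab <- original
  ab[mask] <- 0
  out <- metabolome_panel(ab, panel$block, panel$meta, panel$truth)
  attr(out$abundance, "original") <- original
  out
}
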