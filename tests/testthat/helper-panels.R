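# Small builders shared across tests.

# A compact four-block panel; zero_rate 0 by default so preprocessing stages
# can be exercised in isolation.
tiny_panel <- function(n_per_line = 24, sizes = c(12, 8, 14, 6),
                       frac_affected = 0.35, zero = c(0, 0), seed = 42,
                       ...) {
  generate_panel(synth_config(
    n_per_line = n_per_line, n_metabolites_per_block = sizes,
    frac_affected = frac_affected, zero_rate_range = zero, seed = seed, ...
  ))
}

# Hand-built panel with explicit abundances for filter/impute edge cases.
manual_panel <- function(ab, line = NULL, sex = NULL, imf = NULL,
                         block = NULL) {
  n <- nrow(ab); p <- ncol(ab)
  rownames(ab) <- sprintf("S%02d", seq_len(n))
  colnames(ab) <- sprintf("met_%04d", seq_len(p))
  if (is.null(line)) line <- rep(c("H", "L"), each = n / 2)
  if (is.null(sex)) sex <- rep_len(c("M", "F"), n)
  if (is.null(imf)) imf <- seq_len(n) / 10
  if (is.null(block)) block <- setNames(rep("polar", p), colnames(ab))
  metabolome_panel(ab, block, data.frame(
    sample_id = rownames(ab), line = line, sex = sex, imf = imf
  ))
}

# Independent Procrustes-correlation oracle: explicitly builds the requested
# configurations, double-centers by column means, and solves the orthogonal
# Procrustes problem through the SVD of the cross-product, returning
# sqrt(1 - m12^2) without any score-space reduction.
procrustes_corr_bruteforce <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a), "-")
  bc <- sweep(b, 2, colMeans(b), "-")
  # pad the narrower configuration with zero columns so rotation is square
  k <- max(ncol(ac), ncol(bc))
  ac <- cbind(ac, matrix(0, nrow(ac), k - ncol(ac)))
  bc <- cbind(bc, matrix(0, nrow(bc), k - ncol(bc)))
  d <- svd(crossprod(ac, bc))$d
  m2 <- 1 - sum(d)^2 / (sum(ac^2) * sum(bc^2))
  sqrt(max(0, 1 - m2))
}

# All J(J-1)/2 pairwise log-ratio columns of a positive matrix.
pairwise_logratios <- function(x) {
  lx <- log(x)
  J <- ncol(x)
  pairs <- utils::combn(J, 2)
  out <- apply(pairs, 2, function(ij) lx[, ij[1]] - lx[, ij[2]])
  matrix(out, nrow = nrow(x))
}
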