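sim_two_lines <- function(n_per_line = 12, effect = 0, sd = 1, seed = 1) {
  set.seed(seed)
  line <- rep(c("H", "L"), each = n_per_line)
  sex <- rep(rep(c("M", "F"), n_per_line / 2), 2)
  y <- ifelse(line == "H", effect / 2, -effect / 2) * sd +
    rnorm(2 * n_per_line, 0, sd)
  list(y = y, line = line, sex = sex)
}

test_that("Gibbs posterior mean matches the least-squares estimate", {
  d <- sim_two_lines(effect = 1.2, seed = 2)
  spec <- linear_model_spec(d$y, d$line, d$sex)
  draws <- gibbs_sample(spec, n_draws = 20000, burn_in = 2000, seed = 3)
  ols <- qr.solve(spec$design, d$y)
  mc_se <- apply(draws[, 1:3], 2, sd) / sqrt(nrow(draws) / 10)
  expect_true(all(abs(colMeans(draws[, 1:3]) - ols) < 6 * mc_se))
})

test_that("Gibbs marginals match the closed-form flat-prior posterior", {
  # analytic oracle: with flat priors on b and sigma2, integrating sigma2
  # out of the normal likelihood leaves b marginally multivariate t with
  # df = n - p - 2, location b_hat, scale RSS/df * (X'X)^-1
  d <- sim_two_lines(n_per_line = 10, effect = 0.8, seed = 5)
  spec <- linear_model_spec(d$y, d$line, d$sex)
  X <- spec$design; y <- spec$y
  n <- length(y); p <- ncol(X)
  b_hat <- qr.solve(X, y)
  rss <- sum((y - X %*% b_hat)^2)
  nu <- n - p - 2
  xtxi <- solve(crossprod(X))

  draws <- gibbs_sample(spec, n_draws = 60000, burn_in = 5000, seed = 7)
  for (k in seq_len(p)) {
    sc <- sqrt(rss / nu * xtxi[k, k])
    z <- (draws[seq(1, nrow(draws), by = 10), k] - b_hat[k]) / sc
    ks <- suppressWarnings(ks.test(z, pt, df = nu))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("identical line distributions give a null-centered contrast", {
  d <- sim_two_lines(n_per_line = 24, effect = 0, seed = 11)
  spec <- linear_model_spec(d$y, d$line, d$sex)
  draws <- gibbs_sample(spec, n_draws = 20000, burn_in = 2000, seed = 13)
  s <- summarize_difference(draws[, "line"], pooled_sd(d$y, d$line))
  expect_lt(abs(s$d_hl_median), 3 / sqrt(24))
  expect_lt(s$p0, 0.995)
  expect_gte(s$p0, 0.5)
  expect_true(s$hpd95[1] <= s$d_hl_median && s$d_hl_median <= s$hpd95[2])
})

test_that("difference summaries follow their definitions", {
  s <- summarize_difference(rep(2.5, 100), 1)
  expect_equal(s$d_hl_median, 2.5)
  expect_equal(unname(s$hpd95), c(2.5, 2.5))
  expect_equal(s$p0, 1)
  expect_equal(s$d_sd_units, 2.5)

  set.seed(17)
  sym <- c(rnorm(50000), -rnorm(50000))  # exactly symmetric about 0
  s2 <- summarize_difference(sym, 2)
  expect_lt(abs(s2$p0 - 0.5), 0.02)

  # Gaussian CDF oracle: draws ~ N(2,1) -> P0 = Phi(2)
  set.seed(19)
  s3 <- summarize_difference(rnorm(10000) + 2, 1)
  expect_lt(abs(s3$p0 - pnorm(2)), 0.01)

  expect_error(summarize_difference(numeric(0), 1), "empty")
  expect_error(summarize_difference(rnorm(5), 0), "positive")
})

test_that("HPD is the shortest interval and never wider than equal tails", {
  set.seed(23)
  for (draws in list(rnorm(5000), rexp(5000), rt(5000, 3))) {
    h <- hpd_interval(draws, 0.95)
    et <- quantile(draws, c(0.025, 0.975))
    expect_lte(diff(h), diff(unname(et)) + 1e-12)
    covered <- mean(draws >= h[1] & draws <= h[2])
    expect_gte(covered, 0.95 - 1e-3)
  }
})

test_that("P0 is 1 when every draw shares one sign", {
  expect_equal(summarize_difference(abs(rnorm(100)) + 0.1, 1)$p0, 1)
  expect_equal(summarize_difference(-abs(rnorm(100)) - 0.1, 1)$p0, 1)
})

test_that("per-metabolite fits are reproducible and shaped one row each", {
  p <- tiny_panel(sizes = c(4, 3, 4, 3), zero = c(0, 0), seed = 3)
  tr <- process_blocks(p, impute = FALSE)$transformed
  sel <- colnames(tr)[1:3]
  t1 <- fit_all_selected(tr, p$meta, sel, n_draws = 3000, burn_in = 500,
                         seed = 9)
  t2 <- fit_all_selected(tr, p$meta, sel, n_draws = 3000, burn_in = 500,
                         seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 3)
  one <- fit_all_selected(tr, p$meta, sel[2], n_draws = 3000, burn_in = 500,
                          seed = 9)
  expect_equal(nrow(one), 1)
  expect_error(fit_all_selected(tr, p$meta, character(0)), "empty")
  expect_error(fit_all_selected(tr, p$meta, "not_a_met"), "absent")
})

test_that("estimated standardized differences are unbiased across the
           planted-effect grid", {
  for (effect in c(0.23, 1, 3, 6.04)) {
    est <- vapply(1:20, function(r) {
      d <- sim_two_lines(n_per_line = 24, effect = effect, seed = 1000 + r)
      spec <- linear_model_spec(d$y, d$line, d$sex)
      draws <- gibbs_sample(spec, n_draws = 4000, burn_in = 500,
                            seed = 2000 + r)
      summarize_difference(draws[, "line"],
                           pooled_sd(d$y, d$line))$d_sd_units
    }, numeric(1))
    # simulation error of the mean over 20 replicates at n = 24/line
    expect_lt(abs(mean(est) - effect), 4 * sd(est) / sqrt(20) + 0.05)
  }
})

test_that("model specification rejects degenerate designs", {
  expect_error(linear_model_spec(rnorm(4), rep("H", 4)), "rank-deficient")
  expect_error(linear_model_spec(rnorm(3), c("H", "L", "H"), c("M", "F", "F")),
               "more samples")
})
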