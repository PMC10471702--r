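make_signal_data <- function(n_per_line = 24, p = 40, n_signal = 8,
                             effect = 2, seed = 1) {
  set.seed(seed)
  line <- rep(c("H", "L"), each = n_per_line)
  X <- matrix(rnorm(2 * n_per_line * p), 2 * n_per_line, p,
              dimnames = list(NULL, sprintf("m%03d", seq_len(p))))
  X[, seq_len(n_signal)] <- X[, seq_len(n_signal)] +
    outer(ifelse(line == "H", effect / 2, -effect / 2), rep(1, n_signal))
  # IMF tightly coupled to line so regression folds rarely hit the Q2
  # exclusion; exclusion behaviour itself is tested with weaker signal
  imf <- 0.835 + (line == "H") * 0.45 + rnorm(2 * n_per_line, 0, 0.07)
  list(X = X, line = line, imf = imf)
}

test_that("CMV bookkeeping: model counts, fold geometry, test coverage", {
  d <- make_signal_data(p = 20, seed = 2)
  cc <- cmv_config(iterations = 3, seed = 5)
  res <- run_cmv(d$X, d$line, "discriminant", cc)
  expect_equal(res$n_models, 3 * 8)
  expect_true(all(res$tally <= res$n_models))

  # every fold holds exactly 48/8 = 6 samples, 3 per line
  for (rec in res$models) {
    expect_length(rec$test_idx, 6)
    expect_equal(sum(d$line[rec$test_idx] == "H"), 3)
  }
  # each sample is tested exactly `iterations` times
  counts <- table(unlist(lapply(res$models, `[[`, "test_idx")))
  expect_true(all(counts == 3))
})

test_that("toy two-fold run stays within its tally bound", {
  d <- make_signal_data(n_per_line = 6, p = 6, n_signal = 2, seed = 3)
  cc <- cmv_config(iterations = 1, outer_folds = 2, inner_folds = 3, seed = 1)
  res <- run_cmv(d$X, d$line, "discriminant", cc)
  expect_equal(res$n_models, 2)
  expect_true(all(res$tally <= 2))
})

test_that("consensus threshold is strict and intersects both modes", {
  mk <- function(v, n) {
    t <- setNames(as.integer(v), paste0("m", seq_along(v)))
    attr(t, "n_models") <- n
    t
  }
  cc <- cmv_config()
  # 160 models: > 128 needed; 129 passes, 128 does not
  expect_equal(consensus_selection(mk(c(129, 128, 160), 160),
                                   mk(c(129, 129, 0), 160), cc),
               "m1")
  expect_length(consensus_selection(mk(c(0, 0), 160), mk(c(0, 0), 160), cc), 0)
  expect_error(consensus_selection(mk(1, 160), mk(c(1, 1), 160), cc),
               "universe")
})

test_that("raising the VIP threshold never raises a tally", {
  d <- make_signal_data(p = 25, seed = 7)
  base <- cmv_config(iterations = 2, seed = 13)
  strict <- base; strict$vip_threshold <- 1.3
  r1 <- run_cmv(d$X, d$line, "discriminant", base)
  r2 <- run_cmv(d$X, d$line, "discriminant", strict)
  expect_true(all(r2$tally <= r1$tally))
})

test_that("true labels outperform permuted labels on planted signal", {
  d <- make_signal_data(p = 30, n_signal = 10, effect = 2.5, seed = 11)
  cc <- cmv_config(iterations = 2, seed = 17)
  truth <- run_cmv(d$X, d$line, "discriminant", cc)
  perm <- permutation_cmv(d$X, d$line, "discriminant", cc, n_permutations = 1)
  expect_lt(truth$average_misclassification, 15)
  expect_gt(perm[[1]]$average_misclassification,
            truth$average_misclassification)
  expect_gt(perm[[1]]$average_misclassification, 25)
})

test_that("permuting a constant response propagates the zero-variance error", {
  d <- make_signal_data(n_per_line = 8, p = 6, n_signal = 2, seed = 4)
  expect_error(
    permutation_cmv(d$X, rep(1.5, 16), "regression",
                    cmv_config(iterations = 1, seed = 1)),
    "zero-variance"
  )
})

test_that("regression permutation null centers Q2 at or below zero", {
  d <- make_signal_data(p = 25, n_signal = 10, effect = 2, seed = 19)
  cc <- cmv_config(iterations = 2, seed = 23)
  perm <- permutation_cmv(d$X, d$imf, "regression", cc, n_permutations = 1)
  expect_lt(mean(perm[[1]]$q2_distribution), 0.1)
  # the informative response, by contrast, predicts well
  truth <- run_cmv(d$X, d$imf, "regression", cc, strata = d$line)
  expect_gt(mean(truth$q2_distribution), mean(perm[[1]]$q2_distribution))
})

test_that("Q2 exclusion removes models from the tally but not the count", {
  d <- make_signal_data(p = 20, n_signal = 4, effect = 0.8, seed = 29)
  cc <- cmv_config(iterations = 2, seed = 31)
  res <- run_cmv(d$X, d$imf, "regression", cc, strata = d$line)
  expect_equal(res$n_models, 16)
  if (length(res$excluded_models)) {
    # recompute the tally without exclusions and check it dominates
    t2 <- setNames(integer(ncol(d$X)), colnames(d$X))
    for (rec in res$models) t2[rec$selected] <- t2[rec$selected] + 1L
    expect_true(all(res$tally <= t2))
    expect_true(any(res$tally < t2) ||
                  all(lengths(lapply(res$models[res$excluded_models],
                                     `[[`, "selected")) == 0))
  }
})

test_that("empty selections fall back to majority prediction, tally nothing", {
  d <- make_signal_data(p = 10, n_signal = 0, seed = 37)
  cc <- cmv_config(iterations = 1, seed = 41)
  cc$vip_threshold <- 100  # force empty selection in every fold
  res <- run_cmv(d$X, d$line, "discriminant", cc)
  expect_equal(res$n_models, 8)
  expect_true(all(res$tally == 0))
  expect_true(all(lengths(lapply(res$models, `[[`, "selected")) == 0))
  # balanced training majorities -> tie broken toward class code 0 -> 50%
  expect_equal(res$average_misclassification, 50)
})

test_that("planted metabolites dominate the consensus on strong signal", {
  d <- make_signal_data(p = 30, n_signal = 6, effect = 3, seed = 43)
  cc <- cmv_config(iterations = 3, seed = 47)
  da <- run_cmv(d$X, d$line, "discriminant", cc)
  pls <- run_cmv(d$X, d$imf, "regression", cc, strata = d$line)
  cons <- consensus_selection(da, pls, cc)
  signal <- colnames(d$X)[1:6]
  expect_gt(mean(signal %in% cons), 0.5)
  # false selections among the 24 null metabolites stay rare
  expect_lt(mean(setdiff(colnames(d$X), signal) %in% cons), 0.15)
})
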