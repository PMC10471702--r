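test_that("a single proportional predictor is fitted exactly", {
  set.seed(1)
  x <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "m1"))
  y <- 3 * x[, 1] + 5
  m <- fit_pls(x, y, 1)
  expect_equal(m$n_components, 1)
  expect_equal(unname(predict(m, x)), unname(y), tolerance = 1e-10)
  expect_equal(unname(m$coefficients), 3, tolerance = 1e-10)
})

test_that("score/loading predictions equal the collapsed coefficient form", {
  set.seed(2)
  X <- matrix(rnorm(15 * 6), 15, 6, dimnames = list(NULL, paste0("m", 1:6)))
  y <- rnorm(15)
  m <- fit_pls(X, y, 3)
  via_scores <- drop(m$scores %*% m$y_loadings) + m$y_mean
  expect_equal(unname(predict(m, X)), via_scores, tolerance = 1e-10)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(3)
  X <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- rnorm(10)
  m <- fit_pls(X, y, 5)
  ols <- lm(y ~ X)
  expect_equal(unname(m$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-8)
  expect_equal(unname(predict(m, X)), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(4)
  X <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("m", 1:8)))
  y <- rnorm(20)
  m <- fit_pls(X, y, 5)
  g <- crossprod(m$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-10)
})

test_that("VIP satisfies its formula, symmetry, and unit mean square", {
  set.seed(5)
  # literal-formula oracle on a 3-predictor fit
  X <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(NULL, paste0("m", 1:3)))
  y <- rnorm(12)
  m <- fit_pls(X, y, 2)
  p <- ncol(X)
  ssy <- m$ssy
  vip_lit <- sapply(seq_len(p), function(j) {
    num <- 0; den <- 0
    for (a in seq_len(m$n_components)) {
      w <- m$x_weights[, a]
      num <- num + ssy[a] * (w[j] / sqrt(sum(w^2)))^2
      den <- den + ssy[a]
    }
    sqrt(p * num / den)
  })
  expect_equal(unname(vip_scores(m)), vip_lit, tolerance = 1e-10)
  expect_equal(mean(vip_scores(m)^2), 1, tolerance = 1e-10)

  # one-component model: VIP_j = sqrt(p) |w_j| / ||w||
  m1 <- fit_pls(X, y, 1)
  expect_equal(unname(vip_scores(m1)),
               sqrt(p) * abs(m1$x_weights[, 1]), tolerance = 1e-10)

  # identical predictor copies share VIP = 1
  Xc <- matrix(rep(rnorm(12), 3), 12, 3, dimnames = list(NULL, paste0("c", 1:3)))
  mc <- fit_pls(Xc, rnorm(12), 1)
  expect_equal(unname(vip_scores(mc)), rep(1, 3), tolerance = 1e-10)
})

test_that("unit mean-square VIP holds across random fits", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(8:30, 1); p <- sample(2:12, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
    m <- fit_pls(X, rnorm(n), sample.int(min(p, n - 2), 1))
    expect_equal(mean(vip_scores(m)^2), 1, tolerance = 1e-8)
  }
})

test_that("PLS-DA separates separable data and is coding-symmetric", {
  set.seed(7)
  cls <- rep(c("H", "L"), each = 10)
  X <- cbind(code = as.numeric(cls == "H"),
             matrix(rnorm(20 * 3), 20, 3))
  colnames(X) <- paste0("m", 1:4)
  m <- fit_plsda(X, cls, 4)  # full rank: the code column interpolates y
  expect_equal(classify_plsda(m, X), cls)  # 0% training misclassification

  # relabeling the classes flips codes but not decisions
  cls2 <- ifelse(cls == "H", "b", "a")
  m2 <- fit_plsda(X, cls2, 4)
  expect_equal(classify_plsda(m2, X) == "b", classify_plsda(m, X) == "H")
  expect_error(fit_plsda(X, rep("H", 20), 2), "two classes")
})

test_that("uninformative labels classify at chance level", {
  set.seed(8)
  miss <- replicate(60, {
    X <- matrix(rnorm(24 * 4), 24, 4, dimnames = list(NULL, paste0("m", 1:4)))
    cls <- rep(c("H", "L"), 12)
    tr <- sample(24, 16)
    m <- fit_plsda(X[tr, ], cls[tr], 2)
    mean(classify_plsda(m, X[-tr, ]) != cls[-tr])
  })
  # binomial interval around 0.5 for 60 x 8 dependent-ish trials, generous
  expect_gt(mean(miss), 0.35)
  expect_lt(mean(miss), 0.65)
})

test_that("jackknife intervals collapse for deterministic coefficients and
           match the literal formula", {
  set.seed(9)
  # y exactly linear in a single predictor: every segment refit identical
  x <- matrix(seq_len(21) + 0, 21, 1, dimnames = list(NULL, "m1"))
  y <- 2 * x[, 1]
  m <- fit_pls(x, y, 1)
  ci <- coefficient_ci(x, y, m, inner_folds = 3, seed = 1)
  expect_equal(unname(ci[, "low"]), unname(ci[, "high"]), tolerance = 1e-10)
  expect_equal(unname(ci[, "low"]), unname(m$coefficients), tolerance = 1e-10)

  # literal reimplementation of Martens' jackknife on random data
  X <- matrix(rnorm(21 * 4), 21, 4, dimnames = list(NULL, paste0("m", 1:4)))
  y2 <- rnorm(21)
  m2 <- fit_pls(X, y2, 2)
  segs <- split(1:21, rep(1:3, each = 7))
  ci2 <- coefficient_ci(X, y2, m2, inner_folds = segs)
  bmat <- sapply(segs, function(s)
    fit_pls(X[-s, ], y2[-s], 2)$coefficients)
  se <- sqrt((3 - 1) / 3 * rowSums((bmat - m2$coefficients)^2))
  tq <- qt(0.975, 2)
  expect_equal(unname(ci2[, "low"]), unname(m2$coefficients - tq * se),
               tolerance = 1e-10)
  # exclusion of zero iff |coef| > t * SE
  excl <- ci2[, "low"] > 0 | ci2[, "high"] < 0
  expect_equal(unname(excl), unname(abs(m2$coefficients) > tq * se))
})

test_that("jackknife CI coverage under a pure-noise response is near nominal", {
  set.seed(10)
  hits <- replicate(200, {
    X <- matrix(rnorm(21 * 2), 21, 2, dimnames = list(NULL, c("m1", "m2")))
    y <- rnorm(21)
    m <- fit_pls(X, y, 1)
    ci <- coefficient_ci(X, y, m, inner_folds = 7)
    ci[, "low"] > 0 | ci[, "high"] < 0
  })
  # true coefficients are 0; exclusion rate should sit near alpha = 5%
  rate <- mean(hits)
  expect_lt(abs(rate - 0.05), 2.5 * sqrt(0.05 * 0.95 / 400) + 0.04)
})

test_that("Q2 follows its definition and affine invariance", {
  expect_equal(q2_statistic(c(1, 2), c(1, 2), 1.5), 1)
  y <- c(1, 2, 3)
  expect_equal(q2_statistic(y, rep(2, 3), 2), 0)
  expect_equal(q2_statistic(y, c(1, 1, 3), 2), 0.5)
  set.seed(11)
  yt <- rnorm(10); yp <- rnorm(10); m <- mean(yt)
  expect_equal(q2_statistic(3 * yt - 2, 3 * yp - 2, 3 * m - 2),
               q2_statistic(yt, yp, m), tolerance = 1e-12)
  expect_error(q2_statistic(numeric(0), numeric(0), 0), "nonempty")
  expect_error(q2_statistic(c(1, 1), c(0, 0), 1), "denominator")
})
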