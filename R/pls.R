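#' Fit a univariate partial least squares (PLS1) model by NIPALS
#'
#' Components are extracted sequentially: the weight vector is the
#' normalized covariance direction `X'y / ||X'y||`, scores are `t = Xw`,
#' X is deflated by its rank-one reconstruction from `t`, and y by its
#' regression on `t`. Extraction stops early (with fewer components than
#' requested) when X or y is exhausted. The component weights, loadings and
#' y-loadings are collapsed to a single coefficient vector so that
#' `yhat = (X - center)/scale %*% coefficients + intercept`.
#'
#' @param X Numeric predictor matrix (samples x predictors). Expected
#'   column-standardized upstream; `center`/`scale` control any further
#'   internal treatment.
#' @param y Numeric response vector.
#' @param n_components Number of latent components to extract.
#' @param center Center X columns and y internally (default TRUE).
#' @param scale Scale X columns to unit SD internally (default FALSE; the
#'   workflow standardizes once, globally, before modelling).
#' @return A list of class `pls_model` with `x_weights`, `x_loadings`,
#'   `y_loadings`, `scores`, `coefficients`, `intercept`, `vip`, `center`,
#'   `scale`, `n_components` (effective count).
#' @export
fit_pls <- function(X, y, n_components, center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (stats::var(y) == 0) stop("zero-variance response")
  n <- nrow(X); p <- ncol(X)
  n_components <- min(n_components, p, n - 1L)
  cvec <- if (center) colMeans(X) else rep(0, p)
  svec <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(svec == 0)) stop("zero-variance predictor cannot be scaled")
  Xc <- sweep(sweep(X, 2, cvec, "-"), 2, svec, "/")
  ym <- mean(y)
  yc <- y - ym

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  Tm <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  Xd <- Xc; yd <- yc
  a <- 0L
  for (k in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(yd^2)))) break
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-24) break
    pp <- crossprod(Xd, tt) / tt2
    qq <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pp)
    yd <- yd - qq * tt
    a <- a + 1L
    W[, a] <- w; P[, a] <- pp; Q[a] <- qq; Tm[, a] <- tt
    ssy[a] <- qq^2 * tt2
  }
  if (a == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[seq_len(a)]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  ssy <- ssy[seq_len(a)]

  # collapsed regression vector: B = W (P'W)^{-1} q
  B <- W %*% solve(crossprod(P, W), Q)
  coefficients <- drop(B)
  names(coefficients) <- colnames(X)

  # VIP_j = sqrt(p * sum_a ssy_a w_ja^2 / sum_a ssy_a); weights are unit norm
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X)

  structure(
    list(
      n_components = a, x_weights = W, x_loadings = P, y_loadings = Q,
      scores = Tm, coefficients = coefficients, intercept = ym,
      vip = vip, center = cvec, scale = svec, y_mean = ym,
      mode = "regression", ssy = ssy
    ),
    class = "pls_model"
  )
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the same predictors.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  drop(Xs %*% object$coefficients) + object$intercept
}

#' Fit a PLS discriminant analysis model for two classes
#'
#' Classes are coded 0/1 (`"L"` = 0, `"H"` = 1 when those labels are
#' present, otherwise the first sorted level is 0) and a PLS1 regression is
#' fitted to the coded response. The classification rule assigns the class
#' coded 1 when the predicted score is >= 0.5.
#'
#' @param X Predictor matrix.
#' @param class_labels Vector with exactly two distinct labels.
#' @param n_components Latent components.
#' @param ... Passed to [fit_pls()].
#' @return A `pls_model` with `mode = "discriminant"`, `classes` (label of
#'   code 0, label of code 1).
#' @export
fit_plsda <- function(X, class_labels, n_components, ...) {
  labs <- as.character(class_labels)
  u <- sort(unique(labs))
  if (length(u) != 2) stop("exactly two classes required")
  if (setequal(u, c("H", "L"))) u <- c("L", "H")
  ycode <- as.numeric(labs == u[2])
  m <- fit_pls(X, ycode, n_components, ...)
  m$mode <- "discriminant"
  m$classes <- u
  m
}

#' Classify samples with a fitted PLS-DA model
#'
#' @param model A discriminant `pls_model`.
#' @param newdata Predictor matrix.
#' @return Character vector of predicted class labels.
#' @export
classify_plsda <- function(model, newdata) {
  if (model$mode != "discriminant") stop("not a discriminant model")
  sc <- predict(model, newdata)
  model$classes[(sc >= 0.5) + 1L]
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )` where
#' `SSY_a` is the response variance captured by component `a`. The mean of
#' the squared VIPs is 1 for every fitted model.
#'
#' @param model A fitted `pls_model`.
#' @return Numeric vector of VIP scores, one per predictor.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "pls_model")) stop("unfitted model")
  model$vip
}

#' Jackknife confidence intervals for PLS regression coefficients
#'
#' Martens' jackknife over cross-validation segment refits: the model is
#' refitted leaving out each inner segment in turn, the coefficient spread
#' around the full-data coefficients gives `SE_j^2 =
#' (g-1)/g * sum_m (b_mj - b_j)^2`, and a symmetric t interval with `g - 1`
#' degrees of freedom is returned at the requested level.
#'
#' @param X,y Training data (same as used for `model`).
#' @param model The full-training-data `pls_model`.
#' @param inner_folds Number of segments (>= 2), or a list of index vectors
#'   giving the segments explicitly.
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the random segment split when `inner_folds` is a
#'   count.
#' @return Matrix with columns `low`, `high` (one row per predictor), with
#'   attribute `"se"`.
#' @export
coefficient_ci <- function(X, y, model, inner_folds = 7L, level = 0.95,
                           seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (is.list(inner_folds)) {
    segments <- inner_folds
  } else {
    if (inner_folds < 2) stop("need at least 2 segments")
    if (!is.null(seed)) set.seed(seed)
    segments <- split(sample.int(nrow(X)),
                      rep_len(seq_len(inner_folds), nrow(X)))
  }
  g <- length(segments)
  if (g < 2) stop("need at least 2 segments")
  bfull <- model$coefficients
  bmat <- vapply(segments, function(idx) {
    fit_pls(X[-idx, , drop = FALSE], y[-idx], model$n_components,
            center = TRUE, scale = FALSE)$coefficients
  }, numeric(ncol(X)))
  if (is.null(dim(bmat))) bmat <- matrix(bmat, nrow = 1L)
  se <- sqrt((g - 1) / g * rowSums((bmat - bfull)^2))
  tq <- stats::qt(1 - (1 - level) / 2, df = g - 1)
  ci <- cbind(low = bfull - tq * se, high = bfull + tq * se)
  attr(ci, "se") <- se
  ci
}

#' Cross-validated predictive R-squared (Q-squared)
#'
#' `Q2 = 1 - sum((y - yhat)^2) / sum((y - ybar_train)^2)` where `ybar_train`
#' is the training-set mean. 1 for perfect prediction, 0 for predicting the
#' training mean, negative when worse than the mean.
#'
#' @param y_true Observed test responses.
#' @param y_pred Predicted test responses.
#' @param y_train_mean Mean of the training responses.
#' @return Scalar Q-squared (<= 1).
#' @export
q2_statistic <- function(y_true, y_pred, y_train_mean) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    stop("nonempty vectors of equal length required")
  den <- sum((y_true - y_train_mean)^2)
  if (den == 0) stop("zero denominator: test responses all at the train mean")
  1 - sum((y_true - y_pred)^2) / den
}
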