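## The weighted-MSE loss and the regressor families: constant baseline,
## (regularized) linear regression, gradient boosting and the windowed
## bidirectional-LSTM middle-bin predictor (in lstm.R).

#' Weighting constant of the weighted MSE
#'
#' `alpha` is the maximum observed true target increased by 1, so the error
#' weight `(alpha - y_true) / alpha` never reaches 0. For a transitional
#' gamma track capped at 10 this gives `alpha = 11`.
#'
#' @param targets Non-empty numeric vector of true targets.
#' @return A list of class `wmse_params` with element `alpha`.
#' @export
compute_alpha <- function(targets) {
  if (!length(targets)) stop("empty target vector")
  structure(list(alpha = max(targets) + 1), class = "wmse_params")
}

#' Weighted mean squared error
#'
#' `wMSE = (1/N) * sum((y_true - y_pred)^2 * (alpha - y_true) / alpha)`:
#' squared errors down-weighted in proportion to the true target, so
#' mistakes on high-target (never-transitioning) bins cost less.
#'
#' @param y_true,y_pred Equal-length numeric vectors; all `y_true < alpha`.
#' @param params A [compute_alpha()] result, or a bare numeric alpha.
#' @return Non-negative scalar; 0 iff the prediction is exact.
#' @export
wmse <- function(y_true, y_pred, params) {
  alpha <- if (inherits(params, "wmse_params")) params$alpha else params
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (any(y_true >= alpha))
    stop("y_true >= alpha would give a non-positive error weight")
  mean((y_true - y_pred)^2 * (alpha - y_true) / alpha)
}

## Shared input plumbing: models other than the biLSTM work on flat per-bin
## features, i.e. a windowed dataset with t = 1 (or a plain matrix + targets).
flat_xy <- function(train) {
  if (inherits(train, "windowed_dataset"))
    list(x = flatten_windows(train), y = train$targets)
  else if (is.list(train) && all(c("x", "y") %in% names(train)))
    list(x = as.matrix(train$x), y = train$y)
  else stop("unsupported training input")
}

#' Constant-baseline model
#'
#' Predicts the training-target mean everywhere. By construction its R^2 on
#' its own training split is exactly 0.
#'
#' @param train A `windowed_dataset` (any window size) or `list(x, y)`.
#' @return A model of class `hichip_constant`.
#' @export
fit_constant <- function(train) {
  y <- if (inherits(train, "windowed_dataset")) train$targets else train$y
  if (!length(y)) stop("empty training set")
  structure(list(mean = mean(y), family = "constant"),
            class = c("hichip_constant", "hichip_model"))
}

#' Linear regression with optional L1/L2 penalties
#'
#' Ordinary least squares when both penalties are 0 (falling back to the
#' minimum-norm pseudoinverse solution, with a warning, when the design is
#' singular). Otherwise a lasso / ridge / elastic-net fit with per-penalty
#' strengths `l1` and `l2` in the "1/(2n) RSS + l1*|b|_1 + l2/2*|b|_2^2"
#' parameterization, mapped onto glmnet's `(lambda, alpha)` as
#' `lambda = l1 + l2`, `alpha = l1 / (l1 + l2)`.
#'
#' @param train A `windowed_dataset` with `t = 1`, or `list(x, y)`.
#' @param l1,l2 Penalty strengths (default 0 = none; 0.2 is the scanned
#'   operating point for either penalty).
#' @return A model of class `hichip_linear` exposing `coef()`.
#' @export
fit_linear <- function(train, l1 = 0, l2 = 0) {
  d <- flat_xy(train)
  x <- d$x; y <- d$y
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(x)))
  if (l1 == 0 && l2 == 0) {
    X <- cbind(`(Intercept)` = 1, x)
    fit <- qr(X)
    if (fit$rank < ncol(X)) {
      warning("singular design: using the minimum-norm pseudoinverse solution")
      sv <- svd(X)
      pos <- sv$d > max(sv$d) * 1e-10
      beta <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
      beta <- drop(beta)
    } else beta <- qr.coef(fit, y)
    coefs <- setNames(beta[-1], nm)
    intercept <- unname(beta[1])
  } else {
    lambda <- l1 + l2
    mix <- l1 / lambda
    xg <- x
    if (ncol(xg) == 1L) xg <- cbind(xg, `..pad..` = 0)  # glmnet needs >= 2 cols
    g <- glmnet::glmnet(xg, y, family = "gaussian", alpha = mix,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
    b <- as.numeric(coef(g))
    intercept <- b[1]
    coefs <- setNames(b[2:(ncol(x) + 1)], nm)
  }
  structure(list(coefficients = coefs, intercept = intercept,
                 l1 = l1, l2 = l2, family = "linear"),
            class = c("hichip_linear", "hichip_model"))
}

#' @export
coef.hichip_linear <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Gradient-boosted regression trees
#'
#' Least-squares boosting (xgboost backend), deterministic given the seed.
#' `weight_by_target = TRUE` trains with per-sample weights
#' `(alpha - y)/alpha` so the training objective matches the wMSE metric;
#' off by default.
#'
#' @param train A `windowed_dataset` with `t = 1`, or `list(x, y)`.
#' @param n_estimators Number of trees (reference operating points: 100
#'   with depth 3, or 250 with depth 4).
#' @param max_depth Tree depth.
#' @param learning_rate Shrinkage (default 0.01).
#' @param weight_by_target Align training weights with the wMSE loss.
#' @param seed Integer seed.
#' @return A model of class `hichip_gboost`.
#' @export
fit_gboost <- function(train, n_estimators = 100, max_depth = 3,
                       learning_rate = 0.01, weight_by_target = FALSE,
                       seed = 1L) {
  if (n_estimators < 1) stop("config error: n_estimators must be >= 1")
  d <- flat_xy(train)
  w <- NULL
  if (weight_by_target) {
    alpha <- compute_alpha(d$y)$alpha
    w <- (alpha - d$y) / alpha
  }
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(d$x, label = d$y, weight = w)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = max_depth,
                  eta = learning_rate, nthread = 1,
                  base_score = mean(d$y), seed = seed),
    data = dtrain, nrounds = n_estimators, verbose = 0)
  structure(list(booster = booster, n_features = ncol(d$x),
                 mark_names = colnames(d$x), family = "gboost"),
            class = c("hichip_gboost", "hichip_model"))
}

#' Predictions from a fitted model
#'
#' One prediction per window / row; a pure function of the fitted state.
#'
#' @param object A fitted `hichip_*` model.
#' @param newdata A `windowed_dataset` (matching the model family's window
#'   size), or `list(x, y)` / matrix for flat models.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @name predict.hichip_model
NULL

as_flat_matrix <- function(newdata) {
  if (inherits(newdata, "windowed_dataset")) flatten_windows(newdata)
  else if (is.list(newdata) && "x" %in% names(newdata)) as.matrix(newdata$x)
  else as.matrix(newdata)
}

#' @rdname predict.hichip_model
#' @export
predict.hichip_constant <- function(object, newdata, ...) {
  n <- if (inherits(newdata, "windowed_dataset")) dim(newdata$windows)[1]
       else nrow(as_flat_matrix(newdata))
  rep(object$mean, n)
}

#' @rdname predict.hichip_model
#' @export
predict.hichip_linear <- function(object, newdata, ...) {
  x <- as_flat_matrix(newdata)
  if (ncol(x) != length(object$coefficients)) stop("feature-count mismatch")
  unname(drop(x %*% object$coefficients)) + object$intercept
}

#' @rdname predict.hichip_model
#' @export
predict.hichip_gboost <- function(object, newdata, ...) {
  x <- as_flat_matrix(newdata)
  if (ncol(x) != object$n_features) stop("feature-count mismatch")
  as.numeric(predict(object$booster, xgboost::xgb.DMatrix(x)))
}

#' @export
print.hichip_model <- function(x, ...) {
  cat(sprintf("hichipml %s model\n", x$family))
  if (x$family == "constant") cat(sprintf("  predicts %.4g\n", x$mean))
  if (x$family == "linear")
    cat(sprintf("  %d coefficients (l1 = %g, l2 = %g)\n",
                length(x$coefficients), x$l1, x$l2))
  invisible(x)
}

#' Model specification for cross-validation and importance runs
#'
#' Bundles a model family with its hyperparameters so evaluation routines
#' can retrain from scratch.
#'
#' @param family One of `"constant"`, `"linear"`, `"gboost"`, `"bilstm"`.
#' @param ... Family-specific arguments passed to the fitting function.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("constant", "linear", "gboost", "bilstm"),
                       ...) {
  family <- match.arg(family)
  structure(list(family = family, args = list(...)), class = "model_spec")
}

## Fit any spec on (train, val); val only used by the biLSTM's early stopping.
fit_spec <- function(spec, train, val = NULL, seed = NULL) {
  args <- spec$args
  if (!is.null(seed) && spec$family %in% c("gboost", "bilstm"))
    args$seed <- seed
  switch(spec$family,
         constant = fit_constant(train),
         linear = do.call(fit_linear, c(list(train), args)),
         gboost = do.call(fit_gboost, c(list(train), args)),
         bilstm = do.call(fit_bilstm, c(list(train, val), args)))
}
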