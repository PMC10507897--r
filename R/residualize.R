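#' Fit the residualizing model g
#'
#' Fits a model `g` explaining the feature of interest `z` by the remaining
#' predictors, under squared-error loss, so that `z` can be decomposed as
#' `z = g(x) + eps_z`. Three model classes are available: ordinary least
#' squares (`"ols"`, for low-dimensional problems), ridge regression
#' (`"ridge"`, preferable in higher dimensions where overfitting must be
#' penalized) and a random forest (`"rf"`, allowing non-linear and
#' non-additive dependence). To guard against overfitting — which would make
#' the residuals, and hence the residual importance, artificially small — the
#' forest variant computes its training residuals from out-of-bag predictions.
#'
#' @param x Numeric matrix of predictors (the features other than `z`).
#' @param z Numeric vector to be explained; must be continuous.
#' @param method `"ols"`, `"ridge"` or `"rf"`.
#' @param lambda Ridge penalty (>= 0); predictors are standardized internally
#'   so the penalty is scale-free, and the intercept is unpenalized.
#' @param forest A [forest_spec()] for `method = "rf"`.
#' @param seed Seed (forest variant only).
#' @return An object of class `"residual_model"` with `predict()` and
#'   `residuals()` methods. `residuals(model)` returns the training residuals
#'   (OOB-based for the forest class); `residuals(model, x, z)` evaluates
#'   fresh data.
#' @examples
#' x <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
#' z <- 2 * x[, 1] + rnorm(50, sd = 0.1)
#' g <- fit_g(x, z)
#' head(residuals(g))
#' @export
fit_g <- function(x, z, method = c("ols", "ridge", "rf"), lambda = 1,
                  forest = forest_spec(), seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.matrix(x), is.numeric(x), is.numeric(z))
  if (nrow(x) != length(z)) stop("nrow(x) must equal length(z)", call. = FALSE)
  if (nrow(x) < 2L) stop("at least 2 rows are required", call. = FALSE)
  if (anyNA(x) || anyNA(z)) stop("missing values are not supported", call. = FALSE)
  zu <- unique(z)
  if (length(zu) == 2L && all(zu %in% c(0, 1))) {
    stop("z looks binary; residualization is defined for continuous z only",
         call. = FALSE)
  }
  fit <- switch(method,
    ols = {
      qx <- cbind(`(Intercept)` = 1, x)
      f <- lm.fit(qx, z)
      beta <- f$coefficients
      beta[is.na(beta)] <- 0  # aliased (collinear) columns drop out
      list(beta = beta, fitted = drop(qx %*% beta))
    },
    ridge = {
      if (lambda < 0) stop("ridge penalty must be >= 0", call. = FALSE)
      ctr <- colMeans(x)
      scl <- apply(x, 2, sd)
      scl[scl == 0] <- 1  # constant columns carry no information
      xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
      zc <- z - mean(z)
      p <- ncol(xs)
      beta_s <- solve(crossprod(xs) + diag(lambda, p), crossprod(xs, zc))
      beta <- drop(beta_s) / scl
      intercept <- mean(z) - sum(beta * ctr)
      list(beta = c(`(Intercept)` = intercept, beta),
           fitted = drop(cbind(1, x) %*% c(intercept, beta)))
    },
    rf = {
      d <- tabular_dataset(x, z, "regression")
      fr <- train_forest(d, forest, seed = seed, ensemble_oob = TRUE)
      oob_pred <- fr$ranger$predictions
      miss <- is.na(oob_pred)
      if (any(miss)) {
        warning(sum(miss), " row(s) were in-bag for every tree; ",
                "full-forest predictions used for their residuals", call. = FALSE)
        oob_pred[miss] <- predict(fr$ranger, as.data.frame(x[miss, , drop = FALSE]),
                                  num.threads = 1L)$predictions
      }
      list(forest = fr, fitted = oob_pred)
    })
  res <- z - fit$fitted
  # An exactly explained z leaves residuals at rounding-error scale; treat
  # them as the zero vector they represent, so downstream forests do not
  # split on numerical noise.
  if (max(abs(res)) <= 1e-10 * max(1, max(abs(z)))) res[] <- 0
  structure(list(method = method, lambda = if (method == "ridge") lambda,
                 beta = fit$beta, forest = fit$forest,
                 feature_names = colnames(x),
                 fitted_values = fit$fitted, train_residuals = res,
                 in_sample_loss = mean(res^2)),
            class = "residual_model")
}

#' @export
print.residual_model <- function(x, ...) {
  cat("<residual_model> g: ", x$method,
      if (x$method == "ridge") paste0(" (lambda = ", x$lambda, ")"),
      ", in-sample MSE ", signif(x$in_sample_loss, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.residual_model <- function(object, ...) object$beta

#' Predict the explained part of z
#'
#' @param object A [fit_g()] model.
#' @param newdata Numeric matrix with the same columns `g` was fitted on.
#' @param ... Unused.
#' @return Numeric vector of predictions `g(newdata)`.
#' @export
predict.residual_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  stopifnot(is.matrix(newdata))
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    stop("newdata columns do not match the columns g was fitted on", call. = FALSE)
  }
  if (ncol(newdata) != length(object$feature_names %||% numeric(ncol(newdata)))) {
    stop("newdata has the wrong number of columns", call. = FALSE)
  }
  if (object$method == "rf") {
    predict(object$forest$ranger, as.data.frame(newdata),
            num.threads = 1L)$predictions
  } else {
    drop(cbind(1, newdata) %*% object$beta)
  }
}

#' Residual part of z
#'
#' Returns `z - g(x)`: the part of the feature of interest that the remaining
#' predictors do not explain. Called without `x`/`z` it returns the training
#' residuals (out-of-bag-based when `g` is a forest).
#'
#' @param object A [fit_g()] model.
#' @param x,z Optional new data.
#' @param ... Unused.
#' @return Numeric vector of residuals.
#' @export
residuals.residual_model <- function(object, x = NULL, z = NULL, ...) {
  if (is.null(x) && is.null(z)) return(object$train_residuals)
  stopifnot(!is.null(x), !is.null(z))
  z - predict(object, x)
}
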