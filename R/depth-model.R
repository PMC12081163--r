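#' Depth-retrieval regression models
#'
#' [depth_model()] is the package's central fitting function: it relates
#' polarization features to the depth (mm) of a buried fibrous layer with
#' one of three supervised regression algorithms - support vector
#' regression (SVR, radial kernel), k-nearest neighbours (KNN) or
#' polynomial regression (PR) - and evaluates the fit by seeded five-fold
#' cross-validation using `R^2 = 1 - SS_res / SS_tot` and
#' `RMSE = sqrt(mean((y - yhat)^2))`, plus the per-depth mean absolute
#' error.
#'
#' Four canonical feature sets mirror the grouping of the parameters by
#' what they sense (see [dspfp_feature_sets()]): `Mp` uses the
#' DOP-sensitive PBPs `Delta`, `V` and `c`; `MA` the anisotropy-sensitive
#' `Dstar`, `RA` and `t1`; `MD` the composite DSPFPs `Ct`, `CtDelta` and
#' `RVD`; and `MM` the raw `m44` element.
#'
#' @name depth-models
NULL

#' Coefficient of determination and root mean squared error
#'
#' `r_squared(y, yhat)` returns `1 - SS_res / SS_tot`;
#' `rmse(y, yhat)` returns `sqrt(mean((y - yhat)^2))`;
#' `mae_by_depth(y, yhat)` returns the mean absolute error grouped by the
#' distinct true depths.
#'
#' @param y observed values (true depths, mm).
#' @param yhat predicted values.
#' @return a scalar, or for `mae_by_depth` a data frame with columns
#'   `depth`, `mae`, `n`.
#' @name depth-metrics
#' @examples
#' r_squared(c(1, 2, 3), c(2, 2, 2))   # 0
#' rmse(c(1, 2, 3), c(2, 2, 2))        # sqrt(2/3)
NULL

#' @rdname depth-metrics
#' @export
r_squared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' @rdname depth-metrics
#' @export
rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' @rdname depth-metrics
#' @export
mae_by_depth <- function(y, yhat) {
  ae <- abs(y - yhat)
  m <- tapply(ae, y, mean)
  data.frame(depth = as.numeric(names(m)), mae = as.numeric(m),
             n = as.numeric(table(y)))
}

#' Canonical feature sets for depth retrieval
#'
#' @return named list of character vectors: `Mp` (DOP-sensitive PBPs),
#'   `MA` (anisotropy-sensitive PBPs), `MD` (DSPFPs), `MM` (the `m44`
#'   Mueller element).
#' @export
dspfp_feature_sets <- function() {
  list(Mp = c("Delta", "V", "c"),
       MA = c("Dstar", "RA", "t1"),
       MD = c("Ct", "CtDelta", "RVD"),
       MM = "m44")
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0] <- 1
  list(center = mu, scale = sg)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")

fit_engine <- function(X, y, algorithm, degree, k, cost, gamma) {
  sc <- scale_fit(X)
  Xs <- scale_apply(X, sc)
  if (algorithm == "svr") {
    if (is.null(gamma)) gamma <- 1 / ncol(X)
    fit <- e1071::svm(x = Xs, y = y, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    pred <- function(Xn) {
      requireNamespace("e1071", quietly = TRUE)  # registers predict.svm
      as.numeric(stats::predict(fit, scale_apply(Xn, sc)))
    }
  } else if (algorithm == "knn") {
    fit <- caret::knnreg(as.data.frame(Xs), y, k = k)
    pred <- function(Xn) {
      requireNamespace("caret", quietly = TRUE)  # registers predict.knnreg
      as.numeric(stats::predict(fit, as.data.frame(scale_apply(Xn, sc))))
    }
  } else {  # pr: additive per-feature polynomial terms, no interactions
    df <- as.data.frame(X)
    trm <- paste(sprintf("poly(%s, %d, raw = TRUE)", colnames(X), degree),
                 collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste("..y ~", trm)),
                     data = cbind(df, ..y = y))
    pred <- function(Xn) as.numeric(stats::predict(fit, as.data.frame(Xn)))
  }
  list(fit = fit, predict = pred, scaling = sc)
}

#' Fit a depth-retrieval regression model
#'
#' @param formula model formula, e.g. `depth ~ Ct + CtDelta + RVD`. The
#'   response is the depth in mm.
#' @param data data frame of feature records (e.g. from
#'   [generate_depth_sweep()] or [features_from_image()]). Rows whose
#'   `flag` column is TRUE are excluded; fitting errors if more than 20%
#'   of records are flagged.
#' @param algorithm `"svr"`, `"knn"` or `"pr"`.
#' @param degree polynomial degree for PR (default 3).
#' @param k neighbour count for KNN (default 5, unweighted).
#' @param cost,gamma SVR hyperparameters (defaults: cost 1,
#'   gamma `1/n_features`). Features are standardized using statistics of
#'   the training rows only, so cross-validation folds never leak.
#' @param folds cross-validation folds (default 5).
#' @param seed integer seed controlling the CV shuffle (and hence the
#'   whole fit, which is otherwise deterministic).
#' @return object of class `depth_model` with components `fit` (full-data
#'   engine), `cv` (list: `r_squared`, `rmse`, `mae`, pooled out-of-fold
#'   `pred`/`obs`), `features`, `algorithm`, `n`.
#' @seealso [predict.depth_model()], [predict_depth_map()]
#' @export
depth_model <- function(formula, data,
                        algorithm = c("svr", "knn", "pr"),
                        degree = 3, k = 5, cost = 1, gamma = NULL,
                        folds = 5, seed = NULL) {
  algorithm <- match.arg(algorithm)
  cl <- match.call()
  if ("flag" %in% names(data)) {
    frac <- mean(data$flag)
    if (frac > 0.2)
      stop(sprintf("%.0f%% of records are flagged degenerate (max 20%%)",
                   100 * frac), call. = FALSE)
    data <- data[!data$flag, , drop = FALSE]
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(formula, data = data), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) == 0) stop("empty feature list", call. = FALSE)
  n <- length(y)
  if (folds < 2 || folds > n) stop("invalid fold count", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  pred_cv <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    eng <- fit_engine(X[tr, , drop = FALSE], y[tr], algorithm,
                      degree, k, cost, gamma)
    pred_cv[!tr] <- eng$predict(X[!tr, , drop = FALSE])
  }
  full <- fit_engine(X, y, algorithm, degree, k, cost, gamma)
  structure(list(
    call = cl, formula = formula, algorithm = algorithm,
    features = colnames(X), n = n,
    degree = degree, k = k, cost = cost, gamma = gamma,
    engine = full,
    fitted_values = full$predict(X), y = y,
    cv = list(folds = folds, seed = seed, fold_id = fold_id,
              pred = pred_cv, obs = y,
              r_squared = r_squared(y, pred_cv),
              rmse = rmse(y, pred_cv),
              mae = mae_by_depth(y, pred_cv))),
    class = "depth_model")
}

#' Fit one of the canonical depth models
#'
#' Convenience wrapper around [depth_model()] using the feature sets of
#' [dspfp_feature_sets()].
#'
#' @param data feature records with a `depth` column.
#' @param model `"Mp"`, `"MA"`, `"MD"` or `"MM"`.
#' @param ... passed to [depth_model()] (`algorithm`, `seed`, ...).
#' @return a `depth_model`.
#' @export
depth_model_preset <- function(data, model = c("MD", "Mp", "MA", "MM"), ...) {
  model <- match.arg(model)
  feats <- dspfp_feature_sets()[[model]]
  f <- stats::as.formula(paste("depth ~", paste(feats, collapse = " + ")))
  out <- depth_model(f, data, ...)
  out$preset <- model
  out
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf("Depth-retrieval model (%s%s), %d features, n = %d\n",
              toupper(x$algorithm),
              if (!is.null(x$preset)) paste0(", preset ", x$preset) else "",
              length(x$features), x$n))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  %d-fold CV:  R2 = %.4f   RMSE = %.3f mm\n",
              x$cv$folds, x$cv$r_squared, x$cv$rmse))
  invisible(x)
}

#' @export
summary.depth_model <- function(object, ...) {
  structure(list(model = object, mae = object$cv$mae),
            class = "summary.depth_model")
}

#' @export
print.summary.depth_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-depth cross-validated MAE (mm):\n")
  print(x$mae, row.names = FALSE)
  invisible(x)
}

#' Predict depths for new feature records
#'
#' @param object a `depth_model`.
#' @param newdata data frame containing the model's feature columns.
#'   Rows flagged degenerate (column `flag`) yield `NA`.
#' @param ... ignored.
#' @return numeric vector of predicted depths (mm).
#' @export
predict.depth_model <- function(object, newdata, ...) {
  mask <- if ("flag" %in% names(newdata)) newdata$flag else
    rep(FALSE, nrow(newdata))
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  out <- rep(NA_real_, nrow(newdata))
  if (any(!mask))
    out[!mask] <- object$engine$predict(X[!mask, , drop = FALSE])
  out
}

#' @export
coef.depth_model <- function(object, ...) {
  if (object$algorithm != "pr") {
    message("coefficients are only available for polynomial regression")
    return(invisible(NULL))
  }
  stats::coef(object$engine$fit)
}

#' @export
residuals.depth_model <- function(object, ...) object$y - object$fitted_values

#' @export
fitted.depth_model <- function(object, ...) object$fitted_values

#' Diagnostic plot: cross-validated prediction against true depth
#'
#' @param x a `depth_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.depth_model <- function(x, ...) {
  graphics::plot(x$cv$obs, x$cv$pred,
                 xlab = "true depth (mm)", ylab = "CV predicted depth (mm)",
                 main = sprintf("%s: R2 = %.3f, RMSE = %.2f mm",
                                toupper(x$algorithm), x$cv$r_squared,
                                x$cv$rmse),
                 col = grDevices::adjustcolor("steelblue", 0.5), pch = 16, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
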