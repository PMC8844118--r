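#' Fit a habitat-suitability learner
#'
#' Four learner families behind one surface, with fixed commonly used
#' parameterizations (no per-species tuning):
#' \describe{
#'   \item{glm}{binomial GLM with linear + quadratic terms per variable.}
#'   \item{gam}{binomial additive model (mgcv thin-plate smooths, GCV
#'     smoothness selection, basis dimension capped by the data size).}
#'   \item{gbm}{gradient-boosted trees (xgboost, logistic loss, 100 rounds,
#'     depth 3, eta 0.1).}
#'   \item{rf}{classification random forest (500 trees, default mtry);
#'     suitability = fraction of trees voting presence.}
#' }
#' Predictions from every learner are clipped to `[1e-6, 1 - 1e-6]` to avoid
#' degenerate correlations downstream.
#'
#' @param algorithm one of `"glm"`, `"gam"`, `"gbm"`, `"rf"`.
#' @param x data.frame of predictor values (>= 2 variables).
#' @param y 0/1 labels (both classes present).
#' @param seed integer seed (stochastic learners).
#' @return an `hsm_model` with a `predict()` method returning suitabilities
#'   in `[0, 1]`.
#' @export
fit_hsm <- function(algorithm = c("glm", "gam", "gbm", "rf"), x, y, seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as.data.frame(x)
  if (length(unique(y)) < 2) stop("single-class training data")
  vars <- names(x)
  fit <- switch(algorithm,
    glm = {
      sds <- vapply(x, stats::sd, numeric(1))
      if (any(sds == 0) || qr(scale(as.matrix(x)))$rank < ncol(x))
        stop("collinear-to-singular design; offending variable(s): ",
             paste(vars[duplicated(lapply(x, function(c) round(scale(c), 10))) |
                          sds == 0], collapse = ", "))
      form <- stats::as.formula(paste("y ~",
        paste(sprintf("%s + I(%s^2)", vars, vars), collapse = " + ")))
      stats::glm(form, data = cbind(x, y = y), family = stats::binomial())
    },
    gam = {
      k <- max(3, min(8, floor(nrow(x) / (2 * length(vars)))))
      form <- stats::as.formula(paste("y ~",
        paste(sprintf("s(%s, k = %d)", vars, k), collapse = " + ")))
      mgcv::gam(form, data = cbind(x, y = y), family = stats::binomial(),
                method = "GCV.Cp")
    },
    gbm = {
      dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      set.seed(seed)
      booster <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                                  max_depth = 3, eta = 0.1,
                                                  nthread = 1, seed = seed),
                                    data = dm, nrounds = 100, verbose = 0)
      # keep serialized bytes: booster handles are external pointers that can
      # be invalidated by gc; predict falls back to the raw copy
      list(booster = booster, raw = xgboost::xgb.save.raw(booster))
    },
    rf = {
      set.seed(seed)
      randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                 ntree = 500)
    })
  structure(list(algorithm = algorithm, fit = fit, variables = vars, seed = seed),
            class = "hsm_model")
}

#' Predict suitability from a fitted learner
#'
#' @param object an `hsm_model`.
#' @param newdata data.frame containing the model's variables.
#' @param ... unused.
#' @return suitabilities clipped to `[1e-6, 1 - 1e-6]`.
#' @export
predict.hsm_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$variables, drop = FALSE]
  p <- switch(object$algorithm,
    glm = stats::predict(object$fit, newdata = newdata, type = "response"),
    gam = as.numeric(stats::predict(object$fit, newdata = newdata, type = "response")),
    gbm = {
      dm <- xgboost::xgb.DMatrix(as.matrix(newdata))
      tryCatch(stats::predict(object$fit$booster, dm),
               error = function(e)
                 stats::predict(xgboost::xgb.load.raw(object$fit$raw), dm))
    },
    rf = stats::predict(object$fit, newdata = newdata, type = "prob")[, "1"])
  pmin(pmax(as.numeric(p), 1e-6), 1 - 1e-6)
}

#' Evaluate a fitted model on held-out points
#'
#' @param model an `hsm_model` or `hsm_ensemble`.
#' @param x test predictor values.
#' @param y test 0/1 labels (both classes present).
#' @return one-row data.frame: `rmse`, `auc`, `tss`, `tss_threshold`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_hsm <- function(model, x, y) {
  p <- predict(model, x)
  ts <- tss_best(p, y)
  data.frame(rmse = rmse(p, y), auc = auc(p, y), tss = ts$tss,
             tss_threshold = ts$threshold, sensitivity = ts$sensitivity,
             specificity = ts$specificity)
}

#' AUC-weighted ensemble of retained models
#'
#' Member weights are proportional to the attained AUC
#' (`w_i = auc_i / sum(auc)`); the ensemble prediction is the weighted mean
#' of member predictions (hence always inside the members' range). A single
#' member gives a passthrough tagged `HSM_unique`.
#'
#' @param models list of `hsm_model`s (>= 1).
#' @param aucs numeric AUCs, one per model.
#' @return an `hsm_ensemble` with fields `members`, `weights`, `tag`.
#' @export
ensemble_wmean <- function(models, aucs) {
  if (length(models) == 0) stop("empty model list")
  stopifnot(length(models) == length(aucs))
  w <- aucs / sum(aucs)
  structure(list(members = models, weights = w,
                 tag = if (length(models) == 1L) "HSM_unique" else "EM_wmean"),
            class = "hsm_ensemble")
}

#' @rdname ensemble_wmean
#' @param object an `hsm_ensemble`.
#' @param newdata data.frame of predictor values.
#' @param ... unused.
#' @export
predict.hsm_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members, predict, numeric(nrow(as.data.frame(newdata))),
                  newdata = newdata)
  as.numeric(preds %*% object$weights)
}

#' Standardized permutation variable importance
#'
#' Algorithm-independent: for each variable, its column is permuted and the
#' raw importance is the mean over `n_perm` permutations of
#' `1 - cor(pred_original, pred_permuted)` (negatives clipped to 0).
#' Standardized importances rescale the raw values to percentages summing to
#' 100 (all-zero raw importances stay all zero). If a prediction vector is
#' constant (correlation undefined) the mean absolute prediction difference
#' is used for that permutation instead, with a message.
#'
#' @param model an `hsm_model` or `hsm_ensemble`.
#' @param data data.frame of predictor values (>= 10 rows).
#' @param n_perm permutations per variable (default 5).
#' @param seed integer seed.
#' @return data.frame `variable`, `raw_importance`, `std_imp` (percent).
#' @export
permutation_importance <- function(model, data, n_perm = 5, seed = 1L) {
  data <- as.data.frame(data)
  if (nrow(data) < 10) stop("need >= 10 rows")
  vars <- if (inherits(model, "hsm_ensemble")) model$members[[1]]$variables
          else model$variables
  p0 <- predict(model, data)
  raw <- vapply(vars, function(v) {
    imps <- vapply(seq_len(n_perm), function(k) {
      set.seed(derive_seed(seed, "perm_imp", v, k))
      d <- data
      d[[v]] <- d[[v]][sample.int(nrow(d))]
      p1 <- predict(model, d)
      if (stats::sd(p0) == 0 || stats::sd(p1) == 0) {
        message("constant prediction vector; falling back to mean |difference|")
        mean(abs(p1 - p0))
      } else 1 - stats::cor(p0, p1)
    }, numeric(1))
    max(mean(imps), 0)
  }, numeric(1))
  std <- if (sum(raw) > 0) 100 * raw / sum(raw) else raw * 0
  data.frame(variable = vars, raw_importance = unname(raw), std_imp = unname(std))
}
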