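#' Out-of-fold prediction of CAFPAs from a measurement battery
#'
#' Predicts each of the ten CAFPAs from audiological measurements with a
#' separate regression model per CAFPA, using k-fold cross-validated
#' prediction: models are fitted on the training folds and every patient's
#' CAFPAs are predicted by the model that did *not* see them, so the
#' predictions behave like those for new patients.  Predictions are clipped
#' to \[0, 1\].
#'
#' Supported model families: `"lasso"` (L1-penalized linear regression),
#' `"elastic-net"` (mixed L1/L2 penalty, mixing parameter tuned over a small
#' grid) and `"random-forest"`.  Penalty strength is tuned by nested
#' cross-validation inside each training fold; the random forest's `mtry` is
#' tuned on out-of-bag error over a small grid.
#'
#' @param measurements Data frame (or matrix) of numeric features; a
#'   `patient_id` column, if present, is carried through but not used as a
#'   feature.
#' @param expert_cafpas The target CAFPAs: a cohort data frame or an
#'   n x 10 matrix aligned with `measurements`.
#' @param family Model family (see Details).
#' @param nfolds Number of outer folds (default 5); every fold must contain
#'   at least 10 patients.
#' @param seed Integer master seed (folds and model fitting).
#' @param num_trees Trees per random forest (default 500).
#' @return An object of class `cafpa_cv_prediction`: list with
#'   `predictions` (n x 10 matrix, clipped to \[0, 1\]), `folds` (outer fold
#'   index per patient), `diagnostics` (per-CAFPA out-of-fold RMSE, MAE and
#'   squared correlation), `models` (per CAFPA, per fold), `family`,
#'   `feature_names`, `patient_id`.
#' @examples
#' \donttest{
#' spec <- default_cohort_spec(seed = 5, n_per_category = 20)
#' cohort <- generate_measurements(simulate_cohort(spec),
#'                                 default_forward_spec(), seed = 5)
#' feats <- cohort[, setdiff(names(cohort),
#'                           c("patient_id", CAFPA_NAMES, "labels"))]
#' fit <- predict_cafpas_cv(feats, cohort, family = "lasso", seed = 5)
#' fit$diagnostics
#' }
#' @export
predict_cafpas_cv <- function(measurements, expert_cafpas,
                              family = c("lasso", "elastic-net",
                                         "random-forest"),
                              nfolds = 5L, seed = 1L, num_trees = 500L) {
  family <- match.arg(family)
  nfolds <- as.integer(nfolds)
  if (is.na(nfolds) || nfolds < 2L)
    stop("nfolds must be >= 2", call. = FALSE)
  pid <- NULL
  if (is.data.frame(measurements) && "patient_id" %in% names(measurements)) {
    pid <- measurements$patient_id
    measurements <- measurements[, setdiff(names(measurements), "patient_id"),
                                 drop = FALSE]
  }
  X <- as.matrix(measurements)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) {
    bad <- which(!complete.cases(X))
    stop("non-finite features for patient(s) ",
         paste(if (is.null(pid)) bad else pid[bad], collapse = ", "),
         call. = FALSE)
  }
  Y <- as_cafpa_matrix(if (is.data.frame(expert_cafpas))
    expert_cafpas[, intersect(names(expert_cafpas), CAFPA_NAMES),
                  drop = FALSE] else expert_cafpas)
  if (nrow(Y) != nrow(X))
    stop("measurements and expert CAFPAs must be aligned", call. = FALSE)
  if (!all(is.finite(Y)))
    stop("expert CAFPAs must be complete for cross-validated prediction",
         call. = FALSE)
  n <- nrow(X)
  if (floor(n / nfolds) < 10L)
    stop("fold too small: ", nfolds, " folds over ", n,
         " patients leaves fewer than 10 patients per fold", call. = FALSE)

  set.seed(stage_seed(seed, "cv_folds"))
  folds <- sample(rep_len(seq_len(nfolds), n))
  preds <- matrix(NA_real_, n, length(CAFPA_NAMES),
                  dimnames = list(NULL, CAFPA_NAMES))
  models <- setNames(vector("list", length(CAFPA_NAMES)), CAFPA_NAMES)

  for (j in seq_along(CAFPA_NAMES)) {
    y <- Y[, j]
    models[[j]] <- vector("list", nfolds)
    for (f in seq_len(nfolds)) {
      tr <- folds != f
      set.seed(stage_seed(seed, paste0("fit_", CAFPA_NAMES[j], "_", f)))
      fit <- fit_cafpa_regressor(X[tr, , drop = FALSE], y[tr], family,
                                 num_trees = num_trees)
      preds[!tr, j] <- predict_cafpa_regressor(fit, X[!tr, , drop = FALSE])
      models[[j]][[f]] <- fit
    }
  }
  preds <- pmin(pmax(preds, 0), 1)
  resid <- Y - preds
  diagnostics <- data.frame(
    cafpa = CAFPA_NAMES,
    rmse = sqrt(colMeans(resid^2)),
    mae = colMeans(abs(resid)),
    r2 = vapply(seq_len(ncol(Y)),
                function(j) suppressWarnings(stats::cor(Y[, j],
                                                        preds[, j]))^2,
                numeric(1)),
    row.names = NULL)
  structure(list(predictions = preds, folds = folds,
                 diagnostics = diagnostics, models = models,
                 family = family, feature_names = colnames(X),
                 patient_id = pid, nfolds = nfolds, seed = seed),
            class = "cafpa_cv_prediction")
}

# Fit one regressor on a training fold.
fit_cafpa_regressor <- function(X, y, family, num_trees = 500L) {
  if (family %in% c("lasso", "elastic-net")) {
    alphas <- if (family == "lasso") 1 else c(0.25, 0.5, 0.75)
    best <- NULL
    for (al in alphas) {
      cv <- glmnet::cv.glmnet(X, y, alpha = al, nfolds = 5L)
      if (is.null(best) || min(cv$cvm) < best$cvm) {
        best <- list(cv = cv, alpha = al, cvm = min(cv$cvm))
      }
    }
    list(family = family, fit = best$cv, alpha = best$alpha)
  } else {
    p <- ncol(X)
    grid <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), floor(p / 2))))
    best <- NULL
    df <- data.frame(y = y, X, check.names = FALSE)
    for (m in grid) {
      rf <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                           mtry = m, importance = "impurity",
                           seed = sample.int(2^31 - 1, 1))
      if (is.null(best) || rf$prediction.error < best$fit$prediction.error)
        best <- list(fit = rf, mtry = m)
    }
    list(family = family, fit = best$fit, mtry = best$mtry)
  }
}

predict_cafpa_regressor <- function(model, X) {
  if (model$family %in% c("lasso", "elastic-net")) {
    as.vector(predict(model$fit, newx = X, s = "lambda.min"))
  } else {
    predict(model$fit, data = data.frame(X, check.names = FALSE))$predictions
  }
}

#' @export
print.cafpa_cv_prediction <- function(x, ...) {
  cat("Cross-validated CAFPA prediction (", x$family, ", ", x$nfolds,
      " folds, n = ", nrow(x$predictions), ")\n", sep = "")
  d <- x$diagnostics
  cat(sprintf("out-of-fold RMSE: %.3f (median over CAFPAs), range %.3f-%.3f\n",
              median(d$rmse), min(d$rmse), max(d$rmse)))
  invisible(x)
}

#' Feature importance of the CAFPA prediction models
#'
#' For penalized linear models, the mean absolute (non-zero) coefficient of
#' each feature across the outer folds; for random forests, the mean
#' impurity importance.  One ranked table per CAFPA.
#'
#' @param fit A [predict_cafpas_cv()] result.
#' @return Data frame with columns `cafpa`, `feature`, `importance`, `rank`
#'   (rank 1 = most important); features with zero importance everywhere are
#'   omitted, so the table may be empty.
#' @export
feature_importance <- function(fit) {
  stopifnot(inherits(fit, "cafpa_cv_prediction"))
  rows <- list()
  for (cafpa in CAFPA_NAMES) {
    if (length(fit$models[[cafpa]]) == 0L) next
    imp <- numeric(length(fit$feature_names))
    names(imp) <- fit$feature_names
    for (m in fit$models[[cafpa]]) {
      if (m$family %in% c("lasso", "elastic-net")) {
        cf <- as.matrix(coef(m$fit, s = "lambda.min"))[-1, 1]
        imp[names(cf)] <- imp[names(cf)] + abs(cf)
      } else {
        iv <- m$fit$variable.importance
        imp[names(iv)] <- imp[names(iv)] + pmax(iv, 0)
      }
    }
    imp <- imp / length(fit$models[[cafpa]])
    imp <- imp[imp > 0]
    if (length(imp) == 0L) next
    imp <- sort(imp, decreasing = TRUE)
    rows[[cafpa]] <- data.frame(cafpa = cafpa, feature = names(imp),
                                importance = unname(imp),
                                rank = seq_along(imp), row.names = NULL)
  }
  if (length(rows) == 0L)
    return(data.frame(cafpa = character(), feature = character(),
                      importance = numeric(), rank = integer()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
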