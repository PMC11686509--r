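#' Deterministic shuffled train/test split
#'
#' @param dataset data.frame (>= 8 rows).
#' @param fraction training fraction in (0, 1); default the instrument's
#'   75/25 protocol.
#' @param seed integer seed; the same seed always yields the same split.
#' @return list with `train` and `test` data.frames (disjoint, exhaustive).
#' @export
split_train_test <- function(dataset, fraction = 0.75, seed = 42) {
  if (nrow(dataset) < 8)
    stop("split_train_test: need >= 8 samples", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("split_train_test: fraction must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(nrow(dataset))
  n_train <- round(fraction * nrow(dataset))
  att <- attributes(dataset)["corrected"]
  train <- dataset[sort(idx[seq_len(n_train)]), , drop = FALSE]
  test <- dataset[sort(idx[-seq_len(n_train)]), , drop = FALSE]
  attr(train, "corrected") <- att$corrected
  attr(test, "corrected") <- att$corrected
  list(train = train, test = test)
}

#' Default hyperparameter grids per regression family
#'
#' Ridge and lasso use seven log-spaced penalties from 1e-4 to 1e2; the
#' linear and Bayesian families have no tuned hyperparameter (the Bayesian
#' precision hyperparameters are maximized analytically from the
#' evidence).
#'
#' @param family one of `"linear"`, `"ridge"`, `"lasso"`, `"bayesian"`.
#' @return list of candidate hyperparameter values.
#' @export
default_hyper_grid <- function(family) {
  switch(family,
    ridge = , lasso = as.list(10^seq(-4, 2, length.out = 7)),
    linear = , bayesian = list(NA_real_),
    stop("unknown family: ", family, call. = FALSE))
}

# Evidence-maximized Gaussian linear regression (Bayesian ridge):
# iteratively re-estimates the weight precision alpha and noise precision
# beta from the marginal likelihood, then returns the posterior mean.
bayes_ridge_fit <- function(X, y, maxit = 200, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  e <- eigen(crossprod(X), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  b <- crossprod(e$vectors, crossprod(X, y))  # V' X' y
  alpha <- 1; beta <- 1 / max(var(y), 1e-12)
  for (i in seq_len(maxit)) {
    d <- alpha + beta * lam
    m_rot <- beta * b / d
    m <- e$vectors %*% m_rot
    gam <- sum(beta * lam / d)
    res2 <- sum((y - X %*% m)^2)
    alpha_new <- gam / max(sum(m^2), 1e-300)
    beta_new <- max(n - gam, 1e-12) / max(res2, 1e-300)
    if (abs(alpha_new - alpha) < tol * alpha && abs(beta_new - beta) < tol * beta) {
      alpha <- alpha_new; beta <- beta_new; break
    }
    alpha <- alpha_new; beta <- beta_new
  }
  d <- alpha + beta * lam
  list(coef = as.numeric(e$vectors %*% (beta * b / d)),
       alpha = alpha, beta = beta)
}

# fit one family on standardized X, centered y; returns original-scale
# intercept + coefficients
fit_family <- function(family, X, y, hyper) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ybar <- mean(y)
  cf_std <- switch(family,
    linear = {
      f <- lm.fit(cbind(1, Xs), y)
      cf <- f$coefficients[-1L]; cf[is.na(cf)] <- 0
      cf
    },
    ridge = , lasso = {
      f <- glmnet::glmnet(Xs, y, alpha = if (family == "lasso") 1 else 0,
                          lambda = hyper, standardize = FALSE)
      as.numeric(coef(f, s = hyper))[-1L]
    },
    bayesian = bayes_ridge_fit(Xs, y - ybar)$coef,
    stop("unknown family: ", family, call. = FALSE))
  cf <- cf_std / scl
  intercept <- if (family %in% c("ridge", "lasso")) {
    as.numeric(coef(glmnet::glmnet(Xs, y,
      alpha = if (family == "lasso") 1 else 0,
      lambda = hyper, standardize = FALSE), s = hyper))[1L] - sum(cf * ctr)
  } else ybar - sum(cf * ctr)
  c(`(Intercept)` = intercept, setNames(cf, colnames(X)))
}

predict_coefs <- function(coefs, mat) {
  as.numeric(coefs[1L] + mat %*% coefs[-1L])
}

#' Cross-validated training of the multitask regression layer
#'
#' Implements the instrument's training protocol: for each of the six
#' biomarkers, hyperparameters are chosen by k-fold cross-validation on
#' the training set (minimum mean CV MSE), then the model is refit on the
#' full training set. The six per-biomarker regressors share the same
#' selected-feature inputs (multitask by shared features).
#'
#' @param train training feature table (from [build_feature_table()] /
#'   [split_train_test()]); must be photobleach-corrected.
#' @param family `"linear"`, `"ridge"`, `"lasso"` or `"bayesian"`.
#' @param grid list of candidate hyperparameters
#'   ([default_hyper_grid()] by default; must be nonempty).
#' @param folds number of CV folds (>= 2; default the 10-fold protocol).
#' @param seed fold-assignment seed, recorded in the bundle.
#' @param selection a `feature_selection` from [pearson_select()], a
#'   character vector of feature columns, or NULL for all feature columns.
#' @return object of class `regression_bundle`.
#' @export
tune_and_train <- function(train, family = "bayesian",
                           grid = default_hyper_grid(family), folds = 10,
                           seed = 42, selection = NULL) {
  family <- match.arg(family, c("linear", "ridge", "lasso", "bayesian"))
  if (!length(grid)) stop("tune_and_train: empty hyperparameter grid", call. = FALSE)
  if (folds < 2) stop("tune_and_train: folds must be >= 2", call. = FALSE)
  if (folds > nrow(train))
    stop("tune_and_train: more folds than samples", call. = FALSE)
  if (!isTRUE(attr(train, "corrected")))
    stop("tune_and_train: features must be photobleach-corrected", call. = FALSE)
  feats <- if (is.null(selection)) feature_cols(train)
           else if (inherits(selection, "feature_selection"))
             names(selection$mask)[selection$mask]
           else selection
  lbls <- label_cols(train)
  if (!length(lbls)) stop("tune_and_train: no label columns", call. = FALSE)
  X <- as.matrix(train[, feats, drop = FALSE])
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = nrow(X)))
  models <- list(); chosen <- list(); cv_rows <- list()
  for (lb in lbls) {
    y <- train[[lb]]
    cv_mse <- matrix(NA_real_, length(grid), folds)
    cv_mae <- cv_mse; cv_r2 <- cv_mse
    for (gi in seq_along(grid)) {
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        cf <- fit_family(family, X[tr, , drop = FALSE], y[tr], grid[[gi]])
        pr <- predict_coefs(cf, mat = X[!tr, , drop = FALSE])
        yt <- y[!tr]
        cv_mse[gi, k] <- mean((yt - pr)^2)
        cv_mae[gi, k] <- mean(abs(yt - pr))
        sst <- sum((yt - mean(yt))^2)
        cv_r2[gi, k] <- if (sst > 0) 1 - sum((yt - pr)^2) / sst else NA_real_
      }
    }
    best <- which.min(rowMeans(cv_mse))
    models[[lb]] <- fit_family(family, X, y, grid[[best]])
    chosen[[lb]] <- grid[[best]]
    cv_rows[[lb]] <- data.frame(biomarker = sub("^label_", "", lb),
                                fold = seq_len(folds),
                                mse = cv_mse[best, ], mae = cv_mae[best, ],
                                r2 = cv_r2[best, ])
  }
  structure(list(family = family, models = models, feature_names = feats,
                 selection = selection, grid = grid, chosen = chosen,
                 folds = folds, split_seed = seed,
                 cv_scores = do.call(rbind, c(cv_rows, list(make.row.names = FALSE))),
                 test_scores = NULL),
            class = "regression_bundle")
}

#' @export
print.regression_bundle <- function(x, ...) {
  cat(sprintf("<regression_bundle> family %s, %d features, %d-fold CV (seed %d)\n",
              x$family, length(x$feature_names), x$folds, x$split_seed))
  agg <- aggregate(cbind(mse, mae, r2) ~ biomarker, x$cv_scores, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
coef.regression_bundle <- function(object, ...) {
  do.call(cbind, object$models)
}

flatten_feature_vector <- function(fv) {
  feat_names <- c("height", "width", "area", "position", "prominence")
  vals <- unlist(lapply(seq_len(nrow(fv)), function(i)
    setNames(as.numeric(fv[i, feat_names, drop = FALSE][1, ]),
             paste0(fv$channel[i], "_", feat_names))))
  out <- as.data.frame(as.list(vals))
  attr(out, "corrected") <- attr(fv, "corrected")
  out
}

#' Predict the six biomarker concentrations
#'
#' @param object a `regression_bundle`.
#' @param newdata a photobleach-corrected feature table or
#'   `feature_vector`. Predicting from uncorrected features is an error:
#'   the model was trained on fresh-film-equivalent features.
#' @param ... unused.
#' @return data.frame with one column per biomarker; the attribute
#'   `out_of_range` flags predictions outside the admissible ranges
#'   (values are returned unclamped).
#' @export
predict.regression_bundle <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_vector"))
    newdata <- flatten_feature_vector(newdata)
  if (!isTRUE(attr(newdata, "corrected")))
    stop("predict: features must be photobleach-corrected before prediction",
         call. = FALSE)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss))
    stop("predict: missing feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  out <- as.data.frame(lapply(object$models, predict_coefs, mat = X))
  names(out) <- sub("^label_", "", names(object$models))
  rng <- biomarker_ranges()
  oor <- vapply(names(out), function(nm)
    out[[nm]] < rng[[nm]][1] | out[[nm]] > rng[[nm]][2],
    logical(nrow(out)))
  attr(out, "out_of_range") <- matrix(oor, nrow = nrow(out),
                                      dimnames = list(NULL, names(out)))
  out
}

#' Per-biomarker prediction error metrics
#'
#' Mean squared error, mean absolute error and the coefficient of
#' determination R-squared = 1 - SSres / SStot, per biomarker.
#'
#' @param predictions data.frame/matrix of predictions (or a numeric
#'   vector for a single biomarker).
#' @param truths matching true values.
#' @return data.frame with columns `biomarker`, `mse`, `mae`, `r2`. R2 is
#'   NA (with a warning) when the truths are constant.
#' @export
score_predictions <- function(predictions, truths) {
  if (is.null(dim(predictions))) {
    predictions <- data.frame(value = predictions)
    truths <- data.frame(value = truths)
  }
  predictions <- as.data.frame(predictions)
  truths <- as.data.frame(truths)
  names(truths) <- sub("^label_", "", names(truths))
  if (nrow(predictions) != nrow(truths) || nrow(predictions) < 1)
    stop("score_predictions: predictions and truths must have equal length >= 1",
         call. = FALSE)
  rows <- lapply(names(predictions), function(nm) {
    p <- predictions[[nm]]; t <- truths[[nm]]
    res <- t - p
    sst <- sum((t - mean(t))^2)
    r2 <- if (length(t) >= 2 && sst > 0) 1 - sum(res^2) / sst else {
      warning("score_predictions: constant truths for ", nm,
              "; R2 undefined", call. = FALSE)
      NA_real_
    }
    data.frame(biomarker = nm, mse = mean(res^2), mae = mean(abs(res)), r2 = r2)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Score a trained bundle on a held-out test table
#'
#' @param bundle a `regression_bundle`.
#' @param test photobleach-corrected feature table with labels.
#' @return the bundle with `test_scores` filled in.
#' @export
evaluate_bundle <- function(bundle, test) {
  pred <- predict(bundle, test)
  truth <- test[, label_cols(test), drop = FALSE]
  bundle$test_scores <- score_predictions(pred, truth)
  bundle
}
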