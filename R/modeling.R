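#' Greedy correlation pruning of a feature matrix
#'
#' Removes features until no retained pair has |r| above the cutoff. At each
#' step the currently worst pair (largest |r|) is found and the member with
#' the larger mean absolute correlation to all remaining features is dropped
#' (ties: the later column is dropped). Constant columns have undefined
#' correlation; they are treated as r = 0 against all others and flagged.
#'
#' @param x Numeric matrix or data.frame of feature columns (no missing
#'   values, >= 2 columns).
#' @param cutoff Absolute-correlation cutoff, default 0.95.
#' @return List with `retained` (feature names), `removed` (data.frame of
#'   `feature` and the pairwise `r_trigger` that caused removal), `cutoff`,
#'   and `constant` (names of flagged constant columns).
#' @export
correlation_prune <- function(x, cutoff = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 feature columns")
  if (any(!is.finite(x))) stop("feature matrix contains missing values")
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  constant <- nm[sds < 1e-15]
  C <- suppressWarnings(abs(stats::cor(x)))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  dimnames(C) <- list(nm, nm)
  alive <- seq_len(ncol(x))
  removed <- list()
  repeat {
    Ca <- C[alive, alive, drop = FALSE]
    worst <- max(Ca)
    if (worst <= cutoff) break
    w <- which(Ca == worst, arr.ind = TRUE)[1, ]
    i <- alive[w[1]]; j <- alive[w[2]]
    mean_i <- mean(Ca[w[1], -w[1]])
    mean_j <- mean(Ca[w[2], -w[2]])
    drop <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else max(i, j)
    removed[[length(removed) + 1L]] <- data.frame(
      feature = nm[drop], r_trigger = worst, stringsAsFactors = FALSE)
    alive <- setdiff(alive, drop)
    if (length(alive) == 1L) break
  }
  list(
    retained = nm[alive],
    removed = if (length(removed)) do.call(rbind, removed) else
      data.frame(feature = character(0), r_trigger = numeric(0)),
    cutoff = cutoff,
    constant = constant
  )
}

#' Fit standardization parameters (train set only)
#'
#' @param x Numeric matrix or data.frame of training features.
#' @return List with `center` (column means), `scale` (column sds; columns
#'   with sd 0 get scale 1 and are listed in `zero_var`).
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  zero_var <- colnames(x)[scale < 1e-15]
  scale[scale < 1e-15] <- 1
  list(center = center, scale = scale, zero_var = zero_var)
}

#' Apply standardization parameters to data
#'
#' @param params Output of [standardize_fit()].
#' @param x Matrix or data.frame with exactly the columns the parameters were
#'   fit on.
#' @return Standardized numeric matrix.
#' @export
standardize_apply <- function(params, x) {
  x <- as.matrix(x)
  if (!identical(colnames(x), names(params$center))) {
    stop("contract error: columns do not match standardization parameters")
  }
  scale(x, center = params$center, scale = params$scale)[, , drop = FALSE]
}

#' Default hyperparameter grid for a model family
#'
#' Small, standard grids: RF with 500 trees and mtry in {sqrt(p), p/3};
#' linear SVM cost in {0.1, 1, 10}; polynomial SVM cost x degree {2, 3};
#' GBM trees {100, 300} x depth {2, 3} x learning rate {0.05, 0.1}.
#'
#' @param family One of "RF", "SVM_L", "SVM_P", "GBM".
#' @return data.frame grid, one row per candidate.
#' @export
default_grid <- function(family) {
  switch(family,
    RF = expand.grid(ntree = 500, mtry_kind = c("sqrt", "third"),
                     stringsAsFactors = FALSE),
    SVM_L = expand.grid(cost = c(0.1, 1, 10)),
    SVM_P = expand.grid(cost = c(0.1, 1, 10), degree = c(2, 3)),
    GBM = expand.grid(nrounds = c(100, 300), max_depth = c(2, 3),
                      eta = c(0.05, 0.1)),
    stop("unknown model family: ", family)
  )
}

#' Specify a model family, task, and tuning setup
#'
#' @param family One of "RF" (random forest), "SVM_L" (linear support vector
#'   machine), "SVM_P" (polynomial-kernel SVM), "GBM" (gradient boosting
#'   machine).
#' @param task One of "classify_approach", "classify_windup",
#'   "regress_velocity" (any task starting with "classify" is treated as
#'   classification).
#' @param grid Hyperparameter grid (data.frame); defaults per family.
#' @param tune_k Folds for hyperparameter cross-validation, default 10.
#' @param seed Seed controlling fold assignment and stochastic fits.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("RF", "SVM_L", "SVM_P", "GBM"),
                       task = c("classify_approach", "classify_windup",
                                "regress_velocity"),
                       grid = NULL, tune_k = 10, seed = 1) {
  family <- match.arg(family)
  task <- match.arg(task)
  if (is.null(grid)) grid <- default_grid(family)
  stopifnot(nrow(grid) >= 1, tune_k >= 2)
  structure(list(family = family, task = task, grid = grid,
                 tune_k = tune_k, seed = as.integer(seed)),
            class = "model_spec")
}

is_classification <- function(task) startsWith(task, "classify")

#' Fit one model of a given family
#'
#' @param family Model family, see [model_spec()].
#' @param x Numeric feature matrix (already standardized).
#' @param y Factor (classification) or numeric (regression) response.
#' @param params Named list: one row of the family's grid.
#' @param seed Seed for stochastic learners.
#' @return A `throw_model` with a [predict][predict.throw_model] method.
#' @export
fit_model <- function(family, x, y, params, seed = 1) {
  x <- as.matrix(x)
  classify <- is.factor(y)
  fit <- switch(family,
    RF = {
      p <- ncol(x)
      mtry <- if (identical(params$mtry_kind, "third")) {
        max(1L, floor(p / 3))
      } else max(1L, floor(sqrt(p)))
      set.seed(seed)
      randomForest::randomForest(x = x, y = y,
                                 ntree = params$ntree %||% 500, mtry = mtry)
    },
    SVM_L = e1071::svm(x = x, y = y, kernel = "linear",
                       cost = params$cost %||% 1, scale = FALSE),
    SVM_P = e1071::svm(x = x, y = y, kernel = "polynomial",
                       cost = params$cost %||% 1,
                       degree = params$degree %||% 3,
                       coef0 = 1, scale = FALSE),
    GBM = {
      if (classify) {
        k <- nlevels(y)
        lab <- as.integer(y) - 1L
        obj <- if (k == 2) list(objective = "binary:logistic") else
          list(objective = "multi:softmax", num_class = k)
      } else {
        lab <- y
        obj <- list(objective = "reg:squarederror")
      }
      xgboost::xgb.train(
        params = c(obj, list(max_depth = params$max_depth %||% 3,
                             eta = params$eta %||% 0.1,
                             nthread = 1, seed = seed)),
        data = xgboost::xgb.DMatrix(x, label = lab, nthread = 1),
        nrounds = params$nrounds %||% 100, verbose = 0
      )
    },
    stop("unknown model family: ", family)
  )
  structure(list(family = family, fit = fit, classify = classify,
                 classes = if (classify) levels(y) else NULL,
                 feature_names = colnames(x), params = params),
            class = "throw_model")
}

#' Predict from a fitted throw model
#'
#' @param object A `throw_model` from [fit_model()].
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return Factor (classification, training levels) or numeric vector.
#' @export
predict.throw_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  out <- switch(object$family,
    RF = stats::predict(object$fit, newdata),
    SVM_L = stats::predict(object$fit, newdata),
    SVM_P = stats::predict(object$fit, newdata),
    GBM = {
      raw <- stats::predict(object$fit, newdata)
      if (object$classify) {
        k <- length(object$classes)
        idx <- if (k == 2) as.integer(raw > 0.5) else as.integer(raw)
        factor(object$classes[idx + 1L], levels = object$classes)
      } else raw
    }
  )
  if (object$classify) factor(as.character(out), levels = object$classes)
  else as.numeric(out)
}

# Seeded k-fold assignment; stratified by class for factors.
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  if (is.factor(y)) {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    idx <- sample(seq_along(y))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select hyperparameters by k-fold cross-validation
#'
#' Scores every grid row by mean fold accuracy (classification) or mean fold
#' MAE (regression) under a seeded fold assignment (stratified by class for
#' classification) and returns the best row (first on ties). A single-row
#' grid is returned directly without cross-validation.
#'
#' @param spec A [model_spec()].
#' @param x Standardized feature matrix.
#' @param y Response.
#' @return List with `params` (best row as a list) and `scores` (grid with a
#'   `score` column; NULL for a single-row grid).
#' @export
tune <- function(spec, x, y) {
  grid <- spec$grid
  if (nrow(grid) == 1L) {
    return(list(params = as.list(grid[1, , drop = FALSE]), scores = NULL))
  }
  classify <- is_classification(spec$task)
  if (nrow(x) < spec$tune_k) stop("fewer rows than tuning folds")
  fold <- make_folds(y, spec$tune_k, spec$seed)
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    fs <- numeric(0)
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (classify && nlevels(droplevels(y[tr])) < nlevels(y)) {
        stop("tuning fold lost a class; too few rows per class")
      }
      m <- fit_model(spec$family, x[tr, , drop = FALSE], y[tr], params,
                     seed = spec$seed)
      pred <- predict(m, x[!tr, , drop = FALSE])
      fs <- c(fs, if (classify) mean(pred == y[!tr]) else
        mean(abs(pred - y[!tr])))
    }
    score[g] <- mean(fs)
  }
  best <- if (classify) which.max(score) else which.min(score)
  out <- grid
  out$score <- score
  list(params = as.list(grid[best, , drop = FALSE]), scores = out)
}

#' One-vs-rest classification metrics for a single class
#'
#' @param truth,pred Equal-length factors or character vectors.
#' @param positive_class The class treated as positive.
#' @return Named vector: `sensitivity` TP/(TP+FN), `specificity` TN/(TN+FP),
#'   `balanced_accuracy` (their mean), `f1` 2TP/(2TP+FP+FN). NaN when a
#'   denominator is empty (e.g., the class is absent from `truth`).
#' @export
class_metrics <- function(truth, pred, positive_class) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == positive_class & pred == positive_class)
  fn <- sum(truth == positive_class & pred != positive_class)
  tn <- sum(truth != positive_class & pred != positive_class)
  fp <- sum(truth != positive_class & pred == positive_class)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    f1 = 2 * tp / (2 * tp + fp + fn))
}

#' Per-class one-vs-rest metrics table
#'
#' @param truth,pred Equal-length factors or character vectors.
#' @return data.frame with one row per class in `truth`'s level set.
#' @export
classification_metrics <- function(truth, pred) {
  classes <- if (is.factor(truth)) levels(truth) else sort(unique(truth))
  rows <- lapply(classes, function(cl) {
    m <- class_metrics(truth, pred, cl)
    data.frame(class = cl, t(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regression error metrics
#'
#' @param truth,pred Equal-length numeric vectors (truth in m/s for velocity).
#' @return Named vector: `mae` mean |e|, `rmse` sqrt(mean e^2), `mape`
#'   100 * mean(|e|/truth) (NA with a warning when any truth <= 0).
#' @export
reg_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  e <- pred - truth
  mape <- if (any(truth <= 0)) {
    warning("MAPE undefined: non-positive truth values")
    NA_real_
  } else 100 * mean(abs(e) / truth)
  c(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), mape = mape)
}

# Macro-averaged F1 over the classes present in truth (per-subject response
# for the repeated-measures comparison).
macro_f1 <- function(truth, pred) {
  classes <- unique(as.character(truth))
  f1s <- vapply(classes, function(cl) class_metrics(truth, pred, cl)[["f1"]],
                numeric(1))
  mean(f1s[is.finite(f1s)])
}

#' Leave-one-subject-out evaluation of one model configuration
#'
#' One fold per subject: within each fold, correlation pruning and
#' standardization are fit on the training subjects only, hyperparameters are
#' tuned by k-fold CV on the training subjects, the model is fit and the
#' held-out subject predicted. Per-subject metrics (macro F1 for
#' classification, MAE for regression) feed the repeated-measures comparison.
#'
#' Set `global_preprocess = TRUE` to prune and standardize once on the full
#' data before splitting (the literal "prior to modelling" reading; leaks the
#' held-out subject into preprocessing).
#'
#' @param spec A [model_spec()].
#' @param data data.frame with feature columns, a label column and a subject
#'   column.
#' @param feature_cols Names of the feature columns.
#' @param label_col Name of the response column.
#' @param subject_col Name of the subject id column.
#' @param cutoff Correlation-pruning cutoff.
#' @param global_preprocess Preprocess once on all data (default FALSE).
#' @return An `evaluation_result`: list with `task`, `predictions`
#'   (subject_id, truth, prediction per row), `metrics` (per-class table or
#'   regression vector), `per_subject` (subject_id, value), and `folds`
#'   (per-fold retained-feature count and tuned parameters).
#' @export
loso_evaluate <- function(spec, data, feature_cols, label_col,
                          subject_col = "subject_id", cutoff = 0.95,
                          global_preprocess = FALSE) {
  subjects <- unique(data[[subject_col]])
  if (length(subjects) < 2) stop("need >= 2 distinct subjects for LOSO")
  classify <- is_classification(spec$task)
  y_all <- data[[label_col]]
  if (classify) y_all <- factor(y_all)
  x_all <- as.matrix(data[, feature_cols, drop = FALSE])

  if (global_preprocess) {
    pr <- correlation_prune(x_all, cutoff)
    sp <- standardize_fit(x_all[, pr$retained, drop = FALSE])
  }

  preds <- vector("list", length(subjects))
  folds <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    te <- data[[subject_col]] == s
    if (!any(te)) next
    if (global_preprocess) {
      retained <- pr$retained
      scaler <- sp
    } else {
      prf <- correlation_prune(x_all[!te, , drop = FALSE], cutoff)
      retained <- prf$retained
      scaler <- standardize_fit(x_all[!te, retained, drop = FALSE])
    }
    xtr <- standardize_apply(scaler, x_all[!te, retained, drop = FALSE])
    xte <- standardize_apply(scaler, x_all[te, retained, drop = FALSE])
    ytr <- if (classify) droplevels(y_all[!te]) else y_all[!te]
    if (classify) ytr <- factor(ytr, levels = levels(y_all))
    tuned <- tune(spec, xtr, ytr)
    m <- fit_model(spec$family, xtr, ytr, tuned$params, seed = spec$seed)
    p <- predict(m, xte)
    preds[[si]] <- data.frame(
      subject_id = data[[subject_col]][te],
      truth = if (classify) as.character(y_all[te]) else y_all[te],
      prediction = if (classify) as.character(p) else p,
      stringsAsFactors = FALSE
    )
    folds[[si]] <- data.frame(subject_id = s, n_retained = length(retained),
                              stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  if (classify) {
    lv <- levels(y_all)
    truth_f <- factor(predictions$truth, levels = lv)
    pred_f <- factor(predictions$prediction, levels = lv)
    metrics <- classification_metrics(truth_f, pred_f)
    per_subject <- do.call(rbind, lapply(split(
      predictions, predictions$subject_id), function(d) {
        data.frame(subject_id = d$subject_id[1],
                   value = macro_f1(d$truth, d$prediction),
                   stringsAsFactors = FALSE)
      }))
  } else {
    metrics <- reg_metrics(predictions$truth, predictions$prediction)
    per_subject <- do.call(rbind, lapply(split(
      predictions, predictions$subject_id), function(d) {
        data.frame(subject_id = d$subject_id[1],
                   value = mean(abs(d$prediction - d$truth)),
                   stringsAsFactors = FALSE)
      }))
  }
  rownames(per_subject) <- NULL
  structure(
    list(task = spec$task, family = spec$family, predictions = predictions,
         metrics = metrics, per_subject = per_subject,
         folds = do.call(rbind, folds)),
    class = "evaluation_result"
  )
}

#' Permutation feature importance, scaled to 0-100
#'
#' Importance of a feature is the mean drop in model score (classification
#' accuracy, or negative MAE for regression) over `reps` seeded permutations
#' of that feature's column. Negative drops are clipped to 0 and the result
#' is scaled so the most important feature scores 100.
#'
#' @param model A `throw_model`.
#' @param x Feature matrix the model was fit on (standardized).
#' @param y Response.
#' @param reps Permutation repetitions per feature, default 5.
#' @param seed Seed for the permutations.
#' @return data.frame with `feature`, `importance_raw` (score drop), and
#'   `importance` (scaled to [0, 100]).
#' @export
permutation_importance <- function(model, x, y, reps = 5, seed = 1) {
  stopifnot(reps >= 1)
  x <- as.matrix(x)
  score <- function(xx) {
    p <- predict(model, xx)
    if (model$classify) mean(p == y) else -mean(abs(p - y))
  }
  baseline <- score(x)
  set.seed(seed)
  raw <- vapply(seq_len(ncol(x)), function(j) {
    drops <- vapply(seq_len(reps), function(r) {
      xp <- x
      xp[, j] <- xp[sample(nrow(x)), j]
      baseline - score(xp)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  raw <- pmax(raw, 0)
  scaled <- if (max(raw) > 0) raw * 100 / max(raw) else raw
  data.frame(feature = colnames(x), importance_raw = raw,
             importance = scaled, stringsAsFactors = FALSE)
}
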