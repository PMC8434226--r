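#' Fit a classifier on shapelet distance features
#'
#' Trains either a multiclass logistic regression (via [nnet::multinom()])
#' or a gradient boosted trees classifier (via [xgboost::xgb.train()]) on a
#' minimum-distance feature matrix, selecting hyperparameters by k-fold
#' cross-validated accuracy over a supplied grid.
#'
#' Default grids are deliberately small: `decay` in `{0, 0.01, 0.1}` for the
#' logistic model; `max_depth` in `{2, 3}`, `eta` in `{0.1, 0.3}`,
#' `nrounds = 100` for the trees. Pass `hyperparams` as a named list of
#' vectors to override (the full Cartesian grid is searched).
#'
#' @param features A `wtss_features` or plain numeric matrix with colnames.
#' @param labels Class labels, one per row; `NULL` uses the `labels`
#'   attribute of `features`.
#' @param kind `"multiclass_logistic"` or `"gradient_boosted_trees"`.
#' @param hyperparams Named list of hyperparameter vectors, or `NULL`.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed (fold assignment and xgboost RNG).
#' @param class_weight `"none"` (default) or `"balanced"` (weights inversely
#'   proportional to class frequency), for imbalanced tasks.
#' @return A `wtss_model`: `kind`, `fit`, `classes`, `feature_names`,
#'   `best_params`, `cv_table`, `seed`.
#' @export
fit_classifier <- function(features, labels = NULL,
                           kind = c("multiclass_logistic",
                                    "gradient_boosted_trees"),
                           hyperparams = NULL, cv_folds = 5L, seed = 1L,
                           class_weight = c("none", "balanced")) {
  kind <- match.arg(kind)
  class_weight <- match.arg(class_weight)
  x <- as.matrix(features)
  labels <- labels %||% attr(features, "labels")
  if (is.null(labels) || length(labels) != nrow(x)) {
    stop("labels must align with the feature rows", call. = FALSE)
  }
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  w <- if (class_weight == "balanced") {
    tab <- table(y)
    as.numeric(length(y) / (nlevels(y) * tab[y]))
  } else {
    rep(1, length(y))
  }
  grid <- default_grid(kind, hyperparams)
  folds <- with_local_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(x))))
  cv_table <- grid
  cv_table$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      fit <- fit_one(kind, x[tr, , drop = FALSE], y[tr], w[tr],
                     grid[g, , drop = FALSE], seed)
      pred <- predict_one(kind, fit, x[!tr, , drop = FALSE],
                          levels(y), type = "class")
      correct <- correct + sum(pred == y[!tr])
    }
    cv_table$accuracy[g] <- correct / nrow(x)
  }
  best <- grid[which.max(cv_table$accuracy), , drop = FALSE]
  fit <- fit_one(kind, x, y, w, best, seed)
  structure(
    list(kind = kind, fit = fit, classes = levels(y),
         feature_names = colnames(x), best_params = best,
         cv_table = cv_table, cv_folds = cv_folds, seed = seed),
    class = "wtss_model"
  )
}

default_grid <- function(kind, hyperparams) {
  base <- if (kind == "multiclass_logistic") {
    list(decay = c(0, 0.01, 0.1))
  } else {
    list(max_depth = c(2L, 3L), eta = c(0.1, 0.3), nrounds = 100L)
  }
  if (!is.null(hyperparams)) base[names(hyperparams)] <- hyperparams
  expand.grid(base, stringsAsFactors = FALSE)
}

# shapelet names like "0", "1" are not syntactic R names; model internals
# use positional names X1..Xp and map back by position
internal_names <- function(p) paste0("X", seq_len(p))

fit_one <- function(kind, x, y, w, params, seed) {
  if (kind == "multiclass_logistic") {
    colnames(x) <- internal_names(ncol(x))
    df <- data.frame(.y = y, x)
    nnet::multinom(.y ~ ., data = df, weights = w, decay = params$decay,
                   maxit = 500L, trace = FALSE)
  } else {
    nclass <- nlevels(y)
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L, weight = w)
    obj <- if (nclass > 2L) "multi:softprob" else "binary:logistic"
    params_list <- list(max_depth = params$max_depth, eta = params$eta,
                        objective = obj, nthread = 1L, seed = seed)
    if (nclass > 2L) params_list$num_class <- nclass
    xgboost::xgb.train(params = params_list, data = dtrain,
                       nrounds = params$nrounds, verbose = 0L)
  }
}

predict_one <- function(kind, fit, x, classes, type) {
  if (kind == "multiclass_logistic") {
    colnames(x) <- internal_names(ncol(x))
    df <- as.data.frame(x)
    if (type == "class") {
      as.character(stats::predict(fit, newdata = df, type = "class"))
    } else {
      p <- stats::predict(fit, newdata = df, type = "probs")
      if (is.null(dim(p))) {
        # binary multinom returns P(second class)
        p <- cbind(1 - p, p)
      }
      if (nrow(x) == 1L && is.null(dim(p))) p <- matrix(p, nrow = 1L)
      colnames(p) <- classes
      p
    }
  } else {
    raw <- stats::predict(fit, xgboost::xgb.DMatrix(x))
    p <- if (length(classes) > 2L) {
      matrix(raw, ncol = length(classes), byrow = TRUE)
    } else {
      cbind(1 - raw, raw)
    }
    colnames(p) <- classes
    if (type == "class") classes[max.col(p, ties.method = "first")] else p
  }
}

#' Predict from a fitted shapelet-feature classifier
#'
#' @param object A `wtss_model`.
#' @param newdata Feature matrix with the training columns.
#' @param type `"class"` for labels, `"prob"` for a class-probability
#'   matrix.
#' @param ... Unused.
#' @return Character vector of labels or a numeric probability matrix.
#' @export
predict.wtss_model <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!identical(colnames(x), object$feature_names)) {
    if (is.null(colnames(x)) || !all(object$feature_names %in% colnames(x))) {
      stop("newdata must carry the training feature columns", call. = FALSE)
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  predict_one(object$kind, object$fit, x, object$classes, type)
}

#' @export
print.wtss_model <- function(x, ...) {
  cat(sprintf("<wtss_model> %s, %d features, classes={%s}\n",
              x$kind, length(x$feature_names),
              paste(x$classes, collapse = ",")))
  invisible(x)
}

#' Tabulate a confusion matrix
#'
#' Rows are predicted classes, columns are true classes (the orientation
#' used in all printed reports here).
#'
#' @param predicted,true Class label vectors of equal length.
#' @param classes Optional class ordering; default the sorted union.
#' @return A `wtss_confusion`: integer matrix `counts` plus `class_names`.
#' @export
confusion_matrix <- function(predicted, true, classes = NULL) {
  predicted <- as.character(predicted)
  true <- as.character(true)
  stopifnot(length(predicted) == length(true))
  classes <- classes %||% sort(unique(c(predicted, true)))
  counts <- table(factor(predicted, levels = classes),
                  factor(true, levels = classes))
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(predicted = classes, true = classes))
  structure(list(counts = m, class_names = classes),
            class = "wtss_confusion")
}

#' Build a confusion matrix from a table of counts
#'
#' For scoring an already-tabulated confusion matrix (e.g. one printed in a
#' report): rows are predicted classes, columns true classes.
#'
#' @param counts Square numeric matrix with matching dimnames, or unnamed
#'   (classes then default to `"1"`, `"2"`, ...).
#' @return A `wtss_confusion`.
#' @export
#' @examples
#' cm <- confusion_from_counts(matrix(c(4, 8, 15, 245), 2,
#'   dimnames = list(c("use", "no_use"), c("use", "no_use"))))
#' round(f1_score(cm, positive_class = "use"), 2)
confusion_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("counts must be square (predicted x true)", call. = FALSE)
  }
  classes <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  dimnames(counts) <- list(predicted = classes, true = classes)
  structure(list(counts = counts, class_names = classes),
            class = "wtss_confusion")
}

#' @export
print.wtss_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, cols = true):\n")
  print(x$counts)
  cat(sprintf("macro-F1 = %.4f\n", f1_score(x)))
  invisible(x)
}

#' Evaluate a model on held-out features
#'
#' @param model A `wtss_model`.
#' @param features Feature matrix for the evaluation series.
#' @param labels True labels; `NULL` uses the `labels` attribute.
#' @return A `wtss_confusion` (rows = predicted, cols = true).
#' @export
evaluate <- function(model, features, labels = NULL) {
  labels <- labels %||% attr(features, "labels")
  pred <- predict(model, features, type = "class")
  confusion_matrix(pred, labels,
                   classes = sort(unique(c(model$classes, labels))))
}

#' F1 score from a confusion matrix
#'
#' Binary F1 for a stated positive class (`F1 = 2PR/(P+R)` with precision
#' `TP/(TP+FP)` and recall `TP/(TP+FN)`), or the macro average (unweighted
#' mean of per-class F1) when `positive_class = NULL`. A class with
#' `P + R = 0` contributes an F1 of 0.
#'
#' @param cm A `wtss_confusion` (rows = predicted, cols = true).
#' @param positive_class Class label, or `NULL` for macro-F1.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' f1_score(cm, positive_class = "a")
f1_score <- function(cm, positive_class = NULL) {
  stopifnot(inherits(cm, "wtss_confusion"))
  counts <- cm$counts
  per_class <- function(cl) {
    i <- match(cl, cm$class_names)
    tp <- counts[i, i]
    fp <- sum(counts[i, ]) - tp
    fn <- sum(counts[, i]) - tp
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  if (!is.null(positive_class)) {
    if (!positive_class %in% cm$class_names) {
      stop("unknown positive class '", positive_class, "'", call. = FALSE)
    }
    per_class(positive_class)
  } else {
    mean(vapply(cm$class_names, per_class, numeric(1L)))
  }
}

#' Feature importance of a fitted model
#'
#' Gain-based importance for gradient boosted trees, mean absolute
#' coefficient across classes for the logistic model. Features absent from
#' every tree get importance 0. Sorted descending.
#'
#' @param model A `wtss_model`.
#' @return Data frame with columns `name` and `importance`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "wtss_model"))
  if (model$kind == "gradient_boosted_trees") {
    imp <- xgboost::xgb.importance(model = model$fit)
    out <- data.frame(name = model$feature_names, importance = 0)
    hit <- match(imp$Feature, out$name)
    out$importance[hit[!is.na(hit)]] <- imp$Gain[!is.na(hit)]
  } else {
    coefs <- summary(model$fit)$coefficients
    if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1L,
                                             dimnames = list(NULL,
                                                             names(coefs)))
    cols <- match(internal_names(length(model$feature_names)),
                  colnames(coefs))
    imp_vals <- colMeans(abs(coefs[, cols, drop = FALSE]))
    out <- data.frame(name = model$feature_names, importance = imp_vals)
  }
  out <- out[order(out$importance, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partial dependence of predicted probability on one feature
#'
#' For each grid value `v`, forces the named feature column to `v` for every
#' series and averages the predicted probability of `class`; all other
#' features keep their observed values.
#'
#' @param model A `wtss_model`.
#' @param features Feature matrix (the background dataset).
#' @param shapelet_name Column to sweep.
#' @param grid Numeric grid of distance values (non-empty).
#' @param class Class whose probability is averaged; default the first
#'   model class.
#' @return Data frame with columns `value` and `mean_prob`.
#' @export
partial_dependence <- function(model, features, shapelet_name, grid,
                               class = NULL) {
  x <- as.matrix(features)
  if (!shapelet_name %in% colnames(x)) {
    stop("feature '", shapelet_name, "' not present", call. = FALSE)
  }
  if (!length(grid)) stop("grid must be non-empty", call. = FALSE)
  class <- class %||% model$classes[1L]
  if (!class %in% model$classes) {
    stop("unknown class '", class, "'", call. = FALSE)
  }
  mean_prob <- vapply(grid, function(v) {
    xx <- x
    xx[, shapelet_name] <- v
    mean(predict(model, xx, type = "prob")[, class])
  }, numeric(1L))
  data.frame(value = grid, mean_prob = mean_prob)
}
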