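# separable toy features: class decided by which column is small
toy_features <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(
    cbind(stats::runif(n_per_class, 0, 0.2),
          stats::runif(n_per_class, 0.8, 1)),
    cbind(stats::runif(n_per_class, 0.8, 1),
          stats::runif(n_per_class, 0, 0.2))
  )
  colnames(x) <- c("0", "1")
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  list(x = x, y = rep(c("a", "b"), each = n_per_class))
}

test_that("both classifier kinds separate a linearly separable toy", {
  toy <- toy_features()
  for (kind in c("multiclass_logistic", "gradient_boosted_trees")) {
    m <- fit_classifier(toy$x, toy$y, kind = kind, cv_folds = 3, seed = 2)
    expect_equal(mean(predict(m, toy$x) == toy$y), 1)
    # determinism under identical seed/config
    m2 <- fit_classifier(toy$x, toy$y, kind = kind, cv_folds = 3, seed = 2)
    expect_identical(predict(m2, toy$x), predict(m, toy$x))
    pr <- predict(m, toy$x, type = "prob")
    expect_equal(dim(pr), c(40L, 2L))
    expect_equal(unname(rowSums(pr)), rep(1, 40), tolerance = 1e-6)
  }
  expect_error(fit_classifier(toy$x, rep("a", 40)), "two classes")
})

test_that("confusion matrices tally predictions against truth", {
  pred <- c("a", "a", "b", "c", "b", "a")
  true <- c("a", "b", "b", "c", "c", "a")
  cm <- confusion_matrix(pred, true)
  # hand tally: rows predicted, cols true
  expect_equal(cm$counts["a", "a"], 2L)
  expect_equal(cm$counts["a", "b"], 1L)
  expect_equal(cm$counts["b", "b"], 1L)
  expect_equal(cm$counts["b", "c"], 1L)
  expect_equal(cm$counts["c", "c"], 1L)
  expect_equal(sum(cm$counts), 6L)
  expect_equal(unname(colSums(cm$counts)), c(2L, 2L, 2L))
  # perfect and constant predictors
  cm_perf <- confusion_matrix(true, true)
  expect_true(all(cm_perf$counts[upper.tri(cm_perf$counts)] == 0))
  expect_true(all(cm_perf$counts[lower.tri(cm_perf$counts)] == 0))
  cm_const <- confusion_matrix(rep("a", 6), true)
  expect_equal(sum(cm_const$counts["a", ]), 6L)
  expect_true(all(cm_const$counts[c("b", "c"), ] == 0))
})

test_that("F1 handles binary, macro and degenerate conventions", {
  # imbalanced binary table: TP=4, FP=15, FN=8, TN=245
  cm <- confusion_from_counts(matrix(c(4, 8, 15, 245), 2,
    dimnames = list(c("use", "no_use"), c("use", "no_use"))))
  expect_equal(round(f1_score(cm, positive_class = "use"), 2), 0.26)
  expect_equal(f1_score(cm, positive_class = "use"), 8 / 31,
               tolerance = 1e-12)
  # perfect 4-class diagonal gives macro-F1 1
  diag4 <- confusion_from_counts(diag(c(24, 29, 28, 19)))
  expect_equal(f1_score(diag4), 1)
  # degenerate: no predictions or truths for the positive class
  cm0 <- confusion_from_counts(matrix(c(0, 5, 0, 10), 2,
    dimnames = list(c("p", "n"), c("p", "n"))))
  expect_equal(f1_score(cm0, positive_class = "p"), 0)
  expect_error(f1_score(cm, positive_class = "nope"), "unknown")
  # macro-F1 invariant to class relabeling
  set.seed(3)
  pred <- sample(letters[1:3], 60, replace = TRUE)
  true <- sample(letters[1:3], 60, replace = TRUE)
  f_orig <- f1_score(confusion_matrix(pred, true))
  relab <- c(a = "z", b = "x", c = "y")
  f_perm <- f1_score(confusion_matrix(relab[pred], relab[true]))
  expect_equal(f_perm, f_orig, tolerance = 1e-12)
})

test_that("feature importance ranks a planted informative feature first", {
  set.seed(7)
  n <- 80
  informative <- c(stats::runif(n / 2, 0, 0.3), stats::runif(n / 2, 0.7, 1))
  noise <- stats::runif(n)
  x <- cbind(informative, noise)
  colnames(x) <- c("signal", "noise")
  y <- rep(c("lo", "hi"), each = n / 2)
  m <- fit_classifier(x, y, kind = "gradient_boosted_trees", cv_folds = 3,
                      seed = 5)
  imp <- feature_importance(m)
  expect_equal(imp$name[1L], "signal")
  expect_true(all(imp$importance >= 0))
  expect_true(!is.unsorted(rev(imp$importance)))
  # linear model importances follow |coefficients|
  ml <- fit_classifier(x, y, kind = "multiclass_logistic", cv_folds = 3,
                       seed = 5)
  impl <- feature_importance(ml)
  expect_equal(impl$name[1L], "signal")
})

test_that("partial dependence is flat for an ignored feature and matches a
           direct average", {
  toy <- toy_features(seed = 9)
  # add a pure-noise column the model should ignore
  set.seed(10)
  x <- cbind(toy$x, noise = stats::runif(40))
  colnames(x) <- c("0", "1", "noise")
  m <- fit_classifier(x, toy$y, kind = "multiclass_logistic", cv_folds = 3,
                      seed = 3)
  pd_noise <- partial_dependence(m, x, "noise", grid = c(0, 0.5, 1),
                                 class = "a")
  expect_lt(max(pd_noise$mean_prob) - min(pd_noise$mean_prob), 0.05)
  # two-point grid equals the hand-computed average probability
  pd <- partial_dependence(m, x, "0", grid = c(0.1, 0.9), class = "a")
  for (i in 1:2) {
    xx <- x
    xx[, "0"] <- pd$value[i]
    expect_equal(pd$mean_prob[i],
                 mean(predict(m, xx, type = "prob")[, "a"]),
                 tolerance = 1e-12)
  }
  # monotone response for the real feature
  grid <- seq(0, 1, length.out = 5)
  pd0 <- partial_dependence(m, x, "0", grid = grid, class = "a")
  expect_true(all(diff(pd0$mean_prob) <= 1e-8) ||
                all(diff(pd0$mean_prob) >= -1e-8))
  expect_error(partial_dependence(m, x, "0", numeric(0)), "non-empty")
  expect_error(partial_dependence(m, x, "missing", 0.5), "not present")
})

test_that("class weighting is available for imbalanced labels", {
  set.seed(12)
  x <- cbind(stats::runif(60), stats::runif(60))
  colnames(x) <- c("0", "1")
  y <- c(rep("rare", 6), rep("common", 54))
  m <- fit_classifier(x, y, kind = "multiclass_logistic", cv_folds = 3,
                      seed = 1, class_weight = "balanced")
  expect_s3_class(m, "wtss_model")
  expect_setequal(m$classes, c("rare", "common"))
})
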