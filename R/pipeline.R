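#' End-to-end shapelet discovery and classification
#'
#' Runs the full pipeline on a train/test pair: candidate extraction from
#' the training series ([extract_candidates()]; never from test data, so no
#' leakage), reduction to a final shapelet set (GAK kernel k-means
#' center-lines or a variance filter), minimum-distance feature matrices,
#' classifier fit and held-out evaluation.
#'
#' @param train,test [wtss_dataset()]s.
#' @param scales Wavelet scales for extraction.
#' @param wavelet A [wavelet_spec()].
#' @param tau Dichotomization threshold (default 1).
#' @param min_length Minimum run length (default 3).
#' @param reduce `"kmeans"` (GAK kernel k-means + center-lines) or
#'   `"variance"` (variance filter).
#' @param k Number of clusters for `"kmeans"` (default 12).
#' @param retain Minority-class retain count for `"variance"` (default 20).
#' @param classifier Passed to [fit_classifier()] `kind`.
#' @param minmax Min-max scale all series first (sensor-style workflows).
#' @param seed Integer seed (clustering, CV folds, trees).
#' @param n_init Kernel k-means restarts.
#' @return A list: `shapelets`, `model`, `confusion` (test), `macro_f1`,
#'   `pool_size`, `features_train`, `features_test`.
#' @export
wtss_classify <- function(train, test, scales,
                          wavelet = wavelet_spec(), tau = 1,
                          min_length = 3L,
                          reduce = c("kmeans", "variance"),
                          k = 12L, retain = 20L,
                          classifier = "multiclass_logistic",
                          minmax = FALSE, seed = 1L, n_init = 5L) {
  reduce <- match.arg(reduce)
  if (minmax) {
    train <- minmax_scale_dataset(train)
    test <- minmax_scale_dataset(test)
  }
  pool <- extract_candidates(train, scales, wavelet, tau = tau,
                             min_length = min_length)
  if (!length(pool$candidates)) {
    stop("extraction produced an empty candidate pool", call. = FALSE)
  }
  shapelets <- if (reduce == "kmeans") {
    km <- gak_kernel_kmeans(pool, k = k, seed = seed, n_init = n_init)
    cluster_centerlines(pool, km$assignments)
  } else {
    variance_filter(pool, retain_k_minority = retain)
  }
  ftr <- feature_matrix(shapelets, train)
  fte <- feature_matrix(shapelets, test)
  model <- fit_classifier(ftr, kind = classifier, seed = seed)
  cm <- evaluate(model, fte)
  list(shapelets = shapelets, model = model, confusion = cm,
       macro_f1 = f1_score(cm), pool_size = length(pool$candidates),
       features_train = ftr, features_test = fte)
}

#' Benchmark recipe: scales 32/64, k = 12 center-lines, logistic head
#'
#' The standard four-class benchmark configuration: complex Gaussian
#' wavelet at scales 32 and 64, threshold 1, minimum run length 3, GAK
#' kernel k-means with k = 12, multiclass logistic regression on the
#' minimum distances.
#'
#' @param train,test [wtss_dataset()]s.
#' @param seed Integer seed.
#' @param n_init Kernel k-means restarts (default 5).
#' @return See [wtss_classify()].
#' @export
wtss_trace_recipe <- function(train, test, seed = 1L, n_init = 5L) {
  wtss_classify(
    train, test, scales = c(32, 64),
    wavelet = wavelet_spec("complex_gaussian", 8L),
    tau = 1, min_length = 3L, reduce = "kmeans", k = 12L,
    classifier = "multiclass_logistic", seed = seed, n_init = n_init
  )
}
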