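#' Minimum sliding-window distance between a shapelet and a series
#'
#' Slides the shapelet across every start position of the series and returns
#' the smallest Euclidean distance to an equal-length window. With
#' `normalize_by_length` (default) the squared distance is divided by the
#' shapelet length before the square root, so shapelets of different lengths
#' produce comparable features.
#'
#' @param shapelet Numeric vector of length `L`.
#' @param series A [wtss_series()] or numeric vector with length >= `L`.
#' @param normalize_by_length Divide the squared distance by `L`.
#' @return A non-negative scalar; 0 iff the shapelet occurs exactly.
#' @export
min_distance <- function(shapelet, series, normalize_by_length = TRUE) {
  x <- if (inherits(series, "wtss_series")) series$values else
    as.numeric(series)
  s <- as.numeric(shapelet)
  if (length(s) > length(x)) {
    stop("shapelet (length ", length(s), ") longer than series (length ",
         length(x), ")", call. = FALSE)
  }
  .min_dist_cpp(s, x, normalize_by_length)
}

#' Minimum-distance feature matrix
#'
#' Entry `(i, j)` is [min_distance()] between shapelet `j` and series `i`:
#' the classifier input of the shapelet pipeline. Deterministic.
#'
#' @param shapelets A `wtss_shapelet_set`.
#' @param dataset A [wtss_dataset()].
#' @param normalize_by_length Passed to [min_distance()].
#' @return A `wtss_features`: numeric matrix with series ids as rownames and
#'   shapelet names as colnames, plus a `labels` attribute.
#' @export
feature_matrix <- function(shapelets, dataset, normalize_by_length = TRUE) {
  stopifnot(inherits(shapelets, "wtss_shapelet_set"),
            inherits(dataset, "wtss_dataset"))
  lens <- dataset_lengths(dataset)
  slens <- lengths(shapelets$shapelets)
  bad <- which(outer(slens, lens, ">"), arr.ind = TRUE)
  if (nrow(bad)) {
    pairs <- apply(bad, 1L, function(ij) {
      paste0("shapelet '", names(shapelets$shapelets)[ij[1L]],
             "' (L=", slens[ij[1L]], ") vs series '",
             names(dataset$series)[ij[2L]], "' (length ", lens[ij[2L]], ")")
    })
    stop("shapelet longer than series: ",
         paste(utils::head(pairs, 5L), collapse = "; "),
         if (length(pairs) > 5L) " ..." else "", call. = FALSE)
  }
  m <- matrix(
    0, nrow = dataset$n, ncol = length(shapelets$shapelets),
    dimnames = list(names(dataset$series), names(shapelets$shapelets))
  )
  for (i in seq_len(dataset$n)) {
    x <- dataset$series[[i]]$values
    for (j in seq_along(shapelets$shapelets)) {
      m[i, j] <- .min_dist_cpp(shapelets$shapelets[[j]], x,
                               normalize_by_length)
    }
  }
  structure(m, labels = dataset_labels(dataset), class = c("wtss_features",
                                                           "matrix", "array"))
}

#' @export
print.wtss_features <- function(x, ...) {
  cat(sprintf("<wtss_features> %d series x %d shapelets\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Write a feature matrix as CSV
#'
#' Header row of shapelet names, first column `series_id`, last column
#' `label`.
#'
#' @param features A `wtss_features`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(series_id = rownames(features),
                   as.data.frame(unclass(features)),
                   label = attr(features, "labels"),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
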