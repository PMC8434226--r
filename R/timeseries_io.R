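#' Construct a labeled univariate time series
#'
#' The atomic data object of the package: an ordered sequence of finite real
#' values sampled on an integer index (0-based time axis, no timestamps), with
#' a categorical class label. Series in one dataset may have unequal lengths;
#' operations that require equal length check and error.
#'
#' @param id Opaque identifier, coerced to character.
#' @param values Numeric vector of finite values.
#' @param label Class label, coerced to character.
#' @return An object of class `wtss_series` with fields `id`, `values`,
#'   `label` and `length`.
#' @export
#' @examples
#' s <- wtss_series("s1", c(0.5, 0.7, 0.9), label = "1")
#' s$length
wtss_series <- function(id, values, label) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a series needs at least one value", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("series '", id, "' contains non-finite values", call. = FALSE)
  }
  structure(
    list(
      id = as.character(id)[1L],
      values = values,
      label = as.character(label)[1L],
      length = length(values)
    ),
    class = "wtss_series"
  )
}

#' @export
print.wtss_series <- function(x, ...) {
  cat(sprintf(
    "<wtss_series '%s'> label=%s length=%d range=[%.4g, %.4g]\n",
    x$id, x$label, x$length, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Construct a dataset of labeled time series
#'
#' @param series A list of [wtss_series()] objects.
#' @return An object of class `wtss_dataset` with fields `series` (named by
#'   id), `label_set` and `n`.
#' @export
wtss_dataset <- function(series) {
  if (length(series) < 1L) {
    stop("a dataset needs at least one series", call. = FALSE)
  }
  ok <- vapply(series, inherits, logical(1L), what = "wtss_series")
  if (!all(ok)) {
    stop("all elements must be wtss_series objects", call. = FALSE)
  }
  ids <- vapply(series, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) {
    stop("series ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(series) <- ids
  labels <- vapply(series, `[[`, character(1L), "label")
  structure(
    list(series = series, label_set = sort(unique(labels)), n = length(series)),
    class = "wtss_dataset"
  )
}

#' @export
print.wtss_dataset <- function(x, ...) {
  lens <- dataset_lengths(x)
  cat(sprintf(
    "<wtss_dataset> n=%d classes={%s} lengths %d..%d\n",
    x$n, paste(x$label_set, collapse = ","), min(lens), max(lens)
  ))
  invisible(x)
}

#' @export
length.wtss_dataset <- function(x) x$n

dataset_labels <- function(dataset) {
  vapply(dataset$series, `[[`, character(1L), "label")
}

dataset_lengths <- function(dataset) {
  vapply(dataset$series, `[[`, integer(1L), "length")
}

#' Average total length of the series in a dataset
#'
#' The mean series length, the `ATL` quantity entering the analytic
#' candidate-window count ([brute_force_count()]).
#'
#' @param dataset A [wtss_dataset()].
#' @return A single numeric value.
#' @export
average_total_length <- function(dataset) {
  mean(dataset_lengths(dataset))
}

#' Read a dataset from delimited label-first text
#'
#' Reads the archive-style format used by the UCR time-series repository: one
#' series per row, first field the class label, remaining fields the values.
#' Rows may have different numbers of values (variable-length series are
#' allowed).
#'
#' @param path Path to a text file.
#' @param delimiter Field delimiter; default splits on any whitespace.
#'   Pass "," for comma-separated archives.
#' @param id_prefix Prefix for generated series ids (row number appended).
#' @return A [wtss_dataset()], row order preserved.
#' @export
read_ucr <- function(path, delimiter = "", id_prefix = "series") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty file: ", path, call. = FALSE)
  }
  series <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- if (identical(delimiter, "")) {
      strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    } else {
      strsplit(trimws(lines[[i]]), delimiter, fixed = TRUE)[[1L]]
    }
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L) {
      stop("row ", i, ": need a label and at least one value", call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L] + 1L
      stop("row ", i, ": field ", bad, " ('", fields[bad],
           "') is not numeric", call. = FALSE)
    }
    series[[i]] <- wtss_series(
      id = paste0(id_prefix, "_", i), values = vals, label = fields[1L]
    )
  }
  wtss_dataset(series)
}

#' Write a dataset as delimited label-first text
#'
#' Inverse of [read_ucr()]: one row per series, label first.
#'
#' @param dataset A [wtss_dataset()].
#' @param path Output path.
#' @param delimiter Field delimiter written between label and values.
#' @param digits Significant digits for values (default 15, enough for a
#'   lossless double round-trip in most cases).
#' @return `path`, invisibly.
#' @export
write_ucr <- function(dataset, path, delimiter = "\t", digits = 15L) {
  rows <- vapply(dataset$series, function(s) {
    paste(c(s$label, formatC(s$values, digits = digits, format = "g")),
          collapse = delimiter)
  }, character(1L))
  writeLines(rows, path)
  invisible(path)
}

#' Read a dataset from long-format CSV
#'
#' Expects columns `series_id`, `index`, `value`, `label`; one row per
#' observation, ordered within series by `index`.
#'
#' @param path Path to a CSV file.
#' @return A [wtss_dataset()]; series appear in order of first occurrence.
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "index", "value", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(df$series_id)
  series <- lapply(ids, function(sid) {
    block <- df[df$series_id == sid, , drop = FALSE]
    block <- block[order(block$index), , drop = FALSE]
    lab <- unique(block$label)
    if (length(lab) != 1L) {
      stop("series '", sid, "' has inconsistent labels", call. = FALSE)
    }
    wtss_series(sid, block$value, lab)
  })
  wtss_dataset(series)
}

#' Write a dataset as long-format CSV
#'
#' @param dataset A [wtss_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(dataset, path) {
  blocks <- lapply(dataset$series, function(s) {
    data.frame(
      series_id = s$id, index = seq_len(s$length) - 1L,
      value = s$values, label = s$label, stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

#' Min-max scale a series to the unit interval
#'
#' Affine per-series rescaling so the minimum maps to 0 and the maximum to 1.
#' A constant series maps to all zeros with a warning. Scaling is per-series
#' and an explicit pipeline step: on by default for sensor-panel (PM-like)
#' workflows, typically off for benchmark (TRACE-like) workflows.
#'
#' @param series A [wtss_series()].
#' @return A [wtss_series()] with values in `[0, 1]`.
#' @export
#' @examples
#' minmax_scale(wtss_series("a", c(2, 4, 6), "x"))$values  # 0 0.5 1
minmax_scale <- function(series) {
  stopifnot(inherits(series, "wtss_series"))
  rng <- range(series$values)
  if (rng[1L] == rng[2L]) {
    warning("constant series '", series$id, "': min-max scaling maps to 0",
            call. = FALSE)
    return(wtss_series(series$id, rep(0, series$length), series$label))
  }
  wtss_series(
    series$id,
    (series$values - rng[1L]) / (rng[2L] - rng[1L]),
    series$label
  )
}

#' Min-max scale every series in a dataset
#'
#' @param dataset A [wtss_dataset()].
#' @return A [wtss_dataset()] with each series scaled by [minmax_scale()].
#' @export
minmax_scale_dataset <- function(dataset) {
  wtss_dataset(lapply(dataset$series, minmax_scale))
}

# round-half-up; base round() is banker's rounding, which would give 272.59 ->
# 273 but 0.5-halves to even. Half-up reproduces a 33% holdout of 823 -> 272.
round_half_up <- function(x) floor(x + 0.5)

#' Split a dataset into train and test partitions
#'
#' Random disjoint partition with `round(test_fraction * n)` test series
#' (round-half-up). With `group_by` set, whole groups (e.g. all series from
#' one day or one household) are assigned to the same side, and the fraction
#' applies to groups; grouped splitting matters when rows are repeated
#' measurements of the same unit.
#'
#' @param dataset A [wtss_dataset()].
#' @param test_fraction Fraction in (0, 1) held out for testing.
#' @param seed Integer seed; the split is reproducible.
#' @param group_by Optional character vector, one group id per series (in
#'   dataset order); `NULL` splits per-series.
#' @return A list with elements `train` and `test`, both [wtss_dataset()]s.
#' @export
split_dataset <- function(dataset, test_fraction, seed, group_by = NULL) {
  stopifnot(inherits(dataset, "wtss_dataset"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (dataset$n < 2L) stop("need at least 2 series to split", call. = FALSE)
  units <- if (is.null(group_by)) {
    as.list(seq_len(dataset$n))
  } else {
    if (length(group_by) != dataset$n) {
      stop("group_by must have one entry per series", call. = FALSE)
    }
    split(seq_len(dataset$n), group_by)
  }
  n_units <- length(units)
  n_test <- round_half_up(test_fraction * n_units)
  n_test <- max(1L, min(n_units - 1L, as.integer(n_test)))
  pick <- with_local_seed(seed, sample.int(n_units, n_test))
  test_idx <- sort(unlist(units[pick], use.names = FALSE))
  train_idx <- setdiff(seq_len(dataset$n), test_idx)
  list(
    train = wtss_dataset(dataset$series[train_idx]),
    test = wtss_dataset(dataset$series[test_idx])
  )
}
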