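#' Standardize a power row
#'
#' Z-scores one scale row of a scalogram power matrix (mean 0, sample
#' standard deviation 1). A zero-variance row returns all zeros with a
#' warning; at the default threshold of 1 such a row can produce no
#' candidates.
#'
#' @param power_row Numeric vector, length >= 2.
#' @return Numeric vector of the same length.
#' @export
standardize_row <- function(power_row) {
  if (length(power_row) < 2L) stop("row must have length >= 2", call. = FALSE)
  s <- stats::sd(power_row)
  if (!is.finite(s) || s == 0) {
    warning("zero-variance power row: standardized to all zeros",
            call. = FALSE)
    return(rep(0, length(power_row)))
  }
  (power_row - mean(power_row)) / s
}

#' Dichotomize a standardized row at a threshold
#'
#' `1` where the standardized value is `>= tau` (inclusive), `0` below.
#'
#' @param z_row Numeric vector.
#' @param tau Finite threshold; default 1.
#' @return Integer vector of 0/1, same length.
#' @export
#' @examples
#' binarize(c(0.5, 1.2, 1.0, 0.9), tau = 1)  # 0 1 1 0
binarize <- function(z_row, tau = 1) {
  if (!is.finite(tau)) stop("tau must be finite", call. = FALSE)
  as.integer(z_row >= tau)
}

#' Extract maximal runs of ones
#'
#' Maximal runs of consecutive 1s with length at least `min_length`, in
#' increasing start order. Intervals are 0-based and half-open:
#' `[start, start + length)`.
#'
#' @param binary_row Vector of 0/1.
#' @param min_length Minimum run length kept (>= 1).
#' @return A data frame with columns `start` and `length` (possibly 0 rows).
#' @export
#' @examples
#' extract_runs(c(0, 1, 1, 1, 0, 1, 0), min_length = 1)
extract_runs <- function(binary_row, min_length = 3L) {
  min_length <- as.integer(min_length)
  if (min_length < 1L) stop("min_length must be >= 1", call. = FALSE)
  r <- rle(as.integer(binary_row))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based starts
  keep <- r$values == 1L & r$lengths >= min_length
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Extract the candidate-shapelet pool from a dataset
#'
#' The core unsupervised discovery step. For every series and every scale:
#' wavelet-transform ([cwt()]), take the power row ([power()]), standardize
#' it ([standardize_row()]), dichotomize at `tau` ([binarize()]), and keep
#' maximal runs of at least `min_length` samples ([extract_runs()]). Each
#' surviving run is clipped from the *original* series values at the run's
#' interval and becomes one candidate shapelet carrying its provenance
#' (source series, start, length, scale, class label). Exact duplicates
#' (same source, start, length arising at different scales) are
#' deduplicated; candidates whose run touches the boundary-affected region
#' (within one scale width of either end) are flagged, not dropped.
#'
#' @param dataset A [wtss_dataset()].
#' @param scales Strictly increasing positive scales.
#' @param wavelet A [wavelet_spec()].
#' @param tau Dichotomization threshold on the standardized power (default 1).
#' @param min_length Minimum run length (default 3, filtering noise runs).
#' @param standardize Either `"per_row"` (each series/scale row standardized
#'   on its own, the default) or `"global"` (one mean/sd per scale across the
#'   whole dataset).
#' @param squared Use squared-modulus power instead of modulus.
#' @return A `wtss_pool`: list with `candidates` (list of candidate records)
#'   and `provenance` (the extraction parameters).
#' @export
extract_candidates <- function(dataset, scales, wavelet = wavelet_spec(),
                               tau = 1, min_length = 3L,
                               standardize = c("per_row", "global"),
                               squared = FALSE) {
  stopifnot(inherits(dataset, "wtss_dataset"))
  standardize <- match.arg(standardize)
  powers <- lapply(dataset$series, function(s) {
    power(cwt(s, scales, wavelet), squared = squared)
  })
  if (standardize == "global") {
    row_stats <- lapply(seq_along(scales), function(r) {
      all_vals <- unlist(lapply(powers, function(p) p[r, ]))
      c(mean(all_vals), stats::sd(all_vals))
    })
  }
  candidates <- list()
  for (s in dataset$series) {
    if (diff(range(s$values)) == 0) {
      # a constant series has no signal; its scalogram is numerical dust
      next
    }
    p <- powers[[s$id]]
    for (r in seq_along(scales)) {
      z <- if (standardize == "per_row") {
        standardize_row(p[r, ])
      } else {
        st <- row_stats[[r]]
        if (st[2L] == 0) rep(0, ncol(p)) else (p[r, ] - st[1L]) / st[2L]
      }
      runs <- extract_runs(binarize(z, tau), min_length)
      if (nrow(runs) == 0L) next
      a <- scales[r]
      for (q in seq_len(nrow(runs))) {
        st0 <- runs$start[q]
        len <- runs$length[q]
        candidates[[length(candidates) + 1L]] <- list(
          values = s$values[(st0 + 1L):(st0 + len)],
          source_id = s$id, start = st0, length = len,
          scale = a, label = s$label,
          boundary_flag = st0 < ceiling(a) ||
            (st0 + len) > (s$length - ceiling(a))
        )
      }
    }
  }
  if (length(candidates)) {
    key <- vapply(candidates, function(cc) {
      paste(cc$source_id, cc$start, cc$length, sep = "|")
    }, character(1L))
    candidates <- candidates[!duplicated(key)]
  } else {
    warning("empty candidate pool", call. = FALSE)
  }
  structure(
    list(
      candidates = candidates,
      provenance = list(
        wavelet = wavelet$family, wavelet_order = wavelet$order,
        scales = scales, tau = tau, min_length = as.integer(min_length),
        standardize = standardize, squared = squared
      )
    ),
    class = "wtss_pool"
  )
}

#' @export
print.wtss_pool <- function(x, ...) {
  cat(sprintf(
    "<wtss_pool> %d candidates (scales %s, tau=%g, min_length=%d)\n",
    length(x$candidates),
    paste(x$provenance$scales, collapse = ","),
    x$provenance$tau, x$provenance$min_length
  ))
  invisible(x)
}

#' @export
length.wtss_pool <- function(x) length(x$candidates)

#' Summarize a candidate pool as a data frame
#'
#' @param pool A `wtss_pool`.
#' @return Data frame with one row per candidate: `source_id`, `start`,
#'   `length`, `scale`, `label`, `boundary_flag`, `variance`.
#' @export
pool_summary <- function(pool) {
  stopifnot(inherits(pool, "wtss_pool"))
  if (!length(pool$candidates)) {
    return(data.frame(
      source_id = character(), start = integer(), length = integer(),
      scale = numeric(), label = character(), boundary_flag = logical(),
      variance = numeric()
    ))
  }
  data.frame(
    source_id = vapply(pool$candidates, `[[`, character(1L), "source_id"),
    start = vapply(pool$candidates, `[[`, numeric(1L), "start"),
    length = vapply(pool$candidates, `[[`, numeric(1L), "length"),
    scale = vapply(pool$candidates, `[[`, numeric(1L), "scale"),
    label = vapply(pool$candidates, `[[`, character(1L), "label"),
    boundary_flag = vapply(pool$candidates, `[[`, logical(1L),
                           "boundary_flag"),
    variance = vapply(pool$candidates, function(cc) {
      stats::var(cc$values)
    }, numeric(1L)),
    row.names = NULL
  )
}

#' Write a candidate pool as JSON lines
#'
#' One JSON object per candidate: `source_id`, `start` (0-based), `length`,
#' `scale`, `label`, `values`.
#'
#' @param pool A `wtss_pool`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_jsonl <- function(pool, path) {
  lines <- vapply(pool$candidates, function(cc) {
    jsonlite::toJSON(
      list(source_id = cc$source_id, start = cc$start, length = cc$length,
           scale = cc$scale, label = cc$label, values = cc$values),
      auto_unbox = TRUE, digits = NA
    )
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Exhaustive-search candidate count
#'
#' The number of fixed-length windows an exhaustive shapelet search would
#' examine: `(ATL + 1 - L) * n`, where `ATL` is the average series length,
#' `L` the window length and `n` the number of series. This is the
#' combinatorial baseline the wavelet-based discovery avoids.
#'
#' @param ATL Average total length of the series (positive).
#' @param L Window length, `L <= ATL`.
#' @param n Number of series (positive).
#' @return The window count.
#' @export
#' @examples
#' brute_force_count(1440, 60, 1000)  # 1381000
brute_force_count <- function(ATL, L, n) {
  stopifnot(ATL > 0, L > 0, n > 0)
  if (L > ATL) stop("window length L exceeds the average series length",
                    call. = FALSE)
  (ATL + 1 - L) * n
}
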