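#' Continuous wavelet transform of a series
#'
#' Discretization of the integral transform
#' `Y(a, b) = a^(-1/2) * sum_t X(t) * Conj(psi)((t - b) / a)`
#' on the integer sample grid, one row per scale. The series is zero-padded
#' outside its observed range (no cone-of-influence masking); downstream
#' candidates that touch the boundary-affected region are flagged rather than
#' dropped. Computed by FFT convolution with the sampled wavelet.
#'
#' @param series A [wtss_series()] (length >= 2).
#' @param scales Strictly increasing positive scales, each >= 1. Scales need
#'   not be dyadic; [dyadic_scales()] is a convenience.
#' @param wavelet A [wavelet_spec()]; default complex Gaussian of order 8.
#' @return A `wtss_scalogram`: list with `coefficients` (|scales| x length
#'   complex or real matrix), `scales`, `series_id`, `wavelet`.
#' @export
#' @examples
#' s <- wtss_series("a", sin(2 * pi * (0:127) / 32), "x")
#' sc <- cwt(s, scales = c(4, 8, 16))
#' dim(sc$coefficients)
cwt <- function(series, scales, wavelet = wavelet_spec()) {
  stopifnot(inherits(series, "wtss_series"), inherits(wavelet, "wtss_wavelet"))
  n <- series$length
  if (n < 2L) stop("series must have length >= 2", call. = FALSE)
  scales <- as.numeric(scales)
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be strictly increasing", call. = FALSE)
  }
  if (any(scales > n)) {
    warning("scale(s) ", paste(scales[scales > n], collapse = ", "),
            " exceed the series length (", n,
            "); those rows are boundary-dominated", call. = FALSE)
  }
  coefs <- matrix(0i, nrow = length(scales), ncol = n)
  x <- series$values
  sup <- wavelet$support
  for (r in seq_along(scales)) {
    a <- scales[r]
    jmin <- ceiling(sup[1L] * a)
    jmax <- floor(sup[2L] * a)
    j <- jmin:jmax
    w <- Conj(wavelet_function(wavelet, j / a)) / sqrt(a)
    # Y(b) = sum_j x(b + j) w(j): full convolution of x with reversed w,
    # read off at offset jmax (zero padding implied)
    coefs[r, ] <- cross_correlate(x, w, jmax)
  }
  if (all(Im(coefs) == 0)) coefs <- Re(coefs)
  structure(
    list(coefficients = coefs, scales = scales, series_id = series$id,
         wavelet = wavelet),
    class = "wtss_scalogram"
  )
}

# full linear convolution of real x with (possibly complex) kernel v,
# returning the n cross-correlation values at lags jmax-offset
cross_correlate <- function(x, w, jmax) {
  n <- length(x)
  v <- rev(w)
  m <- n + length(v) - 1L
  fx <- stats::fft(c(as.complex(x), rep(0i, m - n)))
  fv <- stats::fft(c(as.complex(v), rep(0i, m - length(v))))
  full <- stats::fft(fx * fv, inverse = TRUE) / m
  idx <- (0:(n - 1L)) + jmax + 1L
  out <- rep(0i, n)
  valid <- idx >= 1L & idx <= m
  out[valid] <- full[idx[valid]]
  out
}

#' @export
print.wtss_scalogram <- function(x, ...) {
  cat(sprintf("<wtss_scalogram '%s'> %d scales x %d samples (%s, %s)\n",
              x$series_id, length(x$scales), ncol(x$coefficients),
              if (is.complex(x$coefficients)) "complex" else "real",
              x$wavelet$family))
  invisible(x)
}

#' Power matrix of a scalogram
#'
#' The modulus `|Y(a, b)|` of the coefficients by default; squared modulus
#' behind `squared = TRUE`. Modulus preserves the units of the input signal,
#' which keeps thresholded scalogram rows interpretable.
#'
#' @param scalogram A `wtss_scalogram` from [cwt()].
#' @param squared If `TRUE` return `|Y|^2` instead of `|Y|`.
#' @return Non-negative numeric matrix, same shape as the coefficients.
#' @export
power <- function(scalogram, squared = FALSE) {
  stopifnot(inherits(scalogram, "wtss_scalogram"))
  p <- Mod(scalogram$coefficients)
  if (squared) p^2 else p
}

#' Write a scalogram's power matrix as CSV
#'
#' One row per scale (first column the scale value), one column per sample.
#'
#' @param scalogram A `wtss_scalogram`.
#' @param path Output path.
#' @param squared Passed to [power()].
#' @return `path`, invisibly.
#' @export
write_scalogram_csv <- function(scalogram, path, squared = FALSE) {
  p <- power(scalogram, squared = squared)
  df <- data.frame(scale = scalogram$scales, p)
  names(df) <- c("scale", paste0("t", seq_len(ncol(p)) - 1L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
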