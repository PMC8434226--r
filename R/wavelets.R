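#' Specify a wavelet function
#'
#' Builds a wavelet specification for the continuous wavelet transform. The
#' complex Gaussian family (default, order 8) is the workhorse for scalogram
#' segmentation here: its modulus is a single smooth bump in time, so a
#' localized transient yields one contiguous high-power run per scale rather
#' than the split lobes produced by real oscillatory wavelets.
#'
#' Supported families and their time-domain definitions (all L2-normalized
#' numerically over their effective support):
#' * `complex_gaussian`: p-th derivative of `exp(-it) * exp(-t^2)` (order p,
#'   1-8), complex-valued.
#' * `gaussian`: p-th derivative of `exp(-t^2)` (order p, 1-8).
#' * `morlet`: `exp(-t^2/2) * cos(5 t)`.
#' * `mexican_hat`: `(1 - t^2) * exp(-t^2/2)` (second Gaussian derivative).
#' * `haar`: `+1` on `[0, 1/2)`, `-1` on `[1/2, 1)`.
#' * `daubechies`: recognized for completeness but has no closed-form time
#'   evaluation; [cwt()] rejects it (discrete multiresolution pyramids are
#'   out of scope).
#'
#' @param family One of `"complex_gaussian"`, `"gaussian"`, `"morlet"`,
#'   `"mexican_hat"`, `"haar"`, `"daubechies"`.
#' @param order Derivative order for the Gaussian families (1-8); ignored
#'   otherwise.
#' @return An object of class `wtss_wavelet` with the family, order, support
#'   interval, and numerically determined central frequency `fc` (cycles per
#'   unit of the wavelet's own time variable).
#' @export
#' @examples
#' w <- wavelet_spec("complex_gaussian", 8)
#' w$fc
wavelet_spec <- function(family = c("complex_gaussian", "gaussian", "morlet",
                                    "mexican_hat", "haar", "daubechies"),
                         order = 8L) {
  family <- match.arg(family)
  order <- as.integer(order)
  if (family %in% c("complex_gaussian", "gaussian") &&
      (order < 1L || order > 8L)) {
    stop("order must be between 1 and 8 for Gaussian-derivative families",
         call. = FALSE)
  }
  support <- switch(family,
    complex_gaussian = c(-5, 5),
    gaussian = c(-5, 5),
    morlet = c(-8, 8),
    mexican_hat = c(-8, 8),
    haar = c(0, 1),
    daubechies = c(0, 1)
  )
  spec <- structure(
    list(family = family, order = order, support = support, fc = NA_real_),
    class = "wtss_wavelet"
  )
  if (family != "daubechies") {
    spec$fc <- central_frequency(spec)
  }
  spec
}

#' @export
print.wtss_wavelet <- function(x, ...) {
  cat(sprintf("<wtss_wavelet> %s%s fc=%.4g support=[%g, %g]\n",
              x$family,
              if (x$family %in% c("complex_gaussian", "gaussian")) {
                paste0("(order ", x$order, ")")
              } else "",
              x$fc, x$support[1L], x$support[2L]))
  invisible(x)
}

# Polynomial prefactor of the p-th derivative of exp(g(t)) where
# g'(t) = a + b*t: d^p/dt^p exp(g) = P_p(t) exp(g) with
# P_{p} = P_{p-1}' + (a + b t) P_{p-1}. Coefficients ascending in t,
# complex-valued for the complex Gaussian.
gauss_deriv_poly <- function(p, a, b) {
  poly <- as.complex(1)
  for (i in seq_len(p)) {
    n <- length(poly)
    dpoly <- if (n > 1L) poly[-1L] * seq_len(n - 1L) else as.complex(0)
    shifted <- c(as.complex(0), poly)          # t * poly
    lin <- a * c(poly, as.complex(0)) + b * shifted
    m <- max(length(dpoly), length(lin))
    poly <- c(dpoly, rep(as.complex(0), m - length(dpoly))) +
      c(lin, rep(as.complex(0), m - length(lin)))
  }
  poly
}

eval_poly <- function(coef, t) {
  out <- rep(coef[length(coef)], length(t))
  for (i in rev(seq_len(length(coef) - 1L))) {
    out <- out * t + coef[i]
  }
  out
}

#' Evaluate a wavelet function on a grid
#'
#' Returns psi(t), L2-normalized so the sampled energy over the support
#' integrates to 1 (trapezoid rule on a fine grid). Complex for the complex
#' Gaussian family, real otherwise.
#'
#' @param wavelet A [wavelet_spec()].
#' @param t Numeric vector of evaluation points.
#' @return Complex or numeric vector of psi values; zero outside the support.
#' @export
wavelet_function <- function(wavelet, t) {
  stopifnot(inherits(wavelet, "wtss_wavelet"))
  fam <- wavelet$family
  if (fam == "daubechies") {
    stop("daubechies wavelets have no closed-form time evaluation; ",
         "use a continuous family for the CWT", call. = FALSE)
  }
  raw <- switch(fam,
    complex_gaussian = {
      poly <- gauss_deriv_poly(wavelet$order, a = -1i, b = -2 + 0i)
      eval_poly(poly, as.complex(t)) * exp(-1i * t - t^2)
    },
    gaussian = {
      poly <- gauss_deriv_poly(wavelet$order, a = 0 + 0i, b = -2 + 0i)
      Re(eval_poly(poly, as.complex(t))) * exp(-t^2)
    },
    morlet = exp(-t^2 / 2) * cos(5 * t),
    mexican_hat = (1 - t^2) * exp(-t^2 / 2),
    haar = ifelse(t >= 0 & t < 0.5, 1, ifelse(t >= 0.5 & t < 1, -1, 0))
  )
  sup <- wavelet$support
  raw[t < sup[1L] | t > sup[2L]] <- 0
  raw / sqrt(wavelet_energy(wavelet))
}

# Unnormalized energy integral over the support, cached per spec contents.
wavelet_energy <- function(wavelet) {
  key <- paste0(wavelet$family, "_", wavelet$order)
  cached <- .wtss_wavelet_cache[[key]]
  if (!is.null(cached)) return(cached)
  sup <- wavelet$support
  grid <- seq(sup[1L], sup[2L], length.out = 8192L)
  raw <- switch(wavelet$family,
    complex_gaussian = {
      poly <- gauss_deriv_poly(wavelet$order, a = -1i, b = -2 + 0i)
      eval_poly(poly, as.complex(grid)) * exp(-1i * grid - grid^2)
    },
    gaussian = {
      poly <- gauss_deriv_poly(wavelet$order, a = 0 + 0i, b = -2 + 0i)
      Re(eval_poly(poly, as.complex(grid))) * exp(-grid^2)
    },
    morlet = exp(-grid^2 / 2) * cos(5 * grid),
    mexican_hat = (1 - grid^2) * exp(-grid^2 / 2),
    haar = ifelse(grid >= 0 & grid < 0.5, 1, ifelse(grid < 1, -1, 0))
  )
  h <- grid[2L] - grid[1L]
  e <- sum(Mod(raw)^2) * h
  .wtss_wavelet_cache[[key]] <- e
  e
}

.wtss_wavelet_cache <- new.env(parent = emptyenv())

#' Central frequency of a wavelet
#'
#' The dominant oscillation frequency of psi, located as the peak of the
#' magnitude spectrum of the wavelet sampled on a fine grid over its support.
#' Units: cycles per unit of the wavelet time variable; the pseudo-frequency
#' at scale `a` is then `fc / a` cycles per sample.
#'
#' @param wavelet A [wavelet_spec()].
#' @return A positive scalar.
#' @export
central_frequency <- function(wavelet) {
  sup <- wavelet$support
  n <- 4096L
  grid <- seq(sup[1L], sup[2L], length.out = n)
  h <- grid[2L] - grid[1L]
  # bypass the cached fc to allow use during spec construction
  w <- wavelet
  w$fc <- 0
  vals <- wavelet_function_raw(w, grid)
  spec <- Mod(stats::fft(vals))
  freqs <- (seq_len(n) - 1L) / (n * h)
  # for complex wavelets the spectrum is one-sided; for real ones it is
  # symmetric, so restricting to the first half finds the positive peak
  half <- seq_len(floor(n / 2))
  peak <- half[which.max(spec[half])]
  max(freqs[peak], 1 / (n * h))
}

# evaluation without the normalization constant (fc does not depend on it)
wavelet_function_raw <- function(wavelet, t) {
  switch(wavelet$family,
    complex_gaussian = {
      poly <- gauss_deriv_poly(wavelet$order, a = -1i, b = -2 + 0i)
      eval_poly(poly, as.complex(t)) * exp(-1i * t - t^2)
    },
    gaussian = {
      poly <- gauss_deriv_poly(wavelet$order, a = 0 + 0i, b = -2 + 0i)
      Re(eval_poly(poly, as.complex(t))) * exp(-t^2) + 0i
    },
    morlet = exp(-t^2 / 2) * cos(5 * t) + 0i,
    mexican_hat = (1 - t^2) * exp(-t^2 / 2) + 0i,
    haar = ifelse(t >= 0 & t < 0.5, 1, ifelse(t >= 0.5 & t < 1, -1, 0)) + 0i,
    stop("unsupported family", call. = FALSE)
  )
}

#' Dyadic scale grid
#'
#' Powers of two from `2^min_power` to `2^max_power`, the conventional scale
#' progression for scalogram inspection.
#'
#' @param min_power,max_power Non-negative integers, `min_power <= max_power`.
#' @return Numeric vector of scales.
#' @export
#' @examples
#' dyadic_scales(5, 6)  # 32 64
dyadic_scales <- function(min_power, max_power) {
  stopifnot(min_power >= 0, max_power >= min_power)
  2^(seq.int(min_power, max_power))
}

#' Pseudo-frequency of a scale
#'
#' Converts a wavelet scale to the approximate oscillation frequency it
#' responds to: `fa = fc / a`, in cycles per sample.
#'
#' @param fc Central frequency of the wavelet (positive).
#' @param a Scale (positive).
#' @return `fc / a`.
#' @export
pseudo_frequency <- function(fc, a) {
  if (!is.numeric(fc) || any(fc <= 0) || !is.numeric(a) || any(a <= 0)) {
    stop("fc and a must be positive", call. = FALSE)
  }
  fc / a
}
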