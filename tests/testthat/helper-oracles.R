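# Independent brute-force oracles used to validate the optimized paths.
# Each one is a direct transcription of the defining formula, kept free of
# any package internals beyond constructors.

# discretized wavelet transform by direct quadrature:
# Y(a, b) = a^(-1/2) sum_t X(t) Conj(psi)((t - b) / a), zero padding
oracle_cwt_row <- function(x, a, wavelet) {
  n <- length(x)
  vapply(0:(n - 1L), function(b) {
    t_idx <- 0:(n - 1L)
    sum(x * Conj(wavelet_function(wavelet, (t_idx - b) / a))) / sqrt(a)
  }, complex(1L))
}

# naive all-windows minimum Euclidean distance
oracle_min_distance <- function(s, x, normalize = TRUE) {
  L <- length(s)
  best <- Inf
  for (p in 1:(length(x) - L + 1L)) {
    d2 <- sum((x[p:(p + L - 1L)] - s)^2)
    if (normalize) d2 <- d2 / L
    best <- min(best, d2)
  }
  sqrt(best)
}

# global alignment kernel by explicit enumeration of all monotone alignment
# paths from cell (1,1) to (n,m) with steps (1,0), (0,1), (1,1); the weight
# of a path is the product of local kernels over its cells
oracle_gak <- function(x, y, sigma) {
  kloc <- function(i, j) {
    k <- exp(-(x[i] - y[j])^2 / (2 * sigma^2))
    k / (2 - k)
  }
  n <- length(x)
  m <- length(y)
  total <- 0
  walk <- function(i, j, w) {
    w <- w * kloc(i, j)
    if (i == n && j == m) {
      total <<- total + w
      return(invisible())
    }
    if (i < n) walk(i + 1L, j, w)
    if (j < m) walk(i, j + 1L, w)
    if (i < n && j < m) walk(i + 1L, j + 1L, w)
  }
  walk(1L, 1L, 1)
  total
}

# exhaustive enumeration of fixed-length windows across a dataset
oracle_window_count <- function(dataset, L) {
  sum(vapply(dataset$series, function(s) {
    max(0L, s$length - L + 1L)
  }, integer(1L)))
}

# total time covered by extracted intervals, per series/scale
covered_time <- function(pool) {
  df <- pool_summary(pool)
  if (!nrow(df)) return(0)
  sum(df$length)
}

# small random dataset fixture
random_dataset <- function(n = 6L, len_range = c(30L, 60L), n_classes = 2L,
                           seed = 1L) {
  set.seed(seed)
  wtss_dataset(lapply(seq_len(n), function(i) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    wtss_series(paste0("r", i), stats::rnorm(len),
                label = as.character(1L + i %% n_classes))
  }))
}
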