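# internal helpers shared across modules

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream; restores (or removes) .Random.seed on exit.
with_local_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Linear interpolation of a sequence onto `m` equally spaced points spanning
# its full index range; m == length(x) returns x unchanged.
resample_linear <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  if (n == 1L) return(rep(x, m))
  stats::approx(seq_len(n), x, xout = seq(1, n, length.out = m))$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
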