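#' Four-class benchmark-style series with local discriminative patterns
#'
#' Generates labeled series in which each class carries a distinct local
#' template inserted at a uniformly jittered position on a noisy flat
#' baseline, mimicking instrumentation-failure benchmarks where classes
#' differ only in the shape of a localized event, not its exact timing.
#' Templates (unit amplitude, length `pattern_length`):
#' class 1 a rectangular step pulse; class 2 a linear ramp ending in a sharp
#' drop; class 3 a smoothed (Gaussian) bump; class 4 a flat series with a
#' late step up that is sustained to the end of the series (a level change,
#' not a pulse -- its local shape, a rise with no fall, is what
#' distinguishes it from class 1 under shift-invariant distance features).
#'
#' @param n_per_class Series per class (default 25, giving n = 100).
#' @param length Series length (default 275).
#' @param jitter Maximum uniform shift of the pattern position, in samples
#'   (default 30).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 0.1).
#' @param pattern_length Template length (default 60).
#' @param seed Integer seed; the output is fully reproducible.
#' @return A list with `dataset` (a [wtss_dataset()]) and `truth`, a data
#'   frame of planted intervals (`series_id`, `start`, `length`,
#'   `shape_id`, `label`) plus the generator parameters as attributes.
#' @export
generate_trace_like <- function(n_per_class = 25L, length = 275L,
                                jitter = 30L, noise_sd = 0.1,
                                pattern_length = 60L, seed = 1L) {
  length <- as.integer(length)
  jitter <- as.integer(jitter)
  pattern_length <- as.integer(pattern_length)
  base_start <- as.integer(round(length * 0.3))
  if (base_start + jitter + pattern_length > length) {
    stop("pattern does not fit: reduce jitter or pattern_length",
         call. = FALSE)
  }
  tpl <- list(
    step = rep(1, pattern_length),
    ramp_step = c(seq(0, 1, length.out = pattern_length - 10L), rep(0, 10L)),
    smooth = exp(-((seq_len(pattern_length) - pattern_length / 2)^2) /
                   (2 * (pattern_length / 6)^2)),
    late_step = rep(1, pattern_length)
  )
  with_local_seed(seed, {
    series <- list()
    truth <- list()
    idx <- 0L
    for (cl in 1:4) {
      for (r in seq_len(n_per_class)) {
        idx <- idx + 1L
        x <- stats::rnorm(length, 0, noise_sd)
        if (cl == 4L) {
          # late sustained step: level change held to the end of the series
          lo <- length - pattern_length - jitter
          st <- lo + if (jitter > 0L) sample.int(jitter + 1L, 1L) - 1L else 0L
          span <- (st + 1L):length
          x[span] <- x[span] + 1
        } else {
          st <- base_start +
            if (jitter > 0L) sample.int(jitter + 1L, 1L) - 1L else 0L
          span <- (st + 1L):(st + pattern_length)
          x[span] <- x[span] + tpl[[cl]]
        }
        sid <- sprintf("c%d_%03d", cl, r)
        series[[idx]] <- wtss_series(sid, x, label = as.character(cl))
        truth[[idx]] <- data.frame(
          series_id = sid, start = st,
          length = if (cl == 4L) length - st else pattern_length,
          shape_id = names(tpl)[cl], label = as.character(cl)
        )
      }
    }
    truth_df <- do.call(rbind, truth)
    attr(truth_df, "params") <- list(
      n_per_class = n_per_class, length = length, jitter = jitter,
      noise_sd = noise_sd, pattern_length = pattern_length, seed = seed
    )
    list(dataset = wtss_dataset(series), truth = truth_df)
  })
}

#' Spike-train series emulating indoor/outdoor particulate exposure
#'
#' Two-class nonnegative series: a noisy baseline plus Gaussian-shaped
#' transient spikes at Poisson-distributed counts. The `"indoor"` class is
#' enriched for spikes; the `"outdoor"` class has proportionally fewer
#' spikes and a slow sinusoidal trend instead. `labeled_class_effect` in
#' `[0, 1]` controls the separation: at 0 the two classes are exchangeable
#' (a leakage null), at 1 the outdoor class has no spikes at all. Every
#' planted spike interval is recorded as ground truth.
#'
#' @param n Number of series (split evenly between the classes; indoor gets
#'   the remainder).
#' @param length Series length (default 1440, one sample per minute of a
#'   day).
#' @param spike_rate Mean spike count per indoor series (Poisson; default
#'   3).
#' @param spike_count If non-`NULL`, exact spike count per indoor series
#'   (overrides the Poisson draw; useful for controlled recovery tests).
#' @param spike_width_range Min/max full spike width in samples (default
#'   c(20, 60)).
#' @param spike_height_range Min/max spike peak height (default c(0.5, 1)).
#' @param baseline Baseline level (default 0.1).
#' @param baseline_sd Baseline noise standard deviation (default 0.02).
#' @param labeled_class_effect Class separation in `[0, 1]` (default 1).
#' @param seed Integer seed.
#' @return A list with `dataset` and `truth` as in
#'   [generate_trace_like()]; all generated values are >= 0.
#' @export
generate_spike_series <- function(n, length = 1440L, spike_rate = 3,
                                  spike_count = NULL,
                                  spike_width_range = c(20L, 60L),
                                  spike_height_range = c(0.5, 1),
                                  baseline = 0.1, baseline_sd = 0.02,
                                  labeled_class_effect = 1, seed = 1L) {
  length <- as.integer(length)
  if (max(spike_width_range) >= length) {
    stop("spike widths must be smaller than the series length",
         call. = FALSE)
  }
  stopifnot(labeled_class_effect >= 0, labeled_class_effect <= 1)
  n_out <- n %/% 2L
  n_in <- n - n_out
  rate_out <- spike_rate * (1 - labeled_class_effect)
  trend_out <- 0.3 * labeled_class_effect
  with_local_seed(seed, {
    series <- list()
    truth <- list()
    idx <- 0L
    t_axis <- seq_len(length) - 1L
    for (cl in c("indoor", "outdoor")) {
      n_cl <- if (cl == "indoor") n_in else n_out
      for (r in seq_len(n_cl)) {
        idx <- idx + 1L
        sid <- sprintf("%s_%03d", cl, r)
        x <- baseline + stats::rnorm(length, 0, baseline_sd)
        if (cl == "outdoor" && trend_out > 0) {
          phase <- stats::runif(1L, 0, 2 * pi)
          x <- x + trend_out * (1 + sin(2 * pi * t_axis / length + phase)) / 2
        }
        n_spikes <- if (!is.null(spike_count)) {
          # exact count; outdoor scaled by the class effect like the rate
          if (cl == "indoor") {
            as.integer(spike_count)
          } else {
            as.integer(round(spike_count * (1 - labeled_class_effect)))
          }
        } else {
          stats::rpois(1L, if (cl == "indoor") spike_rate else rate_out)
        }
        if (n_spikes > 0L) {
          for (sp in seq_len(n_spikes)) {
            w <- as.integer(round(stats::runif(
              1L, spike_width_range[1L], spike_width_range[2L]
            )))
            h <- stats::runif(1L, spike_height_range[1L],
                              spike_height_range[2L])
            center <- as.integer(round(stats::runif(1L, w, length - w)))
            bump <- h * exp(-((t_axis - center)^2) / (2 * (w / 4)^2))
            x <- x + bump
            truth[[length(truth) + 1L]] <- data.frame(
              series_id = sid, start = as.integer(center - w %/% 2L),
              length = w, shape_id = "spike", label = cl
            )
          }
        }
        x <- pmax(x, 0)
        series[[idx]] <- wtss_series(sid, x, label = cl)
      }
    }
    truth_df <- if (length(truth)) {
      do.call(rbind, truth)
    } else {
      data.frame(series_id = character(), start = integer(),
                 length = integer(), shape_id = character(),
                 label = character())
    }
    attr(truth_df, "params") <- list(
      n = n, length = length, spike_rate = spike_rate,
      spike_count = spike_count, spike_width_range = spike_width_range,
      spike_height_range = spike_height_range, baseline = baseline,
      baseline_sd = baseline_sd,
      labeled_class_effect = labeled_class_effect, seed = seed
    )
    list(dataset = wtss_dataset(series), truth = truth_df)
  })
}

#' Overlap of planted intervals with extracted candidates
#'
#' For each ground-truth interval, checks whether at least one candidate
#' from the same series overlaps it (Jaccard > 0 suffices), the recovery
#' check for the extraction stage.
#'
#' @param truth Ground-truth data frame (`series_id`, `start`, `length`).
#' @param pool A `wtss_pool`.
#' @return `truth` with added logical column `recovered` and numeric
#'   `best_jaccard`.
#' @export
recovery_table <- function(truth, pool) {
  cand <- pool_summary(pool)
  truth$recovered <- FALSE
  truth$best_jaccard <- 0
  for (i in seq_len(nrow(truth))) {
    cc <- cand[cand$source_id == truth$series_id[i], , drop = FALSE]
    if (!nrow(cc)) next
    a1 <- truth$start[i]
    a2 <- a1 + truth$length[i]
    inter <- pmax(0, pmin(a2, cc$start + cc$length) - pmax(a1, cc$start))
    uni <- (a2 - a1) + cc$length - inter
    jac <- inter / uni
    truth$best_jaccard[i] <- max(jac)
    truth$recovered[i] <- any(jac > 0)
  }
  truth
}
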