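#' Construct a shapelet set
#'
#' Internal-facing constructor; users normally obtain shapelet sets from
#' [variance_filter()] or [cluster_centerlines()]. Shapelets are named
#' `"0"`, `"1"`, ... by descending variance (a low number means larger
#' variance), the convention used throughout reporting.
#'
#' @param sequences List of numeric vectors (each length >= 2).
#' @param origin `"filtered_candidate"` or `"cluster_centerline"`.
#' @param info Optional data frame of per-shapelet metadata (one row per
#'   sequence, pre-ordering).
#' @return A `wtss_shapelet_set`: `shapelets` (named list, variance-ordered),
#'   `origin`, `info` (re-ordered to match, with `name` and `variance`
#'   columns added).
#' @export
shapelet_set <- function(sequences, origin = c("filtered_candidate",
                                               "cluster_centerline"),
                         info = NULL) {
  origin <- match.arg(origin)
  if (!length(sequences)) stop("empty shapelet set", call. = FALSE)
  if (any(lengths(sequences) < 2L)) {
    stop("every shapelet needs length >= 2", call. = FALSE)
  }
  v <- vapply(sequences, stats::var, numeric(1L))
  ord <- order(v, decreasing = TRUE)
  sequences <- sequences[ord]
  names(sequences) <- as.character(seq_along(sequences) - 1L)
  if (is.null(info)) {
    info <- data.frame(row.names = seq_along(sequences))
  } else {
    info <- info[ord, , drop = FALSE]
  }
  info <- cbind(
    data.frame(name = names(sequences), variance = v[ord],
               length = lengths(sequences), row.names = NULL),
    info
  )
  structure(list(shapelets = sequences, origin = origin, info = info),
            class = "wtss_shapelet_set")
}

#' @export
print.wtss_shapelet_set <- function(x, ...) {
  cat(sprintf("<wtss_shapelet_set> %d shapelets (%s), lengths %d..%d\n",
              length(x$shapelets), x$origin,
              min(lengths(x$shapelets)), max(lengths(x$shapelets))))
  invisible(x)
}

#' @export
length.wtss_shapelet_set <- function(x) length(x$shapelets)

#' Variance filter of a candidate pool
#'
#' Keeps high-variation candidates. The variance threshold is anchored in a
#' designated class -- by default the minority class (fewest candidates) --
#' as the `retain_k_minority`-th largest candidate variance in that class;
#' all candidates in *all* classes with variance at or above that threshold
#' are retained. This reproduces the "retain at least k in the minority
#' class, apply the same threshold everywhere" rule used for imbalanced
#' tasks. With `by_class = FALSE` the threshold is the k-th largest variance
#' over the pooled candidates.
#'
#' @param pool A `wtss_pool`.
#' @param retain_k_minority Number of candidates the anchor class must
#'   retain (>= 1, at most the anchor-class candidate count).
#' @param by_class Anchor the threshold in one class (default) or pool all.
#' @param minority_class Optional class label overriding the automatic
#'   minority choice.
#' @return A `wtss_shapelet_set` of origin `"filtered_candidate"`.
#' @export
variance_filter <- function(pool, retain_k_minority, by_class = TRUE,
                            minority_class = NULL) {
  stopifnot(inherits(pool, "wtss_pool"))
  df <- pool_summary(pool)
  if (!nrow(df)) stop("cannot filter an empty pool", call. = FALSE)
  retain_k_minority <- as.integer(retain_k_minority)
  stopifnot(retain_k_minority >= 1L)
  if (by_class) {
    tab <- table(df$label)
    anchor <- if (is.null(minority_class)) {
      names(tab)[which.min(tab)]
    } else {
      as.character(minority_class)
    }
    in_anchor <- df$label == anchor
    if (!any(in_anchor)) {
      stop("no candidates in class '", anchor, "'", call. = FALSE)
    }
    anchor_vars <- sort(df$variance[in_anchor], decreasing = TRUE)
    if (retain_k_minority > length(anchor_vars)) {
      stop("retain_k_minority (", retain_k_minority,
           ") exceeds the candidate count of class '", anchor, "' (",
           length(anchor_vars), ")", call. = FALSE)
    }
    threshold <- anchor_vars[retain_k_minority]
  } else {
    all_vars <- sort(df$variance, decreasing = TRUE)
    if (retain_k_minority > length(all_vars)) {
      stop("retain_k_minority exceeds the pool size", call. = FALSE)
    }
    threshold <- all_vars[retain_k_minority]
  }
  keep <- which(df$variance >= threshold)
  shapelet_set(
    lapply(pool$candidates[keep], `[[`, "values"),
    origin = "filtered_candidate",
    info = df[keep, c("source_id", "start", "scale", "label"), drop = FALSE]
  )
}

#' Global alignment kernel between two sequences
#'
#' Sums, over all monotone alignments of the two sequences, the product of
#' per-step Gaussian local similarities (in Cuturi's infinitely divisible
#' form `k/(2-k)`), by dynamic programming in the log domain, so long or
#' dissimilar sequences never under- or overflow. The normalized variant
#' `k(x, y) / sqrt(k(x, x) k(y, y))` equals 1 at `x == y` and is the form
#' used for clustering.
#'
#' @param x,y Non-empty numeric sequences (may differ in length).
#' @param sigma Positive bandwidth of the Gaussian local kernel.
#' @param normalize Return the normalized kernel value.
#' @param log Return the (unnormalized) log-kernel value.
#' @return A non-negative scalar (or its log).
#' @export
gak <- function(x, y, sigma, normalize = FALSE, log = FALSE) {
  stopifnot(length(x) >= 1L, length(y) >= 1L, sigma > 0)
  lk <- .gak_log_cpp(as.numeric(x), as.numeric(y), sigma)
  if (log) {
    if (normalize) stop("choose log or normalize, not both", call. = FALSE)
    return(lk)
  }
  if (normalize) {
    lxx <- .gak_log_cpp(as.numeric(x), as.numeric(x), sigma)
    lyy <- .gak_log_cpp(as.numeric(y), as.numeric(y), sigma)
    return(exp(lk - 0.5 * (lxx + lyy)))
  }
  exp(lk)
}

#' Bandwidth heuristic for the global alignment kernel
#'
#' `sigma = median |x_i - y_j| * sqrt(median length)`, estimated over a
#' random subsample of sequence-value pairs. Scaling by the root of the
#' typical length keeps the per-path product of local kernels comparable
#' across sequence lengths.
#'
#' @param sequences List of numeric vectors.
#' @param seed Seed for the subsample.
#' @param max_values Cap on sampled values per side.
#' @return A positive scalar.
#' @export
gak_sigma <- function(sequences, seed = 1L, max_values = 1000L) {
  vals <- unlist(sequences, use.names = FALSE)
  if (length(vals) > max_values) {
    vals <- with_local_seed(seed, sample(vals, max_values))
  }
  d <- stats::median(abs(outer(vals, vals, "-")))
  if (d == 0) d <- 1  # degenerate all-equal pool
  d * sqrt(stats::median(lengths(sequences)))
}

#' Kernel k-means on the global-alignment-kernel Gram matrix
#'
#' Clusters variable-length candidate shapelets without embedding them in a
#' common vector space: standard kernel k-means on the normalized GAK Gram
#' matrix, where the squared distance of point `i` to the (implicit) center
#' of cluster `C` is `K[i,i] - 2 mean(K[i, C]) + mean(K[C, C])`. The
#' kernel-space inertia is non-increasing across iterations; an empty
#' cluster is re-seeded from the point farthest from its current center.
#' The best of `n_init` random initializations (lowest final inertia) is
#' returned; results are bit-reproducible under a fixed seed.
#'
#' @param pool A `wtss_pool`, or a plain list of numeric sequences.
#' @param k Number of clusters (`1 <= k <=` pool size).
#' @param sigma GAK bandwidth; default the [gak_sigma()] heuristic.
#' @param seed Integer seed.
#' @param n_init Number of random initializations (default 5).
#' @param max_iter Iteration cap per initialization.
#' @return A list: `assignments` (integer vector in `1..k`), `inertia`,
#'   `inertia_trace` (per-iteration inertia of the winning run), `sigma`,
#'   `gram` (the normalized Gram matrix).
#' @export
gak_kernel_kmeans <- function(pool, k, sigma = NULL, seed = 1L, n_init = 5L,
                              max_iter = 100L) {
  seqs <- if (inherits(pool, "wtss_pool")) {
    lapply(pool$candidates, `[[`, "values")
  } else {
    pool
  }
  n <- length(seqs)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie in 1..pool size", call. = FALSE)
  if (is.null(sigma)) sigma <- gak_sigma(seqs, seed = seed)
  K <- .gak_gram_cpp(seqs, sigma, TRUE)
  best <- NULL
  with_local_seed(seed, {
    for (init in seq_len(n_init)) {
      res <- kernel_kmeans_once(K, k, max_iter)
      if (is.null(best) || res$inertia < best$inertia) best <- res
    }
  })
  list(assignments = best$assignments, inertia = best$inertia,
       inertia_trace = best$trace, sigma = sigma, gram = K)
}

# one kernel k-means run on Gram matrix K; uses the current RNG stream
kernel_kmeans_once <- function(K, k, max_iter) {
  n <- nrow(K)
  assign_vec <- sample(rep_len(seq_len(k), n))
  diagK <- diag(K)
  trace <- numeric(0)
  d2 <- NULL
  for (iter in seq_len(max_iter)) {
    # distance of every point to every cluster center in feature space
    d2 <- matrix(Inf, n, k)
    for (c in seq_len(k)) {
      members <- which(assign_vec == c)
      if (!length(members)) {
        # re-seed from the point farthest from its own center
        far <- which.max(apply(d2, 1L, function(row) {
          suppressWarnings(min(row, na.rm = TRUE))
        }))
        members <- far
        assign_vec[far] <- c
      }
      Kic <- rowMeans(K[, members, drop = FALSE])
      Kcc <- mean(K[members, members, drop = FALSE])
      d2[, c] <- diagK - 2 * Kic + Kcc
    }
    new_assign <- max.col(-d2, ties.method = "first")
    trace <- c(trace, sum(d2[cbind(seq_len(n), new_assign)]))
    if (all(new_assign == assign_vec)) {
      assign_vec <- new_assign
      break
    }
    assign_vec <- new_assign
  }
  list(assignments = assign_vec, inertia = trace[length(trace)],
       trace = trace)
}

#' Center-lines of candidate clusters
#'
#' Kernel k-means has no explicit centroids, so each cluster is summarized
#' by a center-line: members are linearly resampled to the cluster's target
#' length (the median member length by default) and averaged pointwise. A
#' singleton cluster's center-line is the member itself.
#'
#' @param pool A `wtss_pool`.
#' @param assignments Integer cluster labels, one per candidate.
#' @param target_length_rule `"median"` (default) or `"max"` member length.
#' @return A `wtss_shapelet_set` of origin `"cluster_centerline"`, with the
#'   source cluster id and member count in `info`.
#' @export
cluster_centerlines <- function(pool, assignments,
                                target_length_rule = c("median", "max")) {
  stopifnot(inherits(pool, "wtss_pool"))
  target_length_rule <- match.arg(target_length_rule)
  seqs <- lapply(pool$candidates, `[[`, "values")
  if (length(assignments) != length(seqs)) {
    stop("one assignment per candidate required", call. = FALSE)
  }
  clusters <- sort(unique(assignments))
  centers <- vector("list", length(clusters))
  meta <- data.frame(cluster = clusters, n_members = NA_integer_)
  for (i in seq_along(clusters)) {
    members <- seqs[assignments == clusters[i]]
    if (!length(members)) stop("empty cluster ", clusters[i], call. = FALSE)
    m <- if (target_length_rule == "median") {
      max(2L, as.integer(round_half_up(stats::median(lengths(members)))))
    } else {
      max(lengths(members))
    }
    resampled <- vapply(members, resample_linear, numeric(m), m = m)
    centers[[i]] <- rowMeans(resampled)
    meta$n_members[i] <- length(members)
  }
  shapelet_set(centers, origin = "cluster_centerline", info = meta)
}

#' Write a shapelet set as JSON
#'
#' @param shapelets A `wtss_shapelet_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shapelets_json <- function(shapelets, path) {
  stopifnot(inherits(shapelets, "wtss_shapelet_set"))
  obj <- lapply(seq_along(shapelets$shapelets), function(i) {
    c(list(name = names(shapelets$shapelets)[i],
           origin = shapelets$origin,
           values = shapelets$shapelets[[i]]),
      as.list(shapelets$info[i, setdiff(names(shapelets$info), "name"),
                             drop = FALSE]))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a shapelet set from JSON
#'
#' @param path Path written by [write_shapelets_json()].
#' @return A `wtss_shapelet_set`.
#' @export
read_shapelets_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  seqs <- lapply(obj, function(o) as.numeric(o$values))
  origin <- obj[[1L]]$origin
  shapelet_set(seqs, origin = origin)
}
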