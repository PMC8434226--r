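#' Soft-minimum window distance
#'
#' Differentiable surrogate of the hard minimum over sliding-window
#' distances: with per-window distances `d_p` (length-normalized squared
#' Euclidean, matching the distance regime of the discovery pipeline) the
#' soft minimum is `sum(d_p exp(alpha d_p)) / sum(exp(alpha d_p))` with
#' `alpha < 0`. As `alpha -> -Inf` it converges to `min(d_p)`; with a
#' single admissible window it equals that window's distance for any alpha.
#' Computed with a shifted exponent so large `|alpha|` never underflows.
#'
#' @param shapelet Numeric vector of length `L`.
#' @param series A [wtss_series()] or numeric vector, length >= `L`.
#' @param alpha Negative sharpness parameter.
#' @return A scalar between the hard minimum and maximum window distance.
#' @export
soft_min_distance <- function(shapelet, series, alpha = -30) {
  if (!is.numeric(alpha) || alpha >= 0) {
    stop("alpha must be negative", call. = FALSE)
  }
  x <- if (inherits(series, "wtss_series")) series$values else
    as.numeric(series)
  d <- window_sq_distances(as.numeric(shapelet), x)
  e <- alpha * d
  e <- e - max(e)
  wts <- exp(e)
  sum(d * wts) / sum(wts)
}

# length-normalized squared Euclidean distance to every window, vectorized:
# d_p = (sum s^2 - 2 w_p . s + sum w_p^2) / L
window_sq_distances <- function(s, x) {
  L <- length(s)
  n <- length(x)
  if (L > n) stop("shapelet longer than series", call. = FALSE)
  P <- n - L + 1L
  cx2 <- cumsum(c(0, x^2))
  w2 <- cx2[(L + 1L):(n + 1L)] - cx2[1L:P]
  cross <- vapply(seq_len(P), function(p) {
    sum(x[p:(p + L - 1L)] * s)
  }, numeric(1L))
  pmax(0, (sum(s^2) - 2 * cross + w2) / L)
}

# all sliding windows of length L from x, as a P x L matrix, with the
# per-window sum of squares (cached by the training loop)
window_matrix <- function(x, L) {
  n <- length(x)
  P <- n - L + 1L
  W <- matrix(0, P, L)
  for (p in seq_len(P)) W[p, ] <- x[p:(p + L - 1L)]
  list(W = W, w2 = rowSums(W^2))
}

# soft-min value and gradient w.r.t. the shapelet from a cached window
# matrix; the single differentiable core shared by training and prediction
soft_min_core <- function(s, wc, alpha) {
  L <- length(s)
  d <- pmax(0, (sum(s^2) - 2 * drop(wc$W %*% s) + wc$w2) / L)
  e <- alpha * d
  e <- e - max(e)
  wts <- exp(e)
  wts <- wts / sum(wts)
  m <- sum(d * wts)
  # dm/dd_q = wts_q (1 + alpha (d_q - m)); dd_q/ds = 2 (s - w_q) / L
  dm_dd <- wts * (1 + alpha * (d - m))
  grad <- (2 / L) * (sum(dm_dd) * s - drop(crossprod(wc$W, dm_dd)))
  list(value = m, grad = grad)
}

#' Soft-minimum distance with its gradient
#'
#' Returns the soft-minimum window distance and its analytic gradient with
#' respect to the shapelet values, the quantities driving the gradient
#' updates in [learn_shapelets()].
#'
#' @inheritParams soft_min_distance
#' @return A list with `value` (scalar) and `grad` (numeric vector of the
#'   shapelet's length).
#' @export
soft_min_grad <- function(shapelet, series, alpha = -30) {
  if (!is.numeric(alpha) || alpha >= 0) {
    stop("alpha must be negative", call. = FALSE)
  }
  x <- if (inherits(series, "wtss_series")) series$values else
    as.numeric(series)
  s <- as.numeric(shapelet)
  soft_min_core(s, window_matrix(x, length(s)), alpha)
}

#' Initialize shapelets for gradient-based learning
#'
#' Either k-means centers of all sliding windows of each requested length
#' (`"kmeans_segments"`, the standard warm start) or randomly sampled
#' actual windows (`"random"`).
#'
#' @param dataset A [wtss_dataset()].
#' @param K Number of shapelets.
#' @param lengths Integer vector of shapelet lengths (recycled to `K`);
#'   every length must fit the shortest series.
#' @param method `"kmeans_segments"` or `"random"`.
#' @param seed Integer seed.
#' @param max_segments Cap on the number of windows fed to k-means per
#'   length (subsampled above this).
#' @return List of `K` numeric vectors.
#' @export
initialize_shapelets <- function(dataset, K, lengths,
                                 method = c("kmeans_segments", "random"),
                                 seed = 1L, max_segments = 5000L) {
  method <- match.arg(method)
  K <- as.integer(K)
  lengths <- rep_len(as.integer(lengths), K)
  min_len <- min(dataset_lengths(dataset))
  if (any(lengths > min_len)) {
    stop("shapelet length exceeds the shortest series (", min_len, ")",
         call. = FALSE)
  }
  with_local_seed(seed, {
    out <- vector("list", K)
    for (Lu in unique(lengths)) {
      idx <- which(lengths == Lu)
      segs <- do.call(rbind, lapply(dataset$series, function(srs) {
        P <- srs$length - Lu + 1L
        t(vapply(seq_len(P), function(p) {
          srs$values[p:(p + Lu - 1L)]
        }, numeric(Lu)))
      }))
      if (nrow(segs) > max_segments) {
        segs <- segs[sample.int(nrow(segs), max_segments), , drop = FALSE]
      }
      if (method == "kmeans_segments") {
        nu <- nrow(unique(segs))
        if (length(idx) > nu) {
          stop("more shapelets requested than distinct windows of length ",
               Lu, call. = FALSE)
        }
        centers <- if (nu == 1L) {
          segs[rep(1L, length(idx)), , drop = FALSE]
        } else {
          stats::kmeans(segs, centers = length(idx), nstart = 3L,
                        iter.max = 50L)$centers
        }
        for (q in seq_along(idx)) out[[idx[q]]] <- as.numeric(centers[q, ])
      } else {
        pick <- sample.int(nrow(segs), length(idx),
                           replace = nrow(segs) < length(idx))
        for (q in seq_along(idx)) out[[idx[q]]] <- as.numeric(segs[pick[q], ])
      }
    }
    out
  })
}

#' Learn shapelets by gradient descent
#'
#' The gradient-based comparator to wavelet discovery: `K` shapelets of
#' pre-specified lengths are treated as trainable weights. Each iteration
#' computes the soft-minimum distance matrix `M` (series x shapelets),
#' feeds it to a multinomial logistic head with L2 penalty `lambda` on the
#' linear weights, and updates both the head and the shapelet values by
#' gradient descent (full-batch by default; per-series stochastic updates
#' with `batch_size`). Stops at `max_iter` or when the relative loss change
#' stays below `tol` across a 50-iteration window.
#'
#' @param dataset A labeled [wtss_dataset()] with >= 2 classes.
#' @param K Number of shapelets.
#' @param lengths Shapelet lengths (recycled to `K`).
#' @param lambda L2 penalty on the linear weights (default 0.01).
#' @param eta Learning rate for the shapelet updates (default 0.1); the
#'   linear head uses `10 * eta`.
#' @param alpha Soft-minimum sharpness (negative; default -30).
#' @param max_iter Iteration cap (default 300).
#' @param seed Integer seed (initialization and batch order).
#' @param init `"kmeans_segments"` or `"random"` (see
#'   [initialize_shapelets()]).
#' @param batch_size `NULL` for full-batch gradient descent, or a positive
#'   integer for stochastic minibatches.
#' @param tol Relative loss-change tolerance (default 1e-6).
#' @return A `wtss_learned_model`: `shapelets`, `weights`, `bias`,
#'   `classes`, `alpha`, `loss_trace`, plus the hyperparameters.
#' @export
learn_shapelets <- function(dataset, K, lengths, lambda = 0.01, eta = 0.1,
                            alpha = -30, max_iter = 300L, seed = 1L,
                            init = "kmeans_segments", batch_size = NULL,
                            tol = 1e-6) {
  stopifnot(inherits(dataset, "wtss_dataset"))
  if (alpha >= 0) stop("alpha must be negative", call. = FALSE)
  y <- factor(dataset_labels(dataset))
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  n <- dataset$n
  C <- nlevels(y)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  shapelets <- initialize_shapelets(dataset, K, lengths, method = init,
                                    seed = seed)
  K <- length(shapelets)
  xs <- lapply(dataset$series, `[[`, "values")
  # window matrices per (series, shapelet length), built once
  ulen <- unique(lengths(shapelets))
  wincache <- lapply(xs, function(x) {
    out <- lapply(ulen, function(Lu) window_matrix(x, Lu))
    names(out) <- as.character(ulen)
    out
  })
  W <- matrix(0, K, C)   # linear weights on M
  b <- rep(0, C)
  eta_w <- 10 * eta
  loss_trace <- numeric(0)
  with_local_seed(seed, {
    for (iter in seq_len(max_iter)) {
      batches <- if (is.null(batch_size)) {
        list(seq_len(n))
      } else {
        split(sample.int(n), ceiling(seq_len(n) / batch_size))
      }
      iter_loss <- 0
      for (batch in batches) {
        nb <- length(batch)
        M <- matrix(0, nb, K)
        smd <- vector("list", nb)
        for (ii in seq_along(batch)) {
          i <- batch[ii]
          smd_i <- vector("list", K)
          for (k in seq_len(K)) {
            s <- shapelets[[k]]
            wc <- wincache[[i]][[as.character(length(s))]]
            core <- soft_min_core(s, wc, alpha)
            M[ii, k] <- core$value
            smd_i[[k]] <- core$grad
          }
          smd[[ii]] <- smd_i
        }
        # multinomial logistic forward/backward on the batch (mean loss)
        Z <- sweep(M %*% W, 2L, b, `+`)
        Z <- Z - apply(Z, 1L, max)
        P <- exp(Z)
        P <- P / rowSums(P)
        Yb <- Y[batch, , drop = FALSE]
        iter_loss <- iter_loss -
          sum(Yb * log(pmax(P, 1e-300))) / n +
          (nb / n) * (lambda / 2) * sum(W^2)
        dZ <- (P - Yb) / nb
        gW <- t(M) %*% dZ + (lambda * nb / n) * W
        gb <- colSums(dZ)
        dM <- dZ %*% t(W)           # nb x K
        for (k in seq_len(K)) {
          g <- numeric(length(shapelets[[k]]))
          for (ii in seq_along(batch)) {
            # loss gradient chains linearly through the soft-min gradient
            g <- g + dM[ii, k] * smd[[ii]][[k]]
          }
          shapelets[[k]] <- shapelets[[k]] - eta * g
        }
        W <- W - eta_w * gW
        b <- b - eta_w * gb
      }
      if (!is.finite(iter_loss)) {
        stop("training diverged (non-finite loss); reduce eta",
             call. = FALSE)
      }
      loss_trace <- c(loss_trace, iter_loss)
      if (iter > 50L) {
        prev <- loss_trace[iter - 50L]
        if (abs(prev - iter_loss) <= tol * max(abs(prev), 1e-12)) break
      }
    }
  })
  structure(
    list(shapelets = shapelets, weights = W, bias = b, classes = levels(y),
         alpha = alpha, lambda = lambda, eta = eta, seed = seed,
         lengths = lengths, loss_trace = loss_trace),
    class = "wtss_learned_model"
  )
}

#' @export
print.wtss_learned_model <- function(x, ...) {
  cat(sprintf(
    "<wtss_learned_model> %d shapelets (lengths %s), classes={%s}, %d iters\n",
    length(x$shapelets), paste(unique(lengths(x$shapelets)), collapse = ","),
    paste(x$classes, collapse = ","), length(x$loss_trace)))
  invisible(x)
}

#' Soft-minimum distance features of a learned model
#'
#' @param model A `wtss_learned_model`.
#' @param dataset A [wtss_dataset()].
#' @return Matrix (series x shapelets) of soft-minimum distances.
#' @export
learned_features <- function(model, dataset) {
  xs <- lapply(dataset$series, `[[`, "values")
  M <- matrix(0, length(xs), length(model$shapelets),
              dimnames = list(names(dataset$series),
                              seq_along(model$shapelets) - 1L))
  for (i in seq_along(xs)) {
    for (k in seq_along(model$shapelets)) {
      M[i, k] <- soft_min_distance(model$shapelets[[k]], xs[[i]],
                                   model$alpha)
    }
  }
  M
}

#' Predict classes from a learned-shapelet model
#'
#' @param object A `wtss_learned_model`.
#' @param newdata A [wtss_dataset()].
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Character labels or a probability matrix.
#' @export
predict.wtss_learned_model <- function(object, newdata,
                                       type = c("class", "prob"), ...) {
  type <- match.arg(type)
  M <- learned_features(object, newdata)
  Z <- sweep(M %*% object$weights, 2L, object$bias, `+`)
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z)
  P <- P / rowSums(P)
  colnames(P) <- object$classes
  if (type == "class") {
    object$classes[max.col(P, ties.method = "first")]
  } else {
    P
  }
}
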