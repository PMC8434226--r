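test_that("soft minimum converges to the hard minimum and bounds hold", {
  set.seed(51)
  s <- stats::rnorm(6)
  x <- stats::rnorm(30)
  # hard minimum of the same per-window distance (normalized squared)
  hard <- min_distance(s, x, normalize_by_length = TRUE)^2
  expect_equal(soft_min_distance(s, x, alpha = -1e6), hard,
               tolerance = 1e-6)
  # monotone approach to the hard min as alpha decreases
  alphas <- c(-1, -5, -25, -125)
  vals <- vapply(alphas, function(a) soft_min_distance(s, x, a), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(vals >= hard - 1e-12))
  # bounded by the max window distance
  dmax <- max(vapply(1:(length(x) - 5), function(p) {
    mean((x[p:(p + 5)] - s)^2)
  }, numeric(1)))
  expect_true(all(vals <= dmax + 1e-12))
  # single admissible window: equals that distance for any alpha
  y <- stats::rnorm(6)
  expect_equal(soft_min_distance(s, y, alpha = -0.5), mean((y - s)^2),
               tolerance = 1e-12)
  expect_error(soft_min_distance(s, x, alpha = 0.5), "negative")
})

test_that("the analytic soft-min gradient matches central differences", {
  set.seed(53)
  for (rep in 1:10) {
    L <- sample(3:8, 1)
    s <- stats::rnorm(L)
    x <- stats::rnorm(sample((L + 2):30, 1))
    alpha <- -stats::runif(1, 1, 20)
    g <- soft_min_grad(s, x, alpha)
    expect_equal(g$value, soft_min_distance(s, x, alpha), tolerance = 1e-12)
    h <- 1e-6
    fd <- vapply(seq_len(L), function(j) {
      sp <- s; sm <- s
      sp[j] <- sp[j] + h
      sm[j] <- sm[j] - h
      (soft_min_distance(sp, x, alpha) -
         soft_min_distance(sm, x, alpha)) / (2 * h)
    }, numeric(1))
    expect_equal(g$grad, fd, tolerance = 1e-5)
  }
})

test_that("initialization is reproducible and respects the data", {
  d <- random_dataset(n = 4, len_range = c(20, 25), seed = 61)
  s1 <- initialize_shapelets(d, K = 3, lengths = c(5, 5, 8),
                             method = "random", seed = 9)
  s2 <- initialize_shapelets(d, K = 3, lengths = c(5, 5, 8),
                             method = "random", seed = 9)
  expect_identical(s1, s2)
  expect_equal(lengths(s1), c(5L, 5L, 8L))
  # constant series: segment k-means centers are constant
  dc <- wtss_dataset(list(wtss_series("c", rep(2, 30), "1")))
  sc <- initialize_shapelets(dc, K = 1, lengths = 6,
                             method = "kmeans_segments", seed = 1)
  expect_equal(sc[[1L]], rep(2, 6))
  # centers equal an independently computed segment k-means
  set.seed(71)
  dd <- wtss_dataset(list(wtss_series("a", stats::rnorm(15), "1")))
  got <- initialize_shapelets(dd, K = 2, lengths = 4,
                              method = "kmeans_segments", seed = 5)
  segs <- t(vapply(1:12, function(p) {
    dd$series[[1L]]$values[p:(p + 3)]
  }, numeric(4)))
  ref <- wtss:::with_local_seed(5, {
    stats::kmeans(segs, centers = 2, nstart = 3L, iter.max = 50L)$centers
  })
  expect_equal(do.call(rbind, got), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(initialize_shapelets(d, K = 1, lengths = 100),
               "shortest series")
})

test_that("zero learning rate leaves shapelets at initialization", {
  g <- generate_trace_like(n_per_class = 4, seed = 73)
  init <- initialize_shapelets(g$dataset, K = 4, lengths = c(25, 50),
                               method = "kmeans_segments", seed = 11)
  m <- learn_shapelets(g$dataset, K = 4, lengths = c(25, 50), eta = 0,
                       max_iter = 5, seed = 11)
  expect_equal(m$shapelets, init, tolerance = 1e-12)
})

test_that("full-batch training decreases the loss monotonically", {
  g <- generate_trace_like(n_per_class = 3, length = 80, jitter = 5,
                           pattern_length = 20, seed = 79)
  m <- learn_shapelets(g$dataset, K = 2, lengths = c(10, 15), eta = 0.005,
                       max_iter = 40, seed = 3)
  expect_true(all(diff(m$loss_trace) <= 1e-8))
  # reproducibility under the seed
  m2 <- learn_shapelets(g$dataset, K = 2, lengths = c(10, 15), eta = 0.005,
                        max_iter = 40, seed = 3)
  expect_identical(m2$shapelets, m$shapelets)
  expect_identical(m2$loss_trace, m$loss_trace)
})

test_that("learned shapelets classify four-class pattern data", {
  tr <- generate_trace_like(n_per_class = 15, seed = 83)
  te <- generate_trace_like(n_per_class = 15, seed = 84)
  m <- learn_shapelets(tr$dataset, K = 8,
                       lengths = c(rep(25, 4), rep(50, 4)),
                       eta = 0.2, max_iter = 200, seed = 3)
  truth <- vapply(te$dataset$series, `[[`, character(1), "label")
  acc <- mean(predict(m, te$dataset) == truth)
  expect_gte(acc, 0.9)
  # serialization round-trip: features through the same linear head
  # reproduce the stored predictions
  M <- learned_features(m, te$dataset)
  Z <- sweep(M %*% m$weights, 2, m$bias, `+`)
  pred2 <- m$classes[max.col(Z, ties.method = "first")]
  expect_identical(pred2, unname(predict(m, te$dataset)))
})
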