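# a pool object built directly from known sequences, for reduction tests
make_pool <- function(seqs, labels = rep("1", length(seqs))) {
  cands <- lapply(seq_along(seqs), function(i) {
    list(values = seqs[[i]], source_id = paste0("s", i), start = 0L,
         length = length(seqs[[i]]), scale = 8, label = labels[i],
         boundary_flag = FALSE)
  })
  structure(list(candidates = cands,
                 provenance = list(scales = 8, tau = 1, min_length = 3)),
            class = "wtss_pool")
}

test_that("variance filter keeps the top-k anchored in the minority class", {
  seqs <- list(A = c(0, 2, 0, 2), B = c(0, 1, 0, 1), C = c(0, 0.2, 0, 0.2))
  pool <- make_pool(unname(seqs))
  out <- variance_filter(pool, retain_k_minority = 2)
  expect_length(out$shapelets, 2L)
  # named 0..m-1 by descending variance
  expect_equal(names(out$shapelets), c("0", "1"))
  expect_equal(out$shapelets[["0"]], seqs$A)
  expect_equal(out$shapelets[["1"]], seqs$B)

  # two classes: threshold from the minority, applied everywhere
  set.seed(11)
  seqs2 <- lapply(1:12, function(i) stats::rnorm(6, sd = i / 4))
  labs <- c(rep("maj", 9), rep("min", 3))
  pool2 <- make_pool(seqs2, labs)
  out2 <- variance_filter(pool2, retain_k_minority = 2)
  vars <- vapply(seqs2, stats::var, numeric(1))
  thr <- sort(vars[labs == "min"], decreasing = TRUE)[2L]
  expect_setequal(out2$info$variance, vars[vars >= thr])
  # brute-force sort-and-threshold oracle on the retained set size
  expect_equal(length(out2$shapelets), sum(vars >= thr))

  # lower retain-k gives a subset of a higher retain-k
  out3 <- variance_filter(pool2, retain_k_minority = 3)
  expect_true(all(out2$info$variance %in% out3$info$variance))
  expect_error(variance_filter(pool2, retain_k_minority = 4,
                               minority_class = "min"), "exceeds")
  expect_error(variance_filter(pool2, retain_k_minority = 1,
                               minority_class = "absent"), "absent")
})

test_that("constant candidates are always filtered out", {
  pool <- make_pool(list(c(1, 1, 1, 1), c(0, 5, 0, 5)))
  out <- variance_filter(pool, retain_k_minority = 1)
  expect_length(out$shapelets, 1L)
  expect_equal(out$shapelets[["0"]], c(0, 5, 0, 5))
})

test_that("alignment kernel matches exhaustive path enumeration", {
  set.seed(17)
  for (i in 1:20) {
    x <- stats::rnorm(sample(2:3, 1))
    y <- stats::rnorm(sample(2:3, 1))
    sigma <- stats::runif(1, 0.5, 2)
    expect_equal(gak(x, y, sigma), oracle_gak(x, y, sigma),
                 tolerance = 1e-10)
  }
  # symmetry and normalized self-similarity
  x <- stats::rnorm(7)
  y <- stats::rnorm(5)
  expect_equal(gak(x, y, 1), gak(y, x, 1), tolerance = 1e-12)
  expect_equal(gak(x, x, 1, normalize = TRUE), 1, tolerance = 1e-12)
  # long dissimilar sequences stay finite via the log domain
  expect_true(is.finite(gak(stats::rnorm(200), stats::rnorm(180) + 50,
                            0.5, log = TRUE)))
})

test_that("the GAK Gram matrix is symmetric positive semidefinite", {
  set.seed(23)
  seqs <- lapply(1:12, function(i) stats::rnorm(sample(5:15, 1)))
  K <- wtss:::.gak_gram_cpp(seqs, 1.5, TRUE)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_true(all(diag(K) == 1))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("kernel k-means is reproducible with non-increasing inertia", {
  set.seed(31)
  seqs <- c(lapply(1:6, function(i) stats::rnorm(10, mean = 0)),
            lapply(1:6, function(i) stats::rnorm(10, mean = 6)))
  pool <- make_pool(seqs)
  km1 <- gak_kernel_kmeans(pool, k = 2, seed = 7, n_init = 3)
  km2 <- gak_kernel_kmeans(pool, k = 2, seed = 7, n_init = 3)
  expect_identical(km1$assignments, km2$assignments)
  expect_identical(km1$inertia, km2$inertia)
  # inertia trace of the winning run never increases
  expect_true(all(diff(km1$inertia_trace) <= 1e-10))
  expect_equal(km1$inertia, min(km1$inertia_trace))
  # the two planted groups are separated
  expect_equal(length(unique(km1$assignments[1:6])), 1L)
  expect_equal(length(unique(km1$assignments[7:12])), 1L)
  expect_false(km1$assignments[1] == km1$assignments[7])

  # degenerate k
  km_all <- gak_kernel_kmeans(pool, k = 1, seed = 1, n_init = 1)
  expect_equal(length(unique(km_all$assignments)), 1L)
  km_single <- gak_kernel_kmeans(pool, k = 12, seed = 1, n_init = 1)
  expect_equal(sort(unique(km_single$assignments)), 1:12)
  expect_error(gak_kernel_kmeans(pool, k = 13, seed = 1), "pool size")
})

test_that("center-lines average members resampled to the target length", {
  # identical members reproduce themselves
  pool <- make_pool(list(c(1, 2, 3), c(1, 2, 3)))
  cl <- cluster_centerlines(pool, c(1L, 1L))
  expect_equal(cl$shapelets[[1L]], c(1, 2, 3))
  # pointwise mean
  pool2 <- make_pool(list(c(0, 0, 0), c(2, 2, 2)))
  cl2 <- cluster_centerlines(pool2, c(1L, 1L))
  expect_equal(cl2$shapelets[[1L]], c(1, 1, 1))
  # singleton cluster returns the member
  pool3 <- make_pool(list(c(5, 6, 7, 8), c(0, 1, 0)))
  cl3 <- cluster_centerlines(pool3, c(1L, 2L))
  vals <- unname(lapply(cl3$shapelets, identity))
  expect_true(any(vapply(vals, identical, logical(1), y = c(5, 6, 7, 8))))
  # mixed lengths: resample-then-average oracle at the median length
  a <- c(0, 1, 2, 3)
  b <- c(1, 3, 5)      # median member length of {4, 3} -> round(3.5) = 4
  pool4 <- make_pool(list(a, b))
  cl4 <- cluster_centerlines(pool4, c(1L, 1L))
  b_res <- stats::approx(seq_along(b), b, xout = seq(1, 3, length.out = 4))$y
  expect_equal(cl4$shapelets[[1L]], (a + b_res) / 2, tolerance = 1e-12)
})

test_that("shapelet sets round-trip through JSON", {
  set.seed(41)
  ss <- shapelet_set(lapply(1:4, function(i) stats::rnorm(5 + i)),
                     origin = "filtered_candidate")
  path <- withr::local_tempfile(fileext = ".json")
  write_shapelets_json(ss, path)
  ss2 <- read_shapelets_json(path)
  expect_equal(ss2$shapelets, ss$shapelets, tolerance = 1e-12)
  expect_equal(ss2$origin, ss$origin)
})
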