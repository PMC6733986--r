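test_that("log-cpm normalization matches its closed form and inverts", {
  m <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  out <- normalize_log_cpm(m)
  expect_equal(unname(out[, 1]), c(log2(1e6 + 1), 0))

  counts <- random_counts(50, 20)
  out <- normalize_log_cpm(counts, pseudocount = 1)
  oracle <- log2(t(t(counts) / colSums(counts)) * 1e6 + 1)
  expect_equal(out, oracle, tolerance = 1e-12)
  ## inverse check: proportions recovered from 2^x - pseudocount
  back <- 2^out - 1
  prop <- t(t(back) / colSums(back))
  expect_equal(prop, t(t(counts) / colSums(counts)), tolerance = 1e-12)

  zero <- counts
  zero[, 3] <- 0L
  expect_error(normalize_log_cpm(zero), "c003")
})

test_that("diffusion operator matches a dense brute-force construction", {
  blobs <- make_blobs(n_per = 5, k = 2, d = 2, sep = 3, seed = 1)
  x <- blobs$x
  k <- 4; ka <- 2
  op <- build_diffusion_operator(x, k, ka)
  expect_true(all(abs(Matrix::rowSums(op$matrix) - 1) < 1e-10))

  ## dense oracle: all-pairs distances, kNN mask (self included, affinity 1),
  ## adaptive kernel, symmetrize, row-normalize
  n <- nrow(x)
  d <- as.matrix(dist(x))
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ])
    nn <- nn[nn != i][1:k]
    sigma <- d[i, nn[ka]]
    a[i, nn] <- exp(-(d[i, nn] / sigma)^2)
    a[i, i] <- 1
  }
  a <- (a + t(a)) / 2
  m <- a / rowSums(a)
  expect_lt(max(abs(as.matrix(op$matrix) - m)), 1e-10)
})

test_that("well-separated clusters yield a block-structured Markov matrix", {
  blobs <- make_blobs(n_per = 50, k = 2, d = 3, sep = 40, sd = 0.5, seed = 2)
  op <- build_diffusion_operator(blobs$x, 10, 5)
  m <- as.matrix(op$matrix)
  across <- m[blobs$labels == 1, blobs$labels == 2]
  expect_lt(max(across), 1e-6)
})

test_that("operator construction rejects invalid neighborhood sizes", {
  x <- make_blobs(n_per = 5, k = 2, d = 2)$x
  expect_error(build_diffusion_operator(x, k_neighbors = 10, ka_adaptive = 2),
               "smaller")
  expect_error(build_diffusion_operator(x, k_neighbors = 4, ka_adaptive = 5),
               "ka_adaptive")
})

test_that("imputation is the identity at t = 0 and averages at t = 1", {
  expr <- matrix(rnorm(30), 3, 10,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:10)))
  op <- build_diffusion_operator(matrix(rnorm(20), 10, 2,
                                        dimnames = list(colnames(expr),
                                                        NULL)), 3, 2)
  expect_identical(impute_expression(expr, op, 0), expr)
  expect_error(impute_expression(expr, op, -1), "non-negative")

  ## 3-cell chain with a hand-written Markov matrix
  m <- rbind(c(0.5, 0.5, 0), c(0.25, 0.5, 0.25), c(0, 0.5, 0.5))
  op3 <- structure(list(matrix = Matrix::Matrix(m),
                        k_neighbors = 2, ka_adaptive = 1),
                   class = "diffusion_operator")
  e3 <- matrix(c(1, 2, 4), 1, 3,
               dimnames = list("g", c("a", "b", "c")))
  out <- impute_expression(e3, op3, 1)
  expect_equal(unname(out[1, ]),
               c(0.5 * 1 + 0.5 * 2, 0.25 * 1 + 0.5 * 2 + 0.25 * 4,
                 0.5 * 2 + 0.5 * 4))
})

test_that("repeated diffusion contracts cells towards a common profile", {
  blobs <- make_blobs(n_per = 20, k = 1, d = 3, sep = 0, seed = 3)
  expr <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(paste0("g", 1:5), rownames(blobs$x)))
  op <- build_diffusion_operator(blobs$x, 8, 4)
  spread <- sapply(c(1, 2, 4, 8), function(t)
    mean(apply(impute_expression(expr, op, t), 1, stats::sd)))
  expect_true(all(diff(spread) < 0))
  far <- impute_expression(expr, op, 256)
  expect_lt(mean(apply(far, 1, stats::sd)), 0.05 * mean(apply(expr, 1, sd)))
  expect_true(all(impute_expression(abs(expr), op, 4) >= 0))
})

test_that("approximate spectral clustering recovers separated blobs exactly", {
  blobs <- make_blobs(n_per = 40, k = 4, d = 5, sep = 10, sd = 1, seed = 4)
  st <- approx_spectral_cluster(blobs$x, K = 4, m_representatives = 40,
                                seed = 1)
  expect_same_partition(st$labels, blobs$labels)
  expect_true(all(st$labels %in% 1:4))
  ## stage 1 lies lowest on the first embedding axis
  means <- tapply(blobs$x[, 1], st$labels, mean)
  expect_true(all(diff(means) > 0))
})

test_that("m = n reduces to plain normalized spectral clustering", {
  blobs <- make_blobs(n_per = 25, k = 3, d = 4, sep = 6, sd = 1, seed = 5)
  x <- blobs$x
  st <- approx_spectral_cluster(x, K = 3, m_representatives = nrow(x),
                                seed = 9)
  ## oracle: dense normalized spectral clustering of all cells, same seed
  d <- as.matrix(dist(x))
  sigma <- stats::median(d[upper.tri(d)])
  w <- exp(-d^2 / (2 * sigma^2))
  dg <- rowSums(w)
  s <- w / sqrt(dg %o% dg)
  u <- eigen((s + t(s)) / 2, symmetric = TRUE)$vectors[, 1:3]
  u <- u / sqrt(rowSums(u^2))
  km <- with_seed(substream_seed(9, "spectral"),
                  stats::kmeans(u, 3, nstart = 10L, iter.max = 100L))
  expect_same_partition(st$labels, km$cluster)
})

test_that("cell order permutation leaves the partition invariant", {
  blobs <- make_blobs(n_per = 30, k = 3, d = 4, sep = 12, sd = 1, seed = 6)
  st1 <- approx_spectral_cluster(blobs$x, 3, 50, seed = 1)
  perm <- withr::with_seed(1, sample(nrow(blobs$x)))
  st2 <- approx_spectral_cluster(blobs$x[perm, ], 3, 50, seed = 1)
  expect_same_partition(st1$labels[rownames(blobs$x)[perm]], st2$labels)
})

test_that("outlier removal flags exactly the planted outlier", {
  withr::with_seed(8, {
    x <- matrix(rnorm(100 * 2, sd = 0.1), 100, 2)
  })
  x[100, ] <- c(50, 50)
  rownames(x) <- sprintf("c%03d", 1:100)
  st <- structure(list(labels = stats::setNames(rep(1L, 100), rownames(x)),
                       K = 1L), class = "stage_assignment")
  keep <- remove_outliers(x, st, c_mad = 3)
  expect_identical(unname(which(!keep)), 100L)

  ## identical coordinates: MAD 0, strict inequality removes nothing
  y <- matrix(1, 20, 2, dimnames = list(sprintf("c%02d", 1:20), NULL))
  st2 <- structure(list(labels = stats::setNames(rep(1L, 20), rownames(y)),
                        K = 1L), class = "stage_assignment")
  expect_true(all(remove_outliers(y, st2, 3)))
  ## infinite multiplier removes nothing
  expect_true(all(remove_outliers(x, st, c_mad = Inf)))
})

test_that("stage profiles match a brute-force group-by oracle", {
  counts <- random_counts(30, 40, seed = 21)
  cpm <- sweep(counts, 2, 1e6 / colSums(counts), `*`)
  labels <- stats::setNames(rep(1:4, each = 10), colnames(counts))
  prof <- stage_profile(cpm, labels)
  oracle <- sapply(1:4, function(s)
    log2(rowMeans(cpm[, labels == s]) + 1))
  expect_equal(unname(prof$mean_expr), unname(oracle), tolerance = 1e-12)
  z <- (oracle - rowMeans(oracle)) / apply(oracle, 1, stats::sd)
  expect_equal(unname(unclass(prof$normalized))[, ], z,
               ignore_attr = TRUE, tolerance = 1e-12)

  ## closed form for two stages at 4 and 16 cpm
  m2 <- matrix(c(4, 4, 16, 16), 1, 4,
               dimnames = list("g", paste0("c", 1:4)))
  lab2 <- stats::setNames(c(1L, 1L, 2L, 2L), colnames(m2))
  p2 <- stage_profile(m2, lab2)
  expect_equal(unname(diff(p2$mean_expr[1, ])), log2(17) - log2(5))

  ## constant gene: all-zero normalized row, flagged
  m3 <- rbind(g1 = rep(5, 4), g2 = c(1, 2, 3, 4))
  colnames(m3) <- paste0("c", 1:4)
  p3 <- stage_profile(m3, stats::setNames(c(1L, 1L, 2L, 2L), colnames(m3)))
  expect_true(all(p3$normalized["g1", ] == 0))
  expect_true("g1" %in% p3$constant)

  expect_error(stage_profile(cpm, labels, stage_subset = c(1, 9)), "empty")
})
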