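test_that("scrubbing exclusion is strict at the boundary", {
  expect_equal(scrub_check(31), "exclude")
  expect_equal(scrub_check(30), "include")
  expect_equal(scrub_check(0), "include")
  expect_equal(scrub_check(c(0, 30, 31, 100)),
               c("include", "include", "exclude", "exclude"))
  expect_error(scrub_check(-1), "non-negative")
})

test_that("prewhitening leaves white noise essentially untouched", {
  set.seed(1)
  ts <- matrix(rnorm(200 * 10), 200, 10)
  out <- prewhiten(ts, max_order = 5)
  orders <- attr(out, "ar_orders")
  expect_true(mean(orders == 0) >= 0.6)
  zero <- which(orders == 0)
  expect_equal(out[, zero], scale(ts[, zero], scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("prewhitening removes AR(1) autocorrelation", {
  set.seed(2)
  acfs <- replicate(10, {
    x <- as.numeric(arima.sim(list(ar = 0.8), 300))
    out <- prewhiten(cbind(x), max_order = 5)
    acf(out[, 1], plot = FALSE, lag.max = 1)$acf[2]
  })
  expect_lt(mean(abs(acfs)), 0.1)
})

test_that("prewhitening rejects constant series by node index", {
  ts <- cbind(rnorm(50), rep(1, 50))
  expect_error(prewhiten(ts), "node\\(s\\): 2")
})

test_that("pearson_matrix matches hand cases and the textbook formula", {
  set.seed(3)
  x <- rnorm(30)
  ts <- cbind(a = x, b = x, c = -x + 0, d = rnorm(30))
  C <- pearson_matrix(ts)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_true(isSymmetric(C))

  m <- matrix(rnorm(20 * 5), 20, 5)
  C2 <- pearson_matrix(m)
  for (i in 1:5) for (j in 1:5) {
    num <- sum((m[, i] - mean(m[, i])) * (m[, j] - mean(m[, j])))
    den <- sqrt(sum((m[, i] - mean(m[, i]))^2) * sum((m[, j] - mean(m[, j]))^2))
    expect_equal(C2[i, j], num / den, tolerance = 1e-12)
  }
  expect_error(pearson_matrix(cbind(rnorm(20), rep(0, 20))), "zero-variance")
})

test_that("pearson_matrix is invariant to positive affine transforms", {
  set.seed(4)
  m <- matrix(rnorm(40 * 6), 40, 6)
  m2 <- sweep(sweep(m, 2, runif(6, 0.5, 3), "*"), 2, rnorm(6), "+")
  expect_equal(pearson_matrix(m), pearson_matrix(m2), tolerance = 1e-12)
})

test_that("proportional threshold retains the exact edge budget", {
  # 5 nodes, 10 possible edges, 20% -> exactly 2
  M <- random_symmetric(5, seed = 5)
  A <- proportional_threshold(M, 0.2)
  expect_equal(sum(A) / 2, 2)
  expect_equal(attr(A, "n_edges"), 2)

  # full density gives the complete graph
  Afull <- proportional_threshold(M, 1)
  expect_equal(sum(Afull) / 2, 10)

  # symmetry and zero diagonal always
  expect_true(isSymmetric(A))
  expect_equal(diag(A), rep(0, 5))
  expect_error(proportional_threshold(M, 0), "density")
  expect_error(proportional_threshold(M, 1.2), "density")
})

test_that("thresholding is monotone in density and deterministic under ties", {
  set.seed(6)
  for (rep in 1:5) {
    M <- random_symmetric(12)
    A1 <- proportional_threshold(M, 0.2)
    A2 <- proportional_threshold(M, 0.5)
    expect_true(all(A2[A1 == 1] == 1))  # nesting
  }
  # exact ties at the cutoff resolved by (i, j) order, reproducibly
  M <- matrix(0.5, 4, 4); diag(M) <- 1
  A <- proportional_threshold(M, 0.5)   # 3 of 6 identical edges
  B <- proportional_threshold(M, 0.5)
  expect_identical(A, B)
  expect_equal(sum(A) / 2, 3)
  expect_equal(A[1, 2] + A[1, 3] + A[1, 4], 3)  # lexicographically first
  expect_equal(attr(A, "n_ties_at_cutoff"), 3L)
})

test_that("absolute ranking mode keeps strong negatives", {
  M <- diag(3)
  M[1, 2] <- M[2, 1] <- -0.9
  M[1, 3] <- M[3, 1] <- 0.5
  M[2, 3] <- M[3, 2] <- 0.1
  signed <- proportional_threshold(M, 1 / 3, mode = "signed")
  absm <- proportional_threshold(M, 1 / 3, mode = "absolute")
  expect_equal(signed[1, 3], 1)
  expect_equal(absm[1, 2], 1)
})

test_that("group averaging matches the elementwise mean", {
  set.seed(7)
  ms <- lapply(1:3, function(i) random_symmetric(6))
  avg <- group_average(ms)
  expect_equal(avg, (ms[[1]] + ms[[2]] + ms[[3]]) / 3, tolerance = 1e-12)
  expect_equal(group_average(ms[1]), ms[[1]])
  expect_equal(group_average(list(ms[[1]], -ms[[1]])),
               matrix(0, 6, 6), ignore_attr = TRUE)
  expect_error(group_average(list()), "non-empty")
  expect_error(group_average(list(random_symmetric(3), random_symmetric(4))))
})

test_that("null prewhiten+pearson pipeline has centred off-diagonals", {
  set.seed(8)
  offdiag <- replicate(10, {
    ts <- matrix(rnorm(120 * 8), 120, 8)
    C <- pearson_matrix(prewhiten(ts, 3))
    mean(C[upper.tri(C)])
  })
  expect_lt(abs(mean(offdiag)), 0.02)
})
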