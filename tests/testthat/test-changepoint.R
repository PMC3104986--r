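test_that("critical values reproduce the classical Kolmogorov constants", {
  expect_equal(kolmogorov_critical(0.05), 1.358, tolerance = 5e-4)
  expect_equal(kolmogorov_critical(0.01), 1.628, tolerance = 5e-4)
  expect_error(kolmogorov_critical(0), "strictly in")
})

test_that("scan equals the exhaustive (r, y) brute-force enumeration", {
  set.seed(202)
  for (rep in 1:25) {
    n1 <- sample(4:10, 1)
    n2 <- sample(4:10, 1)
    g <- sample(10:25, 1)
    xn <- rnorm(n1)
    xc <- rnorm(n2) + sample(c(-2, 0, 2), 1)
    fit <- npcps_test(xn, xc, grid_size = g)
    ora <- oracle_npcps(xn, xc, grid_size = g)
    expect_identical(fit$statistic, ora$D)
    expect_identical(fit$change_point, ora$r)
  }
})

test_that("a cancer group copying the normals gives a near-zero tail deviation", {
  set.seed(3)
  xn <- rnorm(12)
  fit <- npcps_test(xn, xn)
  n1 <- length(xn)
  # at r = n1 the tail ECDF equals the reference within one grid step
  d_at_n1 <- fit$profile$D[fit$profile$r == n1]
  expect_lt(abs(d_at_n1), 1 / sqrt(n1))
})

test_that("upward-shifted cancer samples give a negative (over-expression) statistic", {
  fit <- npcps_test(1:5, c(2, 3, 100, 101), alpha = 0.05)
  expect_lt(fit$statistic, 0)
  ora <- oracle_npcps(1:5, c(2, 3, 100, 101))
  expect_identical(fit$statistic, ora$D)
  expect_identical(fit$change_point, ora$r)
  set.seed(11)
  strong <- npcps_test(rnorm(25), rnorm(25) + 5, alpha = 0.01)
  expect_true(strong$reject)
  expect_identical(strong$direction, "over")
})

test_that("the statistic is invariant under strictly increasing transforms", {
  set.seed(303)
  for (rep in 1:15) {
    xn <- rnorm(15)
    xc <- rnorm(12) + sample(c(-1, 0, 2), 1)
    ref <- npcps_test(xn, xc)
    for (f in list(exp, function(v) 3.7 * v - 11)) {
      tr <- npcps_test(f(xn), f(xc))
      expect_identical(tr$statistic, ref$statistic)
      expect_identical(tr$change_point, ref$change_point)
      expect_identical(tr$tau_hat, ref$tau_hat)
    }
  }
})

test_that("negating the data flips the sign of the statistic exactly", {
  set.seed(404)
  for (rep in 1:25) {
    n1 <- sample(5:20, 1)
    xn <- rnorm(n1)
    xc <- rnorm(sample(5:20, 1)) + sample(c(-2, 0, 2), 1)
    a <- npcps_test(xn, xc)
    b <- npcps_test(-xn, -xc)
    expect_equal(b$statistic, -a$statistic, tolerance = 1e-12)
  }
})

test_that("true change fraction matches the simulated design over the whole k grid", {
  ks <- c(1, 3, 5, 7, 9, 12, 15, 20, 25)
  expect_equal(
    vapply(ks, function(k) true_change_fraction(25, 25, k), numeric(1)),
    c(0.98, 0.94, 0.90, 0.86, 0.82, 0.76, 0.70, 0.60, 0.50)
  )
  expect_error(true_change_fraction(25, 25, 50), "0 < k <= n2")
  expect_error(true_change_fraction(25, 25, 0), "0 < k <= n2")
})

test_that("matrix scan equals the row-wise test and ranks the dominant gene first", {
  set.seed(505)
  sim <- simulate_matrix(genes = 15, n1 = 10, n2 = 10, k = 0, mu = 0, seed = 9)
  x <- sim$x
  x[7, sim$cancer] <- x[7, sim$cancer] + 10  # dominant over-expressed gene
  res <- npcps_matrix(x, sim$normal, sim$cancer, alpha = 0.01)

  for (i in c(1, 7, 15)) {
    fit <- npcps_test(x[i, sim$normal], x[i, sim$cancer], alpha = 0.01)
    row <- res[res$gene_id == rownames(x)[i], ]
    expect_equal(row$D_n, fit$statistic)
    expect_equal(row$cp_index, fit$change_point)
    expect_equal(row$cp_fraction, fit$tau_hat)
  }
  expect_identical(res$gene_id[which.max(abs(res$D_n))], rownames(x)[7])

  # ranking is by descending signed statistic, ties by gene id
  expect_identical(res$D_n, sort(res$D_n, decreasing = TRUE))
  expect_identical(res$rank, seq_len(nrow(res)))

  smry <- attr(res, "summary")
  expect_identical(smry$positive + smry$negative,
                   sum(res$D_n != 0))
})

test_that("genes with missing values are skipped with a warning", {
  set.seed(6)
  sim <- simulate_matrix(genes = 6, n1 = 8, n2 = 8, k = 0, mu = 0, seed = 2)
  x <- sim$x
  x[3, 2] <- NA
  expect_warning(res <- npcps_matrix(x, sim$normal, sim$cancer), "skipped 1")
  expect_identical(nrow(res), 5L)
  expect_identical(attr(res, "skipped"), rownames(x)[3])
})

test_that("degenerate inputs are rejected", {
  expect_error(npcps_test(1, c(1, 2)), "at least 2")
  expect_error(npcps_test(c(1, 2), c(1, Inf)), "finite")
  expect_error(npcps_test(c(1, 2), c(1, 2), alpha = 1.5), "alpha")
})
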