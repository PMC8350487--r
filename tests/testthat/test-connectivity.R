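test_that("correlation_matrix matches textbook Pearson and handles identity cases", {
  set.seed(11)
  ts <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("n", 1:5)))
  r <- correlation_matrix(ts)
  expect_true(isSymmetric(r))
  expect_equal(diag(r), setNames(rep(0, 5), colnames(ts)))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(abs(r[i, j] - pearson_oracle(ts[, i], ts[, j])), 1e-12)
  }
  # identical series -> r = 1; negated series -> r = -1
  ts2 <- cbind(a = ts[, 1], b = ts[, 1], c = -ts[, 1] + 1)
  r2 <- correlation_matrix(ts2)
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], -1)
})

test_that("correlation_matrix rejects degenerate input", {
  expect_error(correlation_matrix(matrix(rnorm(4), 2, 2)), "3 timepoints")
  bad <- cbind(n1 = rnorm(10), n2 = rep(1, 10))
  expect_error(correlation_matrix(bad), "n2")
  nabad <- matrix(c(rnorm(19), NA), 10, 2)
  expect_error(correlation_matrix(nabad), "missing")
})

test_that("fisher_z is atanh with clipping and odd symmetry", {
  r <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  z <- fisher_z(r)
  expect_equal(z[1, 2], 0.549306144334055, tolerance = 1e-12)  # atanh(0.5)
  expect_equal(fisher_z(matrix(0, 3, 3)), matrix(0, 3, 3))
  set.seed(2)
  m <- matrix(runif(16, -0.9, 0.9), 4, 4); diag(m) <- 0
  expect_equal(fisher_z(-m), -fisher_z(m))
  # exact +/-1 stays finite
  ex <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_true(all(is.finite(fisher_z(ex))))
})

test_that("remove_negatives zeroes exactly the negative entries", {
  m <- matrix(c(0, -2, 3, -2, 0, -0.5, 3, -0.5, 0), 3, 3)
  out <- remove_negatives(m)
  expect_equal(sum(out == 0), sum(m < 0) + 3)  # former negatives + diagonal
  expect_equal(out[m >= 0], m[m >= 0])
  expect_equal(remove_negatives(abs(m)), abs(m))
  allneg <- -abs(m); diag(allneg) <- 0
  expect_equal(remove_negatives(allneg), matrix(0, 3, 3))
})

test_that("fdr_threshold survivor set matches a hand-run BH oracle", {
  set.seed(3)
  n_tp <- 40
  ts <- matrix(rnorm(n_tp * 21), n_tp, 21)
  # plant some strong correlations
  ts[, 2] <- ts[, 1] + rnorm(n_tp, sd = 0.3)
  ts[, 3] <- ts[, 1] + rnorm(n_tp, sd = 0.3)
  r <- correlation_matrix(ts)
  z <- remove_negatives(fisher_z(r))
  thr <- fdr_threshold(z, n_timepoints = n_tp, q = 0.005)
  expect_true(isSymmetric(thr))
  # oracle: recompute p per edge, hand BH
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- tanh(z[upper.tri(z)])
  tv <- rv * sqrt((n_tp - 2) / (1 - rv^2))
  p <- 2 * pt(-abs(tv), df = n_tp - 2)
  keep <- bh_oracle(p, 0.005)
  got_kept <- thr[upper.tri(thr)] != 0
  expect_equal(got_kept, keep & z[upper.tri(z)] != 0)
  # saturation: all-near-1 correlations all retained
  sat <- matrix(5, 4, 4); diag(sat) <- 0
  expect_equal(fdr_threshold(sat, 100) != 0, !diag(TRUE, 4))
  expect_error(fdr_threshold(sat, 3), "exceed 3")
})

test_that("sparsity after FDR is monotone non-increasing in q", {
  set.seed(4)
  ts <- matrix(rnorm(30 * 15), 30, 15)
  z <- remove_negatives(fisher_z(correlation_matrix(ts)))
  nz <- sapply(c(0.5, 0.1, 0.01, 0.001), function(q)
    sum(fdr_threshold(z, 30, q) != 0))
  expect_true(all(diff(nz) <= 0))
})

test_that("minmax_normalize maps off-diagonal onto [0,1] and is idempotent", {
  m <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3)
  out <- minmax_normalize(m)
  expect_equal(sort(unique(out[upper.tri(out)])), c(0, 0.5, 1))
  expect_equal(minmax_normalize(out), out)
  expect_equal(diag(out), rep(0, 3))
  const <- matrix(1, 3, 3); diag(const) <- 0
  expect_error(minmax_normalize(const), "degenerate")
})

test_that("full preprocessing chain yields a normalized symmetric matrix", {
  set.seed(5)
  ts <- matrix(rnorm(60 * 20), 60, 20)
  ts[, 2] <- ts[, 1] + rnorm(60, sd = 0.5)
  a <- build_association_matrix(ts)
  off <- a[row(a) != col(a)]
  expect_true(isSymmetric(a))
  expect_equal(diag(a), setNames(rep(0, 20), colnames(a)))
  expect_equal(range(off), c(0, 1))
})
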