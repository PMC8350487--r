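test_that("stepwise chain matches the triple-loop walk-accumulation oracle", {
  set.seed(21)
  for (rep in 1:5) {
    a <- random_assoc_matrix(15)
    chain <- stepwise_chain(a, max_step = 7)
    oracle <- chain_oracle(a, max_step = 7)
    for (s in 1:7) {
      expect_lt(max(abs(chain$matrices[[s]] - oracle[[s]])), 1e-10)
    }
  }
})

test_that("3-node path: step 2 connects exactly the two path endpoints", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  chain <- stepwise_chain(a, max_step = 2)
  ns2 <- chain$matrices[[2]]
  expect_equal(ns2[1, 3], 1)
  expect_equal(ns2[3, 1], 1)
  expect_equal(sum(ns2 != 0), 2)
})

test_that("no walk between disconnected components at any step", {
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[2, 1] <- 1
  a[3, 4] <- a[4, 3] <- 0.5; a[4, 5] <- a[5, 4] <- 0.8
  a <- minmax_normalize(a)
  chain <- stepwise_chain(a, max_step = 4)
  for (s in 1:4) {
    expect_equal(chain$matrices[[s]][1:2, 3:5], matrix(0, 2, 3))
  }
})

test_that("chain support is contained in walk-length reachability", {
  set.seed(22)
  a <- random_assoc_matrix(12, density = 0.25)
  chain <- stepwise_chain(a, max_step = 5)
  for (s in 2:5) {
    reach <- walk_pairs_oracle(a, s)
    sup <- chain$matrices[[s]] > 1e-12
    expect_true(all(reach[sup]))
  }
})

test_that("products preserve symmetry and normalization invariance under affine input maps", {
  set.seed(23)
  a <- random_assoc_matrix(14)
  chain <- stepwise_chain(a)
  for (m in chain$matrices) expect_true(isSymmetric(m))
  # positive affine rescale of the raw weights gives the same chain after
  # the (idempotent) first normalization
  raw <- a * 3.7 + 0.2; diag(raw) <- 0
  chain2 <- stepwise_chain(minmax_normalize(raw))
  for (s in 1:7) expect_equal(chain2$matrices[[s]], chain$matrices[[s]], tolerance = 1e-12)
})

test_that("local chain excludes the barbell bridge and errors on an all-path graph", {
  a <- barbell_matrix()
  nsfc <- stepwise_chain(a)
  lc <- local_chain(a, nsfc)
  nlc1 <- lc$matrices[[1]]
  expect_equal(nlc1["c", "d"], 0)     # bridge has no 2-step alternative
  triangle_edges <- rbind(c("a","b"), c("a","c"), c("b","c"),
                          c("d","e"), c("d","f"), c("e","f"))
  for (r in seq_len(nrow(triangle_edges))) {
    expect_gt(nlc1[triangle_edges[r, 1], triangle_edges[r, 2]], 0)
  }
  expect_equal(lc$mask_count, 12L)    # six undirected edges, stored twice

  # weighted complete graph: every edge has a 2-step path; the mask keeps
  # the full edge support except pairs where the normalized 2-step matrix
  # attains its exact minimum
  set.seed(27)
  k <- matrix(0, 6, 6)
  k[upper.tri(k)] <- runif(15, 0.2, 1)
  k <- minmax_normalize(k + t(k))
  kch <- stepwise_chain(k)
  klc <- local_chain(k, kch)
  dropped <- (k > 0) & (klc$matrices[[1]] == 0)
  argmin2 <- abs(kch$matrices[[2]]) <= 1e-12 & row(k) != col(k)
  expect_true(all(dropped == argmin2))

  # 3-node path: no edge has a 2-step alternative -> empty mask error
  p <- matrix(0, 3, 3); p[1,2] <- p[2,1] <- p[2,3] <- p[3,2] <- 1
  expect_error(local_chain(p, stepwise_chain(p, max_step = 2), max_step = 2), "empty local mask")
})

test_that("local chain recursion matches the oracle with NLC_1 as propagator", {
  set.seed(24)
  a <- random_assoc_matrix(15)
  nsfc <- stepwise_chain(a)
  lc <- local_chain(a, nsfc)
  oracle <- chain_oracle(a, propagate = lc$matrices[[1]], max_step = 7,
                         step1 = lc$matrices[[1]])
  for (s in 1:7) expect_lt(max(abs(lc$matrices[[s]] - oracle[[s]])), 1e-10)
})

test_that("distributed seed lies exactly on non-adjacent cross-pairs with 4-walks", {
  a <- barbell_matrix()
  nsfc <- stepwise_chain(a)
  dc <- distributed_chain(a, nsfc)
  ndc1 <- dc$matrices[[1]]
  cross <- rbind(c("a","e"), c("a","f"), c("b","e"), c("b","f"))
  for (r in seq_len(nrow(cross))) {
    expect_gt(ndc1[cross[r, 1], cross[r, 2]], 0)
  }
  expect_equal(sum(ndc1 > 0), 8)  # the four pairs, symmetric storage

  # oracle check on a random sparse graph: support = {no 1- or 2-walk} & {4-walk}
  set.seed(25)
  g <- random_assoc_matrix(20, density = 0.12)
  ch <- tryCatch(stepwise_chain(g), error = function(e) NULL)
  if (!is.null(ch)) {
    d1 <- tryCatch(distributed_chain(g, ch), error = function(e) NULL)
    if (!is.null(d1)) {
      w1 <- g > 0
      w2 <- walk_pairs_oracle(g, 2)
      w4 <- walk_pairs_oracle(g, 4)
      expected <- !w1 & !w2 & w4
      diag(expected) <- FALSE
      expect_equal(unname(d1$matrices[[1]] > 1e-12), expected)
    }
  }

  # weighted complete graph: no pair lacks both a 1- and 2-step walk -> error
  set.seed(28)
  k <- matrix(0, 6, 6)
  k[upper.tri(k)] <- runif(15, 0.2, 1)
  k <- minmax_normalize(k + t(k))
  expect_error(distributed_chain(k, stepwise_chain(k)), "no distributed pairs")
})

test_that("distributed recursion propagates along NSFC_1, not NDC_1", {
  a <- barbell_matrix()
  nsfc <- stepwise_chain(a)
  dc <- distributed_chain(a, nsfc)
  oracle <- chain_oracle(a, propagate = a, max_step = 7,
                         step1 = dc$matrices[[1]])
  for (s in 2:7) expect_lt(max(abs(dc$matrices[[s]] - oracle[[s]])), 1e-10)
})

test_that("weighted degree equals a naive accumulation over steps 2-7", {
  set.seed(26)
  a <- random_assoc_matrix(12)
  chain <- stepwise_chain(a)
  wd <- weighted_degree(chain)
  expect_lt(max(abs(wd - wd_oracle(chain$matrices))), 1e-12)
  expect_true(all(wd >= 0))
  expect_error(weighted_degree(stepwise_chain(a, max_step = 5)), "steps 2-7")
  # a single nonzero symmetric entry at step 3 contributes 1 to both nodes
  fake <- chain
  for (s in 2:7) fake$matrices[[s]] <- matrix(0, 12, 12)
  fake$matrices[[3]][1, 2] <- fake$matrices[[3]][2, 1] <- 1
  wd2 <- weighted_degree(fake)
  expect_equal(unname(wd2[1:2]), c(1, 1))
  expect_equal(sum(wd2), 2)
})

test_that("NDC_1 mass on a two-module planted graph lies on cross-module pairs", {
  spec <- synthetic_spec(n_nodes = 30, n_modules = 2, p_within = 0.6,
                         p_between = 0.03, seed = 5)
  net <- generate_modular_network(spec)
  modules <- attr(net, "modules")
  a <- minmax_normalize(net)
  nsfc <- stepwise_chain(a)
  dc <- distributed_chain(a, nsfc)
  sup <- which(dc$matrices[[1]] > 1e-12, arr.ind = TRUE)
  expect_gt(nrow(sup), 0)
  expect_true(all(modules[sup[, 1]] != modules[sup[, 2]]))
})
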