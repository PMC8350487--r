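test_that("modular network generator respects block structure and determinism", {
  spec <- synthetic_spec(n_nodes = 60, n_modules = 3, p_within = 0.4,
                         p_between = 0.05, seed = 7)
  a1 <- generate_modular_network(spec)
  a2 <- generate_modular_network(spec)
  expect_identical(a1, a2)
  expect_true(isSymmetric(unname(a1)))
  expect_true(all(a1 >= 0))
  expect_equal(diag(a1), setNames(rep(0, 60), rownames(a1)))

  # realized densities within 3 SD of their binomial expectation, pooled
  # over 5 independent networks
  w_obs <- b_obs <- w_pairs <- b_pairs <- 0
  for (s in 1:5) {
    sp <- synthetic_spec(n_nodes = 60, n_modules = 3, p_within = 0.4,
                         p_between = 0.05, seed = s)
    a <- generate_modular_network(sp)
    m <- attr(a, "modules")
    within <- outer(m, m, `==`) & upper.tri(a)
    between <- outer(m, m, `!=`) & upper.tri(a)
    w_obs <- w_obs + sum(a[within] > 0); w_pairs <- w_pairs + sum(within)
    b_obs <- b_obs + sum(a[between] > 0); b_pairs <- b_pairs + sum(between)
  }
  expect_lt(abs(w_obs - w_pairs * 0.4), 3 * sqrt(w_pairs * 0.4 * 0.6))
  expect_lt(abs(b_obs - b_pairs * 0.05), 3 * sqrt(b_pairs * 0.05 * 0.95))

  # p_between = 0 -> exact block-diagonal
  spec0 <- synthetic_spec(n_nodes = 30, n_modules = 2, p_within = 0.9,
                          p_between = 0, seed = 8)
  a0 <- generate_modular_network(spec0)
  m0 <- attr(a0, "modules")
  expect_true(all(a0[outer(m0, m0, `!=`)] == 0))
})

test_that("cohort generation is deterministic and null effects center near zero", {
  spec <- synthetic_spec(n_subjects = 24, n_nodes = 40, n_modules = 2,
                         effect_size = 0, seed = 9)
  c1 <- suppressMessages(generate_cohort(spec))
  c2 <- suppressMessages(generate_cohort(spec))
  expect_identical(c1$pheno, c2$pheno)
  expect_identical(c1$timeseries, c2$timeseries)
  expect_equal(dim(c1$timeseries[[1]]), c(150, 40))

  # effect_size = 0: WD-DT correlations at effect nodes center on 0
  wd <- t(sapply(c1$timeseries, function(ts) {
    a <- build_association_matrix(ts)
    weighted_degree(local_chain(a, stepwise_chain(a)))
  }))
  cors <- sapply(c1$effect_nodes, function(i) cor(wd[, i], c1$pheno$dt_score))
  expect_lt(abs(mean(cors)), 0.2)
})

test_that("negative planted effect yields negative WD-DT correlations across seeds", {
  negative <- 0
  for (s in 1:5) {
    spec <- synthetic_spec(n_subjects = 30, n_nodes = 40, n_modules = 2,
                           effect_size = -0.5, seed = 400 + s)
    coh <- suppressMessages(generate_cohort(spec))
    wd <- t(sapply(coh$timeseries, function(ts) {
      a <- build_association_matrix(ts)
      weighted_degree(local_chain(a, stepwise_chain(a)))
    }))
    # nodes left without surviving edges have constant (zero) WD; skip them
    cors <- suppressWarnings(
      sapply(coh$effect_nodes, function(i) cor(wd[, i], coh$pheno$dt_score)))
    if (mean(cors, na.rm = TRUE) < 0) negative <- negative + 1
  }
  expect_gte(negative, 4)
})

test_that("expression generator plants anti-correlated genes and clean noise", {
  spec <- synthetic_spec(n_genes = 1000, n_planted = 30, expr_noise_sd = 0,
                         seed = 10)
  map <- setNames(rnorm(68), sprintf("R%02d", 1:68))
  gen <- generate_expression(spec, map)
  res <- gene_similarity(gen$expr, map)
  # noise-free planted genes: similarity exactly -1
  expect_equal(unname(res$score[gen$planted]), rep(-1, 30), tolerance = 1e-10)
  # background scores center on zero
  expect_lt(abs(mean(res$score[gen$background])), 0.1)
  # determinism
  gen2 <- generate_expression(spec, map)
  expect_identical(gen$expr, gen2$expr)
  expect_identical(gen$planted, gen2$planted)
  expect_error(generate_expression(synthetic_spec(n_genes = 10, n_planted = 30),
                                   map), "n_planted")
})

test_that("annotation generator builds a recoverable planted term and decoys", {
  spec <- synthetic_spec(seed = 12, n_planted = 40, n_genes = 1000)
  planted <- sprintf("P%02d", 1:40)
  background <- sprintf("B%03d", 1:960)
  ann <- generate_annotations(planted, background, spec)
  expect_true("PLANTED_CORE" %in% names(ann$terms))
  core <- ann$terms$PLANTED_CORE
  expect_gte(length(intersect(core, planted)), 0.8 * 40 - 1)
  # round-trip through the GMT reader/writer
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, path)
  back <- read_gmt(path, background = ann$background)
  expect_identical(back$terms, ann$terms)
  # decoys are rarely significant
  res <- overrepresentation(planted, ann)
  decoys <- res[res$term != "PLANTED_CORE", ]
  expect_lte(sum(decoys$significant), 1)
})

test_that("interactome generator has a denser core than periphery by construction", {
  spec <- synthetic_spec(seed = 13)
  planted <- sprintf("P%02d", 1:20)
  background <- sprintf("B%03d", 1:300)
  net <- generate_interactome(planted, background, spec)
  in_core <- net$edges$from %in% planted & net$edges$to %in% planted
  core_density <- sum(in_core) / choose(20, 2)
  peri <- net$edges$from %in% background & net$edges$to %in% background
  peri_density <- sum(peri) / choose(300, 2)
  expect_gt(core_density, peri_density)
  net2 <- generate_interactome(planted, background, spec)
  expect_identical(net$edges, net2$edges)
})

test_that("embedding spaces stay close to the base and novelty drives distance", {
  spec <- synthetic_spec(n_subjects = 40, seed = 14)
  emb <- generate_embeddings(spec, vocab_size = 200, dim = 40)
  expect_length(emb$spaces, 5)
  base <- emb$base$vectors
  for (sp in emb$spaces) {
    cosines <- rowSums(sp$vectors * base) /
      (sqrt(rowSums(sp$vectors^2)) * sqrt(rowSums(base^2)))
    expect_gt(min(cosines), 0.7)
  }
  scored <- score_responses(emb$responses, emb$spaces)
  mat <- aggregate_subject(scored)
  dt <- latent_dt_score(mat)
  expect_gt(cor(dt, emb$novelty[names(dt)]), 0.5)
  # high-novelty subjects receive higher mean distances
  top <- names(sort(emb$novelty, decreasing = TRUE))[1:10]
  bottom <- names(sort(emb$novelty))[1:10]
  expect_gt(mean(mat[top, ]), mean(mat[bottom, ]))
  emb2 <- generate_embeddings(spec, vocab_size = 200, dim = 40)
  expect_identical(emb$responses, emb2$responses)
  expect_error(generate_embeddings(spec, dim = 1), "at least 2")
})

test_that("generators leave the caller's RNG stream untouched", {
  spec <- synthetic_spec(n_nodes = 20, n_modules = 2, seed = 15)
  map <- setNames(seq(-1, 1, length.out = 10), paste0("R", 1:10))
  set.seed(123)
  ref <- rnorm(3)
  set.seed(123)
  invisible(generate_modular_network(spec))
  invisible(generate_expression(spec, map))
  expect_equal(rnorm(3), ref)
})
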