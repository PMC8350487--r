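# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with planted effects: a modular (planted-partition)
# connectivity graph, a subject cohort whose weighted degree at chosen
# effect nodes tracks divergent thinking at a planted (negative) slope,
# an expression matrix with genes anti-correlated with a regional map,
# annotation terms concentrated in the planted genes, an interaction
# network with a dense planted core, and word-embedding spaces with
# novelty-controlled responses. Each generator is a pure function of the
# spec (seed included).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Specification of a synthetic study
#'
#' Bundles every parameter of the synthetic generators. Defaults describe
#' the reference conditions the package is exercised under: 60 subjects,
#' 120 nodes in 4 modules, 150 timepoints (a 5-minute scan at TR = 2 s),
#' a planted standardized slope of -0.5 linking weighted degree at the
#' effect nodes to divergent thinking, and a 2,000-gene transcriptome with
#' 50 planted anti-correlated genes at expression noise SD 0.5.
#'
#' @param n_subjects,n_nodes,n_modules,n_timepoints Cohort dimensions.
#' @param effect_size Standardized slope of the planted WD-DT effect
#'   (negative = higher DT, lower connectivity).
#' @param effect_module Module whose nodes carry the effect (default 1).
#' @param p_within,p_between Planted-partition edge probabilities.
#' @param w_within,w_between Length-2 ranges of uniform edge weights.
#' @param n_genes,n_planted,expr_noise_sd Transcriptome screen parameters.
#' @param n_regions Parcellation size (default 68, Desikan-Killiany-like).
#' @param seed Integer master seed; all generators derive from it.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_subjects = 60, n_nodes = 120, n_modules = 4,
                           n_timepoints = 150, effect_size = -0.5,
                           effect_module = 1,
                           p_within = 0.35, p_between = 0.02,
                           w_within = c(0.5, 0.9), w_between = c(0.2, 0.4),
                           n_genes = 2000, n_planted = 50,
                           expr_noise_sd = 0.5, n_regions = 68, seed = 1) {
  stopifnot(n_modules >= 2, p_within > p_between, n_planted <= n_genes)
  structure(list(n_subjects = n_subjects, n_nodes = n_nodes,
                 n_modules = n_modules, n_timepoints = n_timepoints,
                 effect_size = effect_size, effect_module = effect_module,
                 p_within = p_within, p_between = p_between,
                 w_within = w_within, w_between = w_between,
                 n_genes = n_genes, n_planted = n_planted,
                 expr_noise_sd = expr_noise_sd, n_regions = n_regions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

is_connected_matrix <- function(a) {
  n <- nrow(a)
  seen <- logical(n); seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- which(a[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Generate a weighted modular (planted-partition) network
#'
#' Nodes are split into `n_modules` equal-size modules; node pairs within a
#' module receive an edge with probability `p_within` and a uniform weight
#' in `w_within`, pairs across modules with probability `p_between` and
#' weight in `w_between`. Regenerates (up to 50 attempts) until the graph
#' is connected; when `p_between = 0` (a block-diagonal graph, which can
#' never be globally connected) each module must be internally connected
#' instead.
#'
#' @param spec A [synthetic_spec()].
#' @return Symmetric nonnegative matrix with zero diagonal; attribute
#'   `modules` holds the per-node module index.
#' @export
generate_modular_network <- function(spec) {
  with_seed(spec$seed + 101L, {
    n <- spec$n_nodes
    modules <- rep(seq_len(spec$n_modules), length.out = n)
    modules <- sort(modules)
    for (attempt in seq_len(50)) {
      a <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        within <- modules[i] == modules[j]
        p <- if (within) spec$p_within else spec$p_between
        if (stats::runif(1) < p) {
          rng <- if (within) spec$w_within else spec$w_between
          a[i, j] <- a[j, i] <- stats::runif(1, rng[1], rng[2])
        }
      }
      ok <- if (spec$p_between > 0) {
        is_connected_matrix(a)
      } else {
        all(vapply(unique(modules), function(m) {
          is_connected_matrix(a[modules == m, modules == m, drop = FALSE])
        }, logical(1)))
      }
      if (ok) {
        dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
        attr(a, "modules") <- modules
        return(a)
      }
    }
    stop("could not generate a connected modular network in 50 attempts")
  })
}

# Subject covariance: unit diagonal, off-diagonal proportional to the
# (effect-scaled) module graph; repaired to positive definite by eigenvalue
# flooring when needed.
subject_covariance <- function(a_scaled, cor_scale = 0.6) {
  n <- nrow(a_scaled)
  sigma <- cor_scale * a_scaled
  diag(sigma) <- 1
  sigma[sigma > 0.95] <- 0.95
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    e <- eigen(sigma, symmetric = TRUE)
    vals <- pmax(e$values, 0.05)
    sigma <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(sigma))
    sigma <- sigma / tcrossprod(d)
    ch <- chol(sigma)
    attr(ch, "repaired") <- TRUE
  }
  ch
}

#' Generate a synthetic cohort of time series and phenotypes
#'
#' Each subject's node time series is multivariate Gaussian with a
#' covariance that follows the module graph; edge covariances incident to
#' the effect nodes (the nodes of `effect_module`) are scaled by
#' `1 + effect_size * z(DT)` (clamped to `[0.05, 1.9]`), so weighted degree
#' at those nodes associates with divergent thinking at the planted sign.
#' DT is standard normal (latent semantic-distance units); age and sex are
#' drawn to match a young, predominantly female cohort (age
#' N(22.7, 6.4), P(female) = 127/175).
#'
#' @param spec A [synthetic_spec()].
#' @param network Optional pre-generated module graph (from
#'   [generate_modular_network()]).
#' @return List: `timeseries` (per-subject timepoints x nodes matrices),
#'   `pheno` (subject_id, dt_score, age, sex), `effect_nodes`,
#'   `adjacency` (logical node graph), `network`, `modules`.
#' @export
generate_cohort <- function(spec, network = generate_modular_network(spec)) {
  modules <- attr(network, "modules")
  effect_nodes <- which(modules == spec$effect_module)
  with_seed(spec$seed + 202L, {
    n_sub <- spec$n_subjects
    dt <- stats::rnorm(n_sub)
    pheno <- data.frame(
      subject_id = sprintf("sub%03d", seq_len(n_sub)),
      dt_score = dt,
      age = stats::rnorm(n_sub, mean = 22.67, sd = 6.37),
      sex = ifelse(stats::runif(n_sub) < 127 / 175, "F", "M"),
      stringsAsFactors = FALSE
    )
    z <- as.numeric(scale(dt))
    incident <- outer(seq_len(spec$n_nodes) %in% effect_nodes,
                      seq_len(spec$n_nodes) %in% effect_nodes, `|`)
    repaired <- 0L
    ts_list <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      fac <- min(max(1 + spec$effect_size * z[s], 0.05), 1.9)
      a_s <- network
      a_s[incident] <- a_s[incident] * fac
      ch <- subject_covariance(a_s)
      if (isTRUE(attr(ch, "repaired"))) repaired <- repaired + 1L
      ts <- matrix(stats::rnorm(spec$n_timepoints * spec$n_nodes),
                   nrow = spec$n_timepoints) %*% ch
      colnames(ts) <- colnames(network)
      ts_list[[s]] <- ts
    }
    if (repaired > 0) {
      message("nearest-PD repair applied to ", repaired, " subject covariance(s)")
    }
    names(ts_list) <- pheno$subject_id
    list(timeseries = ts_list, pheno = pheno, effect_nodes = effect_nodes,
         adjacency = network > 0, network = network, modules = modules)
  })
}

#' Node-to-region parcel labels for a synthetic cohort
#'
#' Assigns the `n_nodes` nodes round-robin to `n_regions` regions in a
#' seeded random order, emulating an atlas label vector.
#'
#' @param spec A [synthetic_spec()].
#' @return Integer vector of region labels, one per node.
#' @export
generate_parcel_labels <- function(spec) {
  with_seed(spec$seed + 303L, {
    sample(rep(seq_len(spec$n_regions), length.out = spec$n_nodes))
  })
}

#' Generate a gene x region expression matrix with planted genes
#'
#' Planted genes express as the negative of the standardized regional map
#' plus Gaussian noise (SD `expr_noise_sd`), i.e. they are highly expressed
#' where connectivity is low; background genes are independent standard
#' Gaussian across regions.
#'
#' @param spec A [synthetic_spec()].
#' @param map Named numeric regional map (see [parcel_mean()]).
#' @return List: `expr` (gene x region matrix), `planted` and `background`
#'   gene id vectors.
#' @export
generate_expression <- function(spec, map) {
  if (spec$n_planted > spec$n_genes) stop("n_planted exceeds n_genes")
  with_seed(spec$seed + 404L, {
    regions <- names(map)
    n_reg <- length(map)
    ids <- sprintf("G%05d", seq_len(spec$n_genes))
    planted <- sort(sample(ids, spec$n_planted))
    target <- -as.numeric(scale(as.numeric(map)))
    expr <- matrix(stats::rnorm(spec$n_genes * n_reg), spec$n_genes, n_reg,
                   dimnames = list(ids, regions))
    for (g in planted) {
      expr[g, ] <- target + stats::rnorm(n_reg, sd = spec$expr_noise_sd)
    }
    list(expr = expr, planted = planted, background = setdiff(ids, planted))
  })
}

#' Generate an annotation collection with one planted term
#'
#' One term (`PLANTED_CORE`) concentrates in the planted genes (80% of
#' them plus a handful of background genes); `n_decoys` decoy terms are
#' drawn uniformly from the background.
#'
#' @param planted,background Gene id vectors.
#' @param spec A [synthetic_spec()].
#' @param n_decoys Number of decoy terms (default 30).
#' @return An [annotation_collection()] over `c(planted, background)`.
#' @export
generate_annotations <- function(planted, background, spec, n_decoys = 30) {
  with_seed(spec$seed + 505L, {
    core <- sample(planted, max(1, round(0.8 * length(planted))))
    core <- c(core, sample(background, min(5, length(background))))
    terms <- list(PLANTED_CORE = unique(core))
    desc <- c(PLANTED_CORE = "term concentrated in planted genes")
    for (d in seq_len(n_decoys)) {
      id <- sprintf("DECOY_%02d", d)
      terms[[id]] <- sample(background, sample(10:50, 1))
      desc[id] <- "decoy term drawn uniformly from background"
    }
    annotation_collection(terms, desc, background = c(planted, background))
  })
}

#' Generate a gene-interaction network with a dense planted core
#'
#' Planted genes interconnect with probability `p_core`; background genes
#' with `p_periphery`; core-periphery pairs with `p_cross`. Weights are
#' uniform interaction confidences in `(0.2, 1)`.
#'
#' @param planted,background Gene id vectors.
#' @param spec A [synthetic_spec()].
#' @param p_core,p_periphery,p_cross Edge probabilities.
#' @return A [gene_network()].
#' @export
generate_interactome <- function(planted, background, spec,
                                 p_core = 0.35, p_periphery = 0.004,
                                 p_cross = 0.002) {
  with_seed(spec$seed + 606L, {
    sample_edges <- function(ids_a, ids_b, p, same) {
      if (same) {
        pairs <- utils::combn(ids_a, 2)
        from <- pairs[1, ]; to <- pairs[2, ]
      } else {
        grid <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
        from <- grid$a; to <- grid$b
      }
      keep <- stats::runif(length(from)) < p
      data.frame(from = from[keep], to = to[keep],
                 weight = stats::runif(sum(keep), 0.2, 1),
                 stringsAsFactors = FALSE)
    }
    edges <- rbind(
      sample_edges(planted, NULL, p_core, same = TRUE),
      sample_edges(background, NULL, p_periphery, same = TRUE),
      sample_edges(planted, background, p_cross, same = FALSE)
    )
    gene_network(edges)
  })
}

#' Generate five embedding spaces and novelty-controlled responses
#'
#' A base space of unit vectors is built around a topic direction; the two
#' prompt words sit near the topic, and vocabulary words span a range of
#' cosines to it. The five spaces are noisy rotations of the base (per-word
#' cosine to the base vector >= ~0.7). Each subject carries a standard
#' normal novelty trait; their responses are vocabulary words chosen so
#' prompt-response distance increases with novelty.
#'
#' @param spec A [synthetic_spec()].
#' @param vocab_size,dim Vocabulary size and embedding dimension.
#' @param n_responses Responses per subject per prompt.
#' @return List: `spaces` (five `"vector_space"`s), `responses` (subject_id,
#'   item, response), `novelty` (named per-subject trait), `base` space.
#' @export
generate_embeddings <- function(spec, vocab_size = 300, dim = 50,
                                n_responses = 5) {
  if (dim < 2) stop("embedding dimension must be at least 2")
  with_seed(spec$seed + 707L, {
    unitize <- function(m) m / sqrt(rowSums(m^2))
    topic <- stats::rnorm(dim); topic <- topic / sqrt(sum(topic^2))
    prompts <- c("box", "rope")
    vocab <- c(prompts, sprintf("w%04d", seq_len(vocab_size - length(prompts))))
    cosines <- c(0.9, 0.9, stats::runif(vocab_size - 2, -0.8, 0.95))
    raw <- matrix(stats::rnorm(vocab_size * dim), vocab_size, dim)
    raw <- raw - tcrossprod(raw %*% topic, topic)  # orthogonal residual
    raw <- unitize(raw)
    base_vecs <- unitize(cosines * matrix(topic, vocab_size, dim, byrow = TRUE) +
                           sqrt(1 - cosines^2) * raw)
    rownames(base_vecs) <- vocab
    base <- vector_space(base_vecs, "base")

    spaces <- lapply(seq_len(5), function(k) {
      noisy <- unitize(base_vecs + matrix(stats::rnorm(vocab_size * dim,
                                                       sd = 0.5 / sqrt(dim)),
                                          vocab_size, dim))
      rownames(noisy) <- vocab
      vector_space(noisy, paste0("space", k))
    })

    n_sub <- spec$n_subjects
    novelty <- stats::setNames(stats::rnorm(n_sub),
                               sprintf("sub%03d", seq_len(n_sub)))
    rows <- list()
    word_cos <- drop(base_vecs %*% topic)
    for (s in names(novelty)) {
      for (item in prompts) {
        target_cos <- pmin(pmax(0.3 - 0.5 * novelty[[s]] +
                                  stats::rnorm(n_responses, sd = 0.1),
                                -0.75), 0.9)
        picks <- vapply(target_cos, function(tc) {
          cand <- sample(seq_along(vocab)[-(1:2)], 40)
          cand[which.min(abs(word_cos[cand] - tc))]
        }, integer(1))
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = s, item = item, response = vocab[picks],
          stringsAsFactors = FALSE)
      }
    }
    list(spaces = spaces, responses = do.call(rbind, rows),
         novelty = novelty, base = base)
  })
}
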