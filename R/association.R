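# Node-wise GLM of weighted degree on divergent thinking, with Monte-Carlo
# cluster-extent correction for multiple comparisons.

#' Node-wise GLM of weighted degree on divergent thinking
#'
#' For each node, fits ordinary least squares of the subject weighted-degree
#' value on `[intercept, DT, age, sex]` and returns the DT coefficient, its
#' t statistic and two-sided p-value. DT is the predictor of interest; age
#' and sex are nuisance covariates. Sex is encoded as a single 0/1
#' indicator.
#'
#' @param wd Numeric matrix, subjects x nodes, of weighted-degree values.
#' @param pheno Data frame with columns `subject_id`, `dt_score`, `age`,
#'   `sex`, one row per subject, in the row order of `wd` (or matched by
#'   `rownames(wd)` when present).
#' @return Object of class `"association_map"`: data frame fields `beta`,
#'   `t_stat`, `p` (one per node) plus the design matrix and residual
#'   degrees of freedom used, so cluster correction can regress null maps
#'   identically.
#' @export
fit_glm <- function(wd, pheno) {
  wd <- as.matrix(wd)
  if (anyNA(pheno$dt_score)) stop("missing dt_score in phenotype table")
  if (!is.null(rownames(wd)) && all(rownames(wd) %in% pheno$subject_id)) {
    pheno <- pheno[match(rownames(wd), pheno$subject_id), , drop = FALSE]
  }
  if (nrow(pheno) != nrow(wd)) stop("phenotype table and WD matrix disagree on subject count")
  sex <- pheno$sex
  sex01 <- if (is.numeric(sex)) as.numeric(sex != 0) else as.numeric(factor(sex)) - 1
  X <- cbind(intercept = 1, dt = pheno$dt_score, age = pheno$age, sex = sex01)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("too few subjects (", n, ") for ", p, " predictors")
  if (qr(X)$rank < p) stop("rank-deficient design matrix")
  fit <- glm_t_stats(X, wd, coef_index = 2L)
  structure(list(beta = fit$beta, t_stat = fit$t, p = fit$p,
                 design = X, df = n - p, coef_index = 2L,
                 node_ids = colnames(wd),
                 significant_clusters = NULL),
            class = "association_map")
}

# OLS of every column of Y on X at once; t statistic and two-sided p for one
# coefficient. Shared by fit_glm and the Monte-Carlo null, where it runs on
# thousands of noise maps: everything is precomputable except two matrix
# products.
glm_precompute <- function(X) {
  xtx_inv <- solve(crossprod(X))
  list(X = X, M = xtx_inv %*% t(X), xtx_inv = xtx_inv,
       df = nrow(X) - ncol(X))
}

glm_t_stats <- function(X, Y, coef_index, pre = glm_precompute(X)) {
  B <- pre$M %*% Y
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / pre$df
  se <- sqrt(sigma2 * pre$xtx_inv[coef_index, coef_index])
  beta <- B[coef_index, ]
  t <- beta / se
  list(beta = beta, t = t, p = 2 * stats::pt(-abs(t), df = pre$df), df = pre$df)
}

#' Rook-adjacency matrix of a rectangular node lattice
#'
#' Nodes are laid out row-major on an `nr x nc` grid; two nodes are adjacent
#' when they share a grid edge. Used as the cluster-defining neighborhood
#' for synthetic statistic maps.
#'
#' @param nr,nc Grid dimensions.
#' @return Logical `nr*nc` square matrix.
#' @export
lattice_adjacency <- function(nr, nc) {
  n <- nr * nc
  adj <- matrix(FALSE, n, n)
  idx <- function(r, c) (r - 1) * nc + c
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- idx(r, c)
    if (c < nc) { j <- idx(r, c + 1); adj[i, j] <- adj[j, i] <- TRUE }
    if (r < nr) { j <- idx(r + 1, c); adj[i, j] <- adj[j, i] <- TRUE }
  }
  adj
}

# Connected components of `nodes` (integer indices) under a logical
# adjacency matrix; returns a list of integer vectors.
connected_components <- function(adj, nodes) {
  if (length(nodes) == 0) return(list())
  remaining <- nodes
  comps <- list()
  in_set <- logical(nrow(adj)); in_set[nodes] <- TRUE
  visited <- logical(nrow(adj))
  for (start in nodes) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & in_set & !visited)
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

max_cluster_size <- function(adj, t, tcrit) {
  sizes <- 0L
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * t > tcrit)
    if (length(nodes)) {
      sizes <- max(sizes, max(lengths(connected_components(adj, nodes))))
    }
  }
  sizes
}

#' Monte-Carlo cluster-extent correction of an association map
#'
#' Estimates the null distribution of the maximum supra-threshold cluster
#' size by regressing Gaussian-noise response maps on the observed design
#' matrix, exactly as the data were regressed. Observed supra-threshold
#' clusters (positive and negative t handled separately, connected under
#' `adjacency`) are retained when their Monte-Carlo p-value
#' `(1 + #{null max >= size}) / (n_iter + 1)` is at most `alpha`; the null
#' pools both tails within each iteration, so control is family-wise across
#' signs.
#'
#' @param map An `"association_map"` from [fit_glm()].
#' @param adjacency Logical node adjacency matrix defining cluster
#'   connectivity.
#' @param voxel_p Per-node two-sided threshold forming clusters (default
#'   0.05).
#' @param alpha Cluster-level significance (default 0.05, two-tailed across
#'   sign-specific clusters).
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed Optional integer seed for the noise maps; the caller's RNG
#'   state is restored on exit.
#' @return The map with `significant_clusters` (list of node index vectors)
#'   and a `clusters` data frame (size, sign, p_cluster, significant).
#' @export
cluster_correct <- function(map, adjacency, voxel_p = 0.05, alpha = 0.05,
                            n_iter = 10000, seed = NULL) {
  stopifnot(inherits(map, "association_map"))
  adjacency <- as.matrix(adjacency) != 0
  m <- length(map$t_stat)
  if (nrow(adjacency) != m) stop("adjacency must cover all ", m, " nodes")
  if (n_iter < 100) stop("n_iter < 100 gives an unstable cluster-size quantile")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  X <- map$design
  n <- nrow(X)
  pre <- glm_precompute(X)
  tcrit <- stats::qt(1 - voxel_p / 2, df = map$df)

  null_max <- integer(n_iter)
  chunk <- max(1L, min(n_iter, as.integer(4e6 / (n * m))))
  done <- 0L
  while (done < n_iter) {
    b <- min(chunk, n_iter - done)
    Y <- matrix(stats::rnorm(n * m * b), nrow = n)
    tall <- glm_t_stats(X, Y, map$coef_index, pre = pre)$t
    tmat <- matrix(tall, nrow = m)
    for (k in seq_len(b)) {
      null_max[done + k] <- max_cluster_size(adjacency, tmat[, k], tcrit)
    }
    done <- done + b
  }

  clusters <- list(); sizes <- integer(0); signs <- integer(0)
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * map$t_stat > tcrit)
    for (comp in connected_components(adjacency, nodes)) {
      clusters[[length(clusters) + 1]] <- comp
      sizes <- c(sizes, length(comp))
      signs <- c(signs, sgn)
    }
  }
  p_cluster <- vapply(sizes, function(s) (1 + sum(null_max >= s)) / (n_iter + 1), numeric(1))
  significant <- p_cluster <= alpha
  map$clusters <- data.frame(size = sizes, sign = signs,
                             p_cluster = p_cluster, significant = significant)
  map$significant_clusters <- clusters[significant]
  map$null_max_sizes <- null_max
  map
}
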