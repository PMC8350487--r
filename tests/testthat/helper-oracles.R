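# Independent brute-force oracles. Each is deliberately naive (loops,
# factorial formulas, breadth-first search) and shares no code with the
# package implementation it checks.

# Textbook Pearson correlation of two vectors.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Hand-run Benjamini-Hochberg: returns logical survivor vector at level q.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  keep <- logical(m)
  kmax <- 0
  for (i in seq_len(m)) {
    if (p[ord[i]] <= q * i / m) kmax <- i
  }
  if (kmax > 0) keep[ord[seq_len(kmax)]] <- TRUE
  keep
}

# Min-max normalization over off-diagonal entries, coded independently.
minmax_oracle <- function(m) {
  off <- c()
  n <- nrow(m)
  for (i in 1:n) for (j in 1:n) if (i != j) off <- c(off, m[i, j])
  out <- (m - min(off)) / (max(off) - min(off))
  for (i in 1:n) out[i, i] <- 0
  out
}

# Step normalization with the no-walk zero baseline, coded independently.
step_norm_oracle <- function(m) {
  off <- c()
  n <- nrow(m)
  for (i in 1:n) for (j in 1:n) if (i != j) off <- c(off, m[i, j])
  lo <- min(0, min(off))
  out <- (m - lo) / (max(off) - lo)
  for (i in 1:n) out[i, i] <- 0
  out
}

# Triple-loop walk accumulation for the stepwise chain: returns the list of
# normalized step matrices; products, symmetrization and normalization all
# computed entry by entry.
chain_oracle <- function(a, propagate = a, max_step = 7, step1 = a) {
  n <- nrow(a)
  mats <- list(step1)
  for (s in 2:max_step) {
    raw <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      acc <- 0
      for (k in 1:n) acc <- acc + mats[[s - 1]][i, k] * propagate[k, j]
      raw[i, j] <- acc
    }
    sym <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) sym[i, j] <- (raw[i, j] + raw[j, i]) / 2
    mats[[s]] <- step_norm_oracle(sym)
  }
  mats
}

# Naive weighted-degree accumulation: row sums of steps 2..7, via loops.
wd_oracle <- function(mats) {
  n <- nrow(mats[[1]])
  wd <- numeric(n)
  for (s in 2:7) for (i in 1:n) for (j in 1:n) wd[i] <- wd[i] + mats[[s]][i, j]
  wd
}

# Exact hypergeometric upper tail from the factorial formula.
hyper_oracle <- function(k, K, n, N) {
  total <- 0
  for (x in k:min(n, K)) {
    total <- total + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  total
}

# Breadth-first shortest-path closeness with Wasserman-Faust scaling.
closeness_oracle <- function(edges, gene, all_nodes) {
  nbr <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  dist <- c()
  frontier <- gene; d <- 0
  seen <- gene
  while (length(frontier)) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(nbr[frontier])), seen)
    if (!length(nxt)) break
    dist[nxt] <- d
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  m <- length(seen)
  if (m < 2) return(0)
  (m - 1) / sum(dist) * (m - 1) / (length(all_nodes) - 1)
}

# Pairs of nodes connected by at least one walk of exactly `len` steps,
# by explicit walk enumeration on a binary adjacency structure.
walk_pairs_oracle <- function(adj, len) {
  n <- nrow(adj)
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  has_walk <- matrix(FALSE, n, n)
  recurse <- function(start, current, remaining) {
    if (remaining == 0) {
      has_walk[start, current] <<- TRUE
      return(invisible())
    }
    for (nb in nbr[[current]]) recurse(start, nb, remaining - 1)
  }
  for (i in seq_len(n)) recurse(i, i, len)
  diag(has_walk) <- FALSE
  has_walk
}
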