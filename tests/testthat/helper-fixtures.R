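# Fixtures built in code.

# Two triangles {1,2,3} and {4,5,6} joined by the bridge 3-4, unit weights.
barbell_matrix <- function() {
  a <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5), c(4, 6), c(5, 6))
  for (r in seq_len(nrow(edges))) {
    a[edges[r, 1], edges[r, 2]] <- 1
    a[edges[r, 2], edges[r, 1]] <- 1
  }
  a
}

# A random sparse symmetric matrix already in preprocessed form (zero
# diagonal, off-diagonal min 0 / max 1), guaranteed connected enough for
# 7-step chains.
random_assoc_matrix <- function(n, density = 0.4) {
  repeat {
    a <- matrix(0, n, n)
    ut <- upper.tri(a)
    vals <- ifelse(stats::runif(sum(ut)) < density, stats::runif(sum(ut)), 0)
    a[ut] <- vals
    a <- a + t(a)
    if (max(a) > min(a[row(a) != col(a)])) {
      a <- connectogene::minmax_normalize(a)
      sq <- a %*% a
      diag(sq) <- 0
      if (any(a > 0) && max(sq) > 0 && any(sq[a == 0 & row(a) != col(a)] > 0)) return(a)
    }
  }
}

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Small phenotype table.
make_pheno <- function(n, dt = stats::rnorm(n)) {
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             dt_score = dt,
             age = stats::rnorm(n, 23, 6),
             sex = sample(c("F", "M"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
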