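# Stepwise functional connectivity (SFC) chains and weighted-degree maps.
#
# A chain is a list of n x n matrices, one per step s = 1..max_step. Step 1
# is the (possibly masked) normalized association matrix; for s > 1 the
# step-s matrix is a matrix product accumulating weighted walks of length s,
# with the diagonal zeroed (i != j) and min-max normalization applied after
# every product.

ZERO_TOL <- 1e-12

# Per-step normalization. A step matrix accumulates nonnegative walk
# weights, and a zero entry means "no walk of this length": that baseline
# must survive normalization, or the = 0 / != 0 masks that seed the local
# and distributed chains lose their meaning on graphs where every pair has
# a walk. So for nonnegative matrices the minimum is taken as the no-walk
# baseline 0 (division by the maximum); a negative minimum (never produced
# by the chains themselves) falls back to the full affine map.
normalize_step <- function(m) {
  off <- m[row(m) != col(m)]
  lo <- min(0, min(off))
  hi <- max(off)
  if (hi <= min(off) || hi <= lo) {
    stop("degenerate normalization: off-diagonal entries are constant")
  }
  out <- (m - lo) / (hi - lo)
  diag(out) <- 0
  out
}

chain_step <- function(prev, propagate, step) {
  sfc <- prev %*% propagate
  sfc <- (sfc + t(sfc)) / 2  # products of distinct symmetric matrices need re-symmetrizing
  diag(sfc) <- 0
  off <- sfc[row(sfc) != col(sfc)]
  if (max(off) <= min(off)) {
    stop("degenerate (constant) product matrix at step ", step)
  }
  normalize_step(sfc)
}

check_normalized <- function(a) {
  off <- a[row(a) != col(a)]
  if (min(off) < -ZERO_TOL || max(off) > 1 + ZERO_TOL) {
    stop("association matrix must be min-max normalized (off-diagonal in [0,1])")
  }
  if (any(abs(diag(a)) > ZERO_TOL)) stop("association matrix must have a zero diagonal")
}

#' Stepwise functional connectivity chain
#'
#' Builds the normalized stepwise connectivity matrices NSFC_1..NSFC_S.
#' NSFC_1 is the preprocessed association matrix itself; for s > 1,
#' `SFC_s = NSFC_(s-1) %*% NSFC_1` with the diagonal zeroed and the product
#' re-symmetrized, then normalized onto `[0, 1]` to give NSFC_s. Entry
#' (i, j) of step s therefore accumulates the weight of all s-step walks
#' from i to j, and stays exactly 0 when no such walk exists (the
#' normalization treats 0, the no-walk baseline, as the minimum).
#'
#' @param a Preprocessed association matrix (symmetric, zero diagonal,
#'   off-diagonal min 0 and max 1; see [build_association_matrix()]).
#' @param max_step Number of steps S (default 7).
#' @return Object of class `"stepwise_chain"`: a list with `matrices` (list
#'   of S matrices), `max_step`, and `flavor = "stepwise"`.
#' @export
stepwise_chain <- function(a, max_step = 7) {
  a <- as.matrix(a)
  check_normalized(a)
  mats <- vector("list", max_step)
  mats[[1]] <- a
  for (s in seq_len(max_step)[-1]) {
    mats[[s]] <- chain_step(mats[[s - 1]], a, s)
  }
  structure(list(matrices = mats, max_step = max_step, flavor = "stepwise"),
            class = "stepwise_chain")
}

#' Local connectivity chain
#'
#' Local connectivity keeps only direct links that also have a two-step
#' alternative path (links inside network modules): NLC_1 is the normalized
#' association matrix restricted to entries where NSFC_2 is nonzero, all
#' other entries 0. For s > 1, `LC_s = NLC_(s-1) %*% NLC_1` (diagonal
#' zeroed), then min-max normalized.
#'
#' @param a Preprocessed association matrix NSFC_1.
#' @param nsfc Stepwise chain computed from `a` (see [stepwise_chain()]).
#' @param max_step Number of steps (default 7).
#' @return Object of class `"stepwise_chain"` with `flavor = "local"` and
#'   `mask_count`, the number of (directed) edges retained in NLC_1.
#' @export
local_chain <- function(a, nsfc, max_step = 7) {
  a <- as.matrix(a)
  stopifnot(inherits(nsfc, "stepwise_chain"))
  if (nsfc$max_step < 2) stop("stepwise chain must reach step 2")
  mask <- abs(nsfc$matrices[[2]]) > ZERO_TOL
  nlc1 <- ifelse(mask, a, 0)
  diag(nlc1) <- 0
  if (all(abs(nlc1) <= ZERO_TOL)) {
    stop("empty local mask: no direct edge has a 2-step alternative path")
  }
  mats <- vector("list", max_step)
  mats[[1]] <- nlc1
  for (s in seq_len(max_step)[-1]) {
    mats[[s]] <- chain_step(mats[[s - 1]], nlc1, s)
  }
  structure(list(matrices = mats, max_step = max_step, flavor = "local",
                 mask_count = sum(nlc1 > ZERO_TOL)),
            class = "stepwise_chain")
}

#' Distributed connectivity chain
#'
#' Distributed connectivity seeds from node pairs with no one- or two-step
#' connection but a four-step one (links bridging modules):
#' `NDC_1(i, j) = NSFC_4(i, j)` where `NSFC_1(i, j) = NSFC_2(i, j) = 0`,
#' else 0. For s > 1, `DC_s = NDC_(s-1) %*% NSFC_1` (diagonal zeroed), then
#' min-max normalized. Note the asymmetry with the local chain: distributed
#' steps propagate along the full association matrix NSFC_1, not along
#' NDC_1.
#'
#' @inheritParams local_chain
#' @return Object of class `"stepwise_chain"` with `flavor = "distributed"`.
#' @export
distributed_chain <- function(a, nsfc, max_step = 7) {
  a <- as.matrix(a)
  stopifnot(inherits(nsfc, "stepwise_chain"))
  if (nsfc$max_step < 4) stop("stepwise chain must reach step 4")
  mask <- abs(nsfc$matrices[[1]]) <= ZERO_TOL & abs(nsfc$matrices[[2]]) <= ZERO_TOL
  ndc1 <- ifelse(mask, nsfc$matrices[[4]], 0)
  diag(ndc1) <- 0
  if (all(abs(ndc1) <= ZERO_TOL)) {
    stop("no distributed pairs at this scale: every node pair has a 1- or 2-step walk, or no 4-step walk")
  }
  mats <- vector("list", max_step)
  mats[[1]] <- ndc1
  for (s in seq_len(max_step)[-1]) {
    mats[[s]] <- chain_step(mats[[s - 1]], a, s)
  }
  structure(list(matrices = mats, max_step = max_step, flavor = "distributed"),
            class = "stepwise_chain")
}

#' Weighted-degree map of a connectivity chain
#'
#' The per-node weighted degree (WD) is the row sum of link weights
#' accumulated over the normalized step matrices of steps 2-7:
#' `WD(i) = sum_{s=2..7} sum_j M_s(i, j)`.
#'
#' @param chain A `"stepwise_chain"` with at least 7 steps (any flavor).
#' @return Numeric vector, one nonnegative value per node.
#' @export
weighted_degree <- function(chain) {
  stopifnot(inherits(chain, "stepwise_chain"))
  if (chain$max_step < 7) {
    stop("chain has ", chain$max_step, " steps; weighted degree sums steps 2-7")
  }
  wd <- numeric(nrow(chain$matrices[[1]]))
  for (s in 2:7) wd <- wd + rowSums(chain$matrices[[s]])
  names(wd) <- rownames(chain$matrices[[1]])
  wd
}

#' @export
print.stepwise_chain <- function(x, ...) {
  cat(sprintf("<%s connectivity chain: %d nodes, %d steps>\n",
              x$flavor, nrow(x$matrices[[1]]), x$max_step))
  invisible(x)
}
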