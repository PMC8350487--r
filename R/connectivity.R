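#' Pearson association matrix from a node time-series matrix
#'
#' Computes the node-by-node Pearson correlation matrix of a BOLD-like
#' time-series matrix (rows are timepoints, columns are nodes). The diagonal
#' is set to 0 by convention: self-connectivity carries no information in
#' graph analyses of functional connectivity.
#'
#' @param ts Numeric matrix, timepoints x nodes. Column names (if present)
#'   are carried through as node identifiers.
#' @return Symmetric numeric matrix (nodes x nodes) of correlations with a
#'   zero diagonal.
#' @examples
#' ts <- matrix(rnorm(50), 10, 5)
#' r <- correlation_matrix(ts)
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time-series matrix must be numeric")
  if (anyNA(ts)) stop("time-series matrix contains missing values")
  if (nrow(ts) < 3) stop("at least 3 timepoints are required, got ", nrow(ts))
  if (ncol(ts) < 2) stop("at least 2 nodes are required")
  v <- apply(ts, 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    ids <- if (!is.null(colnames(ts))) colnames(ts)[bad] else bad
    stop("zero-variance node(s): ", paste(ids, collapse = ", "))
  }
  r <- stats::cor(ts)
  diag(r) <- 0
  r
}

#' Fisher r-to-z transform of an association matrix
#'
#' Applies atanh entrywise. Correlations are clipped to +/-(1 - 1e-7) first
#' so that exact +/-1 entries (e.g. duplicated series) do not produce
#' infinities. The diagonal stays 0.
#'
#' @param a Symmetric correlation matrix with zero diagonal.
#' @return Matrix of Fisher z values, same shape, zero diagonal.
#' @export
fisher_z <- function(a) {
  a <- as.matrix(a)
  clip <- 1 - 1e-7
  a[a > clip] <- clip
  a[a < -clip] <- -clip
  z <- atanh(a)
  diag(z) <- 0
  z
}

#' Zero out negative matrix entries
#'
#' Negative functional-connectivity weights have a contested interpretation
#' in graph-integration analyses and are removed before any walk-based
#' measure is computed.
#'
#' @param a Numeric matrix.
#' @return Matrix with all negative entries replaced by 0.
#' @export
remove_negatives <- function(a) {
  a <- as.matrix(a)
  a[a < 0] <- 0
  a
}

#' FDR-threshold an association matrix
#'
#' Converts each upper-triangle edge back to a correlation (when the input
#' holds Fisher z values), derives a two-sided p-value from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n` timepoints, applies
#' Benjamini-Hochberg control at level `q` across the upper triangle, zeroes
#' edges that do not survive, and mirrors the result to keep symmetry.
#'
#' @param a Symmetric matrix of edge weights (Fisher z by default).
#' @param n_timepoints Number of timepoints the correlations were estimated
#'   from; must exceed 3.
#' @param q Benjamini-Hochberg false-discovery level (default 0.005, chosen
#'   to strip the weakest connections).
#' @param on Either `"fisher_z"` (entries are atanh(r); default, matching the
#'   preprocessing order correlation -> Fisher z -> negative removal -> FDR)
#'   or `"correlation"` (entries are raw r).
#' @return Thresholded symmetric matrix, zero diagonal.
#' @export
fdr_threshold <- function(a, n_timepoints, q = 0.005,
                          on = c("fisher_z", "correlation")) {
  on <- match.arg(on)
  a <- as.matrix(a)
  if (n_timepoints <= 3) stop("n_timepoints must exceed 3")
  n <- nrow(a)
  ut <- upper.tri(a)
  vals <- a[ut]
  r <- if (on == "fisher_z") tanh(vals) else vals
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  df <- n_timepoints - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  keep <- stats::p.adjust(p, method = "BH") <= q
  out <- matrix(0, n, n, dimnames = dimnames(a))
  kept <- vals
  kept[!keep] <- 0
  out[ut] <- kept
  out <- out + t(out)
  diag(out) <- 0
  out
}

#' Min-max normalize a matrix over its off-diagonal entries
#'
#' Rescales off-diagonal entries to `[0, 1]` via `(m - min) / (max - min)`,
#' with min/max taken over the off-diagonal only. The diagonal is forced to
#' 0 (self-connectivity is excluded from every stepwise computation).
#'
#' @param m Numeric square matrix.
#' @return Matrix with off-diagonal values in `[0, 1]` (min exactly 0 and
#'   max exactly 1) and a zero diagonal.
#' @export
minmax_normalize <- function(m) {
  m <- as.matrix(m)
  off <- m[row(m) != col(m)]
  lo <- min(off)
  hi <- max(off)
  if (hi <= lo) stop("degenerate normalization: off-diagonal entries are constant")
  out <- (m - lo) / (hi - lo)
  diag(out) <- 0
  out
}

#' Full association-matrix preprocessing chain
#'
#' Convenience wrapper running correlation -> Fisher z -> negative removal
#' -> FDR thresholding -> min-max normalization, the preprocessing that
#' produces the normalized association matrix every stepwise chain starts
#' from.
#'
#' @inheritParams correlation_matrix
#' @param q FDR level passed to [fdr_threshold()].
#' @return Symmetric matrix, zero diagonal, off-diagonal in `[0, 1]`.
#' @export
build_association_matrix <- function(ts, q = 0.005) {
  r <- correlation_matrix(ts)
  z <- remove_negatives(fisher_z(r))
  thr <- fdr_threshold(z, n_timepoints = nrow(ts), q = q)
  minmax_normalize(thr)
}
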