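# Transcriptome-wide spatial-similarity screen: correlate every gene's
# regional expression profile with a regional connectivity map, take the
# whole-transcriptome score distribution as the empirical null, and select
# the genes beyond k SD of it in either tail.

#' Spatial similarity of gene expression with a regional connectivity map
#'
#' Computes, per gene, the Pearson correlation between the gene's expression
#' across cortical regions and the regional connectivity (or statistic) map,
#' over the regions shared by both inputs (matched by name, identically
#' ordered).
#'
#' @param expr Numeric gene x region matrix with gene row names and region
#'   column names.
#' @param map Named numeric vector: the regional map (see [parcel_mean()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Object of class `"similarity_result"`: `score` (named per-gene
#'   vector, `NA` for zero-variance genes), `n_regions`, `method`; null
#'   moments and tails are filled in by [null_and_select()].
#' @export
gene_similarity <- function(expr, map, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix must have gene row names")
  shared <- intersect(colnames(expr), names(map))
  if (length(shared) < 3) stop("fewer than 3 shared regions between expression and map")
  e <- expr[, shared, drop = FALSE]
  m <- map[shared]
  sds <- apply(e, 1, stats::sd)
  score <- rep(NA_real_, nrow(e))
  names(score) <- rownames(e)
  ok <- sds > 0
  if (any(ok)) {
    score[ok] <- drop(stats::cor(t(e[ok, , drop = FALSE]), m, method = method))
  }
  if (any(!ok)) {
    message(sum(!ok), " zero-variance gene(s) scored as missing")
  }
  structure(list(score = score, n_regions = length(shared), method = method,
                 null_mean = NULL, null_sd = NULL,
                 lower_tail = NULL, upper_tail = NULL, k_sd = NULL),
            class = "similarity_result")
}

#' Empirical null and two-tailed gene selection
#'
#' The whole-transcriptome score distribution itself is the null: its mean
#' and standard deviation are the empirical null moments, and candidate
#' genes are those whose score lies beyond `k_sd` standard deviations of it
#' on either side. Downstream analyses typically consume the lower tail
#' (genes highly expressed where connectivity is low).
#'
#' @param res A `"similarity_result"` from [gene_similarity()].
#' @param k_sd Threshold multiplier (default 2).
#' @return The result with `null_mean`, `null_sd`, `lower_tail`,
#'   `upper_tail` and `k_sd` populated.
#' @export
null_and_select <- function(res, k_sd = 2) {
  stopifnot(inherits(res, "similarity_result"))
  sc <- res$score[!is.na(res$score)]
  if (length(sc) < 100) stop("fewer than 100 scored genes: null moments unstable")
  mu <- mean(sc)
  sdv <- stats::sd(sc)
  if (sdv == 0) stop("degenerate null: all gene scores identical")
  res$null_mean <- mu
  res$null_sd <- sdv
  res$k_sd <- k_sd
  res$lower_tail <- names(sc)[sc < mu - k_sd * sdv]
  res$upper_tail <- names(sc)[sc > mu + k_sd * sdv]
  res
}

#' Intersection of two candidate gene lists
#'
#' Genes present in both lists, in the order of the first.
#'
#' @param a,b Character vectors of gene ids.
#' @return Character vector.
#' @export
shared_genes <- function(a, b) {
  a[a %in% b]
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity screen: %d genes over %d regions (%s)>\n",
              length(x$score), x$n_regions, x$method))
  if (!is.null(x$null_mean)) {
    cat(sprintf("  null mean %.4f, sd %.4f; tails at %g SD: %d lower / %d upper\n",
                x$null_mean, x$null_sd, x$k_sd,
                length(x$lower_tail), length(x$upper_tail)))
  }
  invisible(x)
}
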