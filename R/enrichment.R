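# Gene-set overrepresentation against GMT annotation collections, with
# fold enrichment and Bonferroni control.

#' Read a GMT annotation file
#'
#' Standard GMT: one tab-separated line per term, fields term id,
#' description, then member genes. Duplicate genes within a term are
#' deduplicated.
#'
#' @param path Path to a GMT file.
#' @param background Optional gene universe; defaults to the union of all
#'   term genes.
#' @return Object of class `"annotation_collection"`: `terms` (named list of
#'   character vectors), `descriptions`, `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  terms <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line ", i, ": fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    terms[[f[[1]]]] <- genes
    desc[f[[1]]] <- f[[2]]
  }
  if (is.null(background)) background <- unique(unlist(terms))
  annotation_collection(terms, desc, background)
}

#' Construct an annotation collection
#'
#' @param terms Named list of character gene vectors (term id -> genes).
#' @param descriptions Named character vector of term descriptions.
#' @param background Gene universe; every term gene must belong to it.
#' @return An `"annotation_collection"`.
#' @export
annotation_collection <- function(terms, descriptions = NULL, background = NULL) {
  if (is.null(background)) background <- unique(unlist(terms))
  stray <- setdiff(unique(unlist(terms)), background)
  if (length(stray)) stop("term gene(s) outside background: ", paste(utils::head(stray, 5), collapse = ", "))
  if (any(lengths(terms) < 1)) stop("empty term(s) in collection")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(terms)), names(terms))
  }
  structure(list(terms = terms, descriptions = descriptions, background = background),
            class = "annotation_collection")
}

#' Write an annotation collection to GMT
#'
#' @param ann An `"annotation_collection"`.
#' @param path Output path.
#' @export
write_gmt <- function(ann, path) {
  lines <- vapply(names(ann$terms), function(id) {
    paste(c(id, ann$descriptions[[id]], ann$terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Overrepresentation of a candidate gene list in annotation terms
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) per term: with
#' `N` background genes, `K` in the term, `n` candidates and `k` candidates
#' in the term, p is the probability of drawing at least `k` term genes in
#' `n` draws without replacement. Fold enrichment is `(k/n) / (K/N)`.
#' Bonferroni correction multiplies p by the number of tested terms; a term
#' is reported significant when `FE > fe_min` and Bonferroni `q < q_max`.
#'
#' @param candidates Character vector of candidate gene ids; must be a
#'   subset of the background.
#' @param ann An `"annotation_collection"`.
#' @param fe_min Minimum fold enrichment to call a term (default 2).
#' @param q_max Bonferroni-corrected significance threshold (default 0.05).
#' @return Data frame, one row per term: `term`, `description`, `k`, `K`,
#'   `n`, `N`, `fold_enrichment`, `p`, `q`, `significant`, sorted by p.
#' @export
overrepresentation <- function(candidates, ann, fe_min = 2, q_max = 0.05) {
  stopifnot(inherits(ann, "annotation_collection"))
  candidates <- unique(candidates)
  outside <- setdiff(candidates, ann$background)
  if (length(outside)) {
    stop("candidate gene(s) absent from background: ", paste(outside, collapse = ", "))
  }
  N <- length(ann$background)
  n <- length(candidates)
  n_terms <- length(ann$terms)
  rows <- lapply(names(ann$terms), function(id) {
    term_genes <- intersect(ann$terms[[id]], ann$background)
    K <- length(term_genes)
    k <- length(intersect(candidates, term_genes))
    fe <- (k / n) / (K / N)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = id, description = ann$descriptions[[id]],
               k = k, K = K, n = n, N = N,
               fold_enrichment = fe, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- pmin(1, out$p * n_terms)
  out$significant <- out$fold_enrichment > fe_min & out$q < q_max
  out[order(out$p), , drop = FALSE]
}
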