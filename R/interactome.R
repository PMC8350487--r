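# Closeness centrality of candidate genes in a gene-gene interaction
# network (composite interaction confidences, e.g. predicted physical
# interactions and shared protein domains).

#' Read a gene-interaction edge list
#'
#' Tab-separated rows `gene_a  gene_b  [weight]`. Missing weights default to
#' 1; duplicate edges (either orientation) keep the maximum weight;
#' self-loop rows are skipped with a notice.
#'
#' @param path Path to a TSV edge list (no header by default).
#' @param header Whether the file has a header row.
#' @return Object of class `"gene_network"`: data frame `edges` with columns
#'   `from`, `to`, `weight`, and `nodes`, the sorted gene ids.
#' @export
read_edge_list <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs at least two columns")
  names(df)[1:2] <- c("from", "to")
  df$weight <- if (ncol(df) >= 3) as.numeric(df[[3]]) else 1
  gene_network(df[, c("from", "to", "weight")])
}

#' Construct a gene network from an edge data frame
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `weight` (default 1). Undirected; duplicates keep the max weight;
#'   self-loops are dropped with a notice.
#' @return A `"gene_network"`.
#' @export
gene_network <- function(edges) {
  edges <- as.data.frame(edges)
  if (is.null(edges$weight)) edges$weight <- 1
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  loops <- edges$from == edges$to
  if (any(loops)) {
    message(sum(loops), " self-loop row(s) skipped")
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[[`, "", 1),
                    to = vapply(parts, `[[`, "", 2),
                    weight = as.numeric(w),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(edges = out, nodes = sort(unique(c(out$from, out$to)))),
            class = "gene_network")
}

#' Write a gene network as a TSV edge list
#'
#' @param network A `"gene_network"`.
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Closeness centrality of genes in an interaction network
#'
#' For a gene in a connected component of size `m` within a network of `n`
#' nodes, closeness is `(m - 1) / sum(d)` over shortest-path distances `d`
#' to the other component members, scaled by `(m - 1) / (n - 1)`
#' (Wasserman-Faust correction, so values are comparable across components
#' of a disconnected graph). Distances are hop counts by default; with
#' `weighted = TRUE` edge lengths are `1 / weight`, treating weights as
#' interaction confidences.
#'
#' @param network A `"gene_network"`.
#' @param genes Gene ids to score; genes absent from the network get `NA`
#'   with a notice. Default: all network nodes.
#' @param weighted Use inverse-confidence edge lengths (default FALSE).
#' @return Data frame `gene`, `component_size`, `closeness`.
#' @export
closeness_centrality <- function(network, genes = NULL, weighted = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  if (is.null(genes)) genes <- network$nodes
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE)
  nn <- length(network$nodes)
  present <- genes[genes %in% network$nodes]
  absent <- setdiff(genes, present)
  if (length(absent)) {
    message(length(absent), " gene(s) absent from network: ",
            paste(utils::head(absent, 5), collapse = ", "))
  }
  comp <- igraph::components(g)
  wts <- if (weighted) 1 / igraph::E(g)$weight else NA
  D <- igraph::distances(g, v = present, weights = wts)
  memb <- comp$membership[present]
  res <- vapply(seq_along(present), function(i) {
    m <- comp$csize[memb[[i]]]
    if (m < 2) return(c(m, 0))
    d <- D[i, ]
    d <- d[is.finite(d) & d > 0]
    c(m, (m - 1) / sum(d) * (m - 1) / (nn - 1))
  }, numeric(2))
  out <- data.frame(gene = c(present, absent),
                    component_size = c(res[1, ], rep(NA_integer_, length(absent))),
                    closeness = c(res[2, ], rep(NA_real_, length(absent))),
                    stringsAsFactors = FALSE)
  out[match(genes, out$gene), , drop = FALSE]
}
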