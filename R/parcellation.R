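#' Region-level means of a node-level statistic map
#'
#' Summarizes a per-node map (e.g. the regression t map) into per-region
#' means of a cortical parcellation such as the 68-region Desikan-Killiany
#' atlas. Nodes labelled `0` (or `NA`) are unassigned and ignored. Regions
#' with no member nodes are omitted, not zero-filled; when `region_ids`
#' requests such a region, a notice is emitted.
#'
#' @param node_map Numeric vector, one value per node.
#' @param labels Region label per node (integer or character; `0`/`NA` =
#'   unassigned).
#' @param region_ids Optional ordered region labels to report; defaults to
#'   the sorted labels present.
#' @return Named numeric vector of unweighted region means, with attribute
#'   `n_nodes` giving member counts.
#' @export
parcel_mean <- function(node_map, labels, region_ids = NULL) {
  if (length(node_map) != length(labels)) stop("labels must cover all nodes")
  assigned <- !is.na(labels) & labels != 0
  vals <- node_map[assigned]
  labs <- as.character(labels[assigned])
  means <- tapply(vals, labs, mean)
  counts <- tapply(vals, labs, length)
  if (!is.null(region_ids)) {
    region_ids <- as.character(region_ids)
    missing <- setdiff(region_ids, names(means))
    if (length(missing)) {
      message("region(s) with no member nodes omitted: ", paste(missing, collapse = ", "))
    }
    keep <- intersect(region_ids, names(means))
    means <- means[keep]; counts <- counts[keep]
  } else {
    ord <- order(names(means))
    means <- means[ord]; counts <- counts[ord]
  }
  out <- as.numeric(means)
  names(out) <- names(means)
  attr(out, "n_nodes") <- as.integer(counts)
  out
}
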