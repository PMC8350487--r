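# Semantic-distance creativity scoring: cosine distance between prompt and
# response word vectors in several embedding spaces, aggregated per subject
# and combined into one latent divergent-thinking (DT) score.

#' Semantic distance between two embedding vectors
#'
#' `1 - cosine(u, v)`, ranging over `[0, 2]`: 0 for identical directions, 1
#' for orthogonal vectors, 2 for antiparallel ones. Larger distances mark
#' more novel prompt-response pairs.
#'
#' @param u,v Numeric vectors of equal dimension and nonzero norm.
#' @return Scalar in `[0, 2]`.
#' @export
semantic_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm vector")
  1 - sum(u * v) / (nu * nv)
}

#' Read a word-vector space from TSV
#'
#' Rows are `word  x1  x2 ...`; no header.
#'
#' @param path Path to a TSV embedding table.
#' @param name Space name (defaults to the file name).
#' @return Object of class `"vector_space"`: `name` and `vectors`, a numeric
#'   matrix with word row names.
#' @export
read_vector_space <- function(path, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  vectors <- as.matrix(df[, -1, drop = FALSE])
  rownames(vectors) <- df[[1]]
  colnames(vectors) <- NULL
  vector_space(vectors, name)
}

#' Construct a vector space from a word-by-dimension matrix
#'
#' @param vectors Numeric matrix with word row names; no zero rows.
#' @param name Space name.
#' @return A `"vector_space"`.
#' @export
vector_space <- function(vectors, name = "space") {
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors))) stop("vectors must have word row names")
  if (any(rowSums(vectors^2) == 0)) stop("zero vector(s) in space ", name)
  structure(list(name = name, vectors = vectors), class = "vector_space")
}

#' Compose a multi-word phrase into one vector
#'
#' Element-wise mean of the vectors of the resolvable words (the additive
#' composition convention); unresolvable words are reported with a notice.
#'
#' @param words Character vector.
#' @param space A `"vector_space"`.
#' @return Numeric vector of the space's dimension.
#' @export
multiword_vector <- function(words, space) {
  stopifnot(inherits(space, "vector_space"))
  known <- words[words %in% rownames(space$vectors)]
  missing <- setdiff(words, known)
  if (length(missing)) {
    message("word(s) not in space ", space$name, ": ", paste(missing, collapse = ", "))
  }
  if (length(known) == 0) stop("no resolvable words in: ", paste(words, collapse = " "))
  colMeans(space$vectors[known, , drop = FALSE])
}

#' Score prompt-response pairs in several embedding spaces
#'
#' For each response row and each space, computes the semantic distance
#' between the prompt word(s) and the response word(s), both composed via
#' [multiword_vector()]. Rows whose prompt or response has no resolvable
#' word in a space get `NA` there.
#'
#' @param responses Data frame with columns `subject_id`, `item` (prompt)
#'   and `response`; multi-word fields are split on whitespace.
#' @param spaces List of `"vector_space"` objects.
#' @return Data frame: `subject_id`, `item`, `response`, one distance column
#'   per space.
#' @export
score_responses <- function(responses, spaces) {
  stopifnot(all(c("subject_id", "item", "response") %in% names(responses)))
  out <- responses[, c("subject_id", "item", "response")]
  for (sp in spaces) {
    d <- vapply(seq_len(nrow(responses)), function(i) {
      pw <- strsplit(as.character(responses$item[[i]]), "\\s+")[[1]]
      rw <- strsplit(as.character(responses$response[[i]]), "\\s+")[[1]]
      tryCatch(
        semantic_distance(suppressMessages(multiword_vector(pw, sp)),
                          suppressMessages(multiword_vector(rw, sp))),
        error = function(e) NA_real_)
    }, numeric(1))
    out[[sp$name]] <- d
  }
  out
}

#' Aggregate scored responses into a subject x space matrix
#'
#' Mean distance per subject and space over all scored (non-missing)
#' responses; subjects with no scored response in some space are excluded
#' with a notice.
#'
#' @param scored Output of [score_responses()].
#' @return Numeric matrix, subjects x spaces, with subject row names.
#' @export
aggregate_subject <- function(scored) {
  space_cols <- setdiff(names(scored), c("subject_id", "item", "response"))
  subjects <- unique(as.character(scored$subject_id))
  mat <- matrix(NA_real_, length(subjects), length(space_cols),
                dimnames = list(subjects, space_cols))
  for (j in space_cols) {
    m <- tapply(scored[[j]], as.character(scored$subject_id),
                function(x) mean(x, na.rm = TRUE))
    mat[names(m), j] <- m
  }
  bad <- apply(mat, 1, function(x) any(!is.finite(x)))
  if (any(bad)) {
    message("subject(s) with no scored response excluded: ",
            paste(rownames(mat)[bad], collapse = ", "))
    mat <- mat[!bad, , drop = FALSE]
  }
  mat
}

#' Latent divergent-thinking score across embedding spaces
#'
#' Extracts the common variance of the per-space mean distances as the first
#' principal component of the column-standardized subject x space matrix,
#' sign-aligned so that loadings are predominantly positive (higher score =
#' larger semantic distance across spaces). A factor-analysis extraction is
#' available as an alternative.
#'
#' @param distances Numeric subject x space matrix (see
#'   [aggregate_subject()]).
#' @param method `"pca"` (default) or `"fa"` (one-factor maximum
#'   likelihood).
#' @return Named numeric vector of latent DT scores, one per subject.
#' @export
latent_dt_score <- function(distances, method = c("pca", "fa")) {
  method <- match.arg(method)
  distances <- as.matrix(distances)
  if (ncol(distances) < 2) stop("at least 2 spaces required")
  if (nrow(distances) < 3) stop("at least 3 subjects required")
  sds <- apply(distances, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(distances)[sds == 0], collapse = ", "))
  }
  Z <- scale(distances)
  if (method == "pca") {
    pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    loadings <- pc$rotation[, 1]
    scores <- pc$x[, 1]
  } else {
    fa <- stats::factanal(Z, factors = 1, scores = "regression")
    loadings <- drop(fa$loadings)
    scores <- drop(fa$scores)
  }
  if (sum(loadings > 0) < sum(loadings < 0)) scores <- -scores
  stats::setNames(as.numeric(scores), rownames(distances))
}
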