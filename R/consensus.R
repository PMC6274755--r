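# Multi-enhancer consensus utilities: genes are typically controlled by
# several enhancers whose eRNA profiles carry largely redundant information
# about the TF; these helpers combine them.

#' Meta-enhancer: per-sample median over a TF's enhancers
#'
#' Collapses the eRNA profiles of all putative enhancers of one TF into a
#' single anchor by taking the per-sample median expression. The result is a
#' non-negative vector usable as an anchor candidate in both continuous and
#' binary mode.
#'
#' @param enhancer_rows Enhancers x samples matrix (>= 1 row).
#' @return Numeric vector of length `ncol(enhancer_rows)`.
#' @export
meta_enhancer <- function(enhancer_rows) {
  if (is.null(dim(enhancer_rows))) enhancer_rows <- matrix(enhancer_rows, nrow = 1)
  if (nrow(enhancer_rows) == 0) stop("meta_enhancer: no enhancer rows")
  apply(enhancer_rows, 2, stats::median)
}

#' Consensus target scores from the first principal component
#'
#' 'Averages' the binary target predictions made from each enhancer of a TF
#' by taking the first principal component of the enhancers x genes 0/1
#' prediction matrix (genes as observations, enhancers as variables). The
#' per-gene PC scores are sign-fixed to correlate non-negatively with the
#' per-gene mean prediction, so the output is a deterministic consensus
#' target score.
#'
#' @param binary_prediction_matrix Enhancers x genes matrix of 0/1
#'   predictions (>= 2 rows, >= 2 columns).
#' @return Named numeric vector of gene scores with attribute
#'   `"explained_variance"` (share of variance captured by the first PC).
#' @export
consensus_targets_pca <- function(binary_prediction_matrix) {
  m <- binary_prediction_matrix
  if (is.null(dim(m)) || nrow(m) < 2 || ncol(m) < 2) {
    stop("consensus_targets_pca needs >= 2 enhancer rows and >= 2 gene columns")
  }
  if (max(m) == min(m)) stop("degenerate error: constant prediction matrix")
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  scores <- pr$x[, 1]
  cm <- colMeans(m)
  s <- sum(scores * (cm - mean(cm)))
  if (s < 0) scores <- -scores
  ev <- pr$sdev^2
  attr(scores, "explained_variance") <- ev[1] / sum(ev)
  scores
}

#' Jaccard similarity and clustering of predicted target sets
#'
#' Computes the pairwise Jaccard similarity |X intersect Y| / |X union Y|
#' between target sets (e.g. the per TF-enhancer-pair predictions) and
#' clusters them by average-linkage hierarchical clustering of the Jaccard
#' distance. TF-enhancer pairs of the same factor typically cluster
#' together, reflecting the redundancy of a factor's enhancers.
#'
#' @param sets Named list (>= 2 elements) of character vectors of gene
#'   identifiers.
#' @return List with `similarity` (symmetric matrix), `hclust` (the
#'   average-linkage tree) and `order` (deterministic leaf order).
#' @export
cluster_target_sets <- function(sets) {
  if (length(sets) < 2) stop("cluster_target_sets needs >= 2 target sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  k <- length(sets)
  sim <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      u <- length(union(sets[[i]], sets[[j]]))
      sim[i, j] <- sim[j, i] <-
        if (u == 0) 1 else length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  list(similarity = sim, hclust = hc, order = hc$order)
}
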