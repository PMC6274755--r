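# Validation utilities: score thresholding, precision-recall curves, and
# BH-corrected hypergeometric enrichment against ground-truth target sets.

#' Threshold a score table into predicted target sets
#'
#' Per TF, the genes whose combined score strictly exceeds the threshold
#' (default 0.8) become the predicted target set.
#'
#' @param x An `"anchor_scores"` object ([infer_targets()]).
#' @param threshold Score cutoff in \[0, 1\] (default 0.8; strict
#'   "exceeding").
#' @return Named list of [target_set()] objects (source `"predicted"`),
#'   one per TF with predictions.
#' @export
threshold_predictions <- function(x, threshold = 0.8) {
  stopifnot(inherits(x, "anchor_scores"), threshold >= 0, threshold <= 1)
  s <- x$scores
  tfs <- unique(s$tf_id)
  out <- lapply(tfs, function(tf) {
    sub <- s[s$tf_id == tf, ]
    target_set(tf, sub$gene[sub$score > threshold], "predicted")
  })
  stats::setNames(out, tfs)
}

#' Precision-recall curve and area
#'
#' Standard precision-recall curve over descending score thresholds (one
#' threshold per distinct score; ties are handled as a block), with the
#' interpolation-free step integral as the area. The prevalence of positives
#' is reported alongside: it is the precision of a random classifier and the
#' horizontal background line of a PR plot.
#'
#' @param scores Numeric score vector.
#' @param truth 0/1 (or logical) vector of the same length with at least one
#'   positive and one negative.
#' @return List with `curve` (data.frame: threshold, recall, precision),
#'   `auc` (step integral) and `prevalence`.
#' @export
precision_recall <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(scores) != length(truth)) stop("dimension error: unequal lengths")
  npos <- sum(truth)
  if (npos == 0) stop("undefined recall: no positive example in truth")
  if (npos == length(truth)) stop("no negative example in truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- cumsum(rle(s)$lengths)       # block ends of tied scores
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / npos
  precision <- tp / (tp + fp)
  auc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = s[last], recall = recall,
                          precision = precision),
       auc = auc,
       prevalence = npos / length(truth))
}

#' Hypergeometric enrichment of predicted vs ground-truth targets
#'
#' Upper-tail hypergeometric test P(X >= overlap) for the overlap between a
#' predicted and a ground-truth target set inside a universe of
#' `universe_n` scored genes. Use [enrichment_table()] to apply the BH
#' correction across all TFs of one run.
#'
#' @param predicted,truth [target_set()] objects (or character vectors of
#'   gene IDs).
#' @param universe_n Number of genes in the universe (the genes scored for
#'   this TF, not the whole genome).
#' @return data.frame row with `tf_id`, `overlap`, `predicted_n`,
#'   `truth_n`, `universe_n`, `pvalue`.
#' @export
enrichment_test <- function(predicted, truth, universe_n) {
  pg <- if (inherits(predicted, "target_set")) predicted$genes else predicted
  tg <- if (inherits(truth, "target_set")) truth$genes else truth
  tf <- if (inherits(predicted, "target_set")) predicted$tf_id else NA_character_
  k <- length(pg); K <- length(tg)
  if (universe_n < max(k, K)) {
    stop("value error: universe smaller than a gene set")
  }
  ov <- length(intersect(pg, tg))
  p <- stats::phyper(ov - 1, K, universe_n - K, k, lower.tail = FALSE)
  data.frame(tf_id = tf, overlap = ov, predicted_n = k, truth_n = K,
             universe_n = universe_n, pvalue = p, stringsAsFactors = FALSE)
}

#' Enrichment across TFs with BH correction
#'
#' Runs [enrichment_test()] for every TF present in both the predicted and
#' the ground-truth collections and applies the Benjamini-Hochberg FDR
#' correction across the resulting p-values.
#'
#' @param predicted Named list of predicted [target_set()]s (e.g. from
#'   [threshold_predictions()]).
#' @param truths Named list of ground-truth [target_set()]s keyed by TF.
#' @param universe_n Universe size (scalar, or named vector per TF).
#' @return data.frame with one row per TF: the [enrichment_test()] columns
#'   plus `qvalue`.
#' @export
enrichment_table <- function(predicted, truths, universe_n) {
  tfs <- intersect(names(predicted), names(truths))
  if (length(tfs) == 0) stop("no TF shared between predictions and truths")
  un <- if (length(universe_n) == 1) stats::setNames(rep(universe_n, length(tfs)), tfs)
        else universe_n[tfs]
  rows <- lapply(tfs, function(tf) {
    enrichment_test(predicted[[tf]], truths[[tf]], un[[tf]])
  })
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}
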