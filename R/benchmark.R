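#' Run one seeded benchmark of the inference pipeline
#'
#' Simulates a scenario, runs adaptive inference, and measures: the pooled
#' area under the precision-recall curve of the default combined score and
#' of the traditional score (P2 * P3, computed from the same posteriors),
#' the pooled hypergeometric enrichment of predictions at score > 0.8
#' against the true target pairs, and the fraction of TFs for which the
#' adaptive selector picked the true anchor mode.
#'
#' Pooling is over (TF, gene) pairs across all TFs of the run; the
#' enrichment universe is the set of scored pairs.
#'
#' @param seed RNG seed of the scenario.
#' @param preset Scenario preset name (see [scenario_preset()]).
#' @param threshold Score threshold for the enrichment measurement
#'   (default 0.8).
#' @return List with `aupr_default`, `aupr_traditional`, `enrichment_p`,
#'   `mode_accuracy`, `n_predicted_tfs`, `n_pairs`.
#' @export
scenario_benchmark <- function(seed, preset = "confounded-network",
                               threshold = 0.8) {
  sim <- simulate_dataset(scenario_preset(preset, seed = seed))
  res <- infer_targets(sim$genes, sim$enhancers, sim$tf_table)
  sc <- res$scores
  if (nrow(sc) == 0) stop("benchmark run produced no predictions")
  truth_pairs <- unlist(lapply(names(sim$truth), function(tf)
    paste(tf, sim$truth[[tf]]$genes)))
  pair_id <- paste(sc$tf_id, sc$gene)
  is_true <- pair_id %in% truth_pairs

  aupr_default <- precision_recall(sc$score, is_true)$auc
  aupr_traditional <- precision_recall(
    traditional_posterior(sc$P2, sc$P3), is_true)$auc

  predicted <- pair_id[sc$score > threshold]
  enr <- enrichment_test(predicted, pair_id[is_true], length(pair_id))

  done <- res$anchors$status == "predicted"
  truth_mode <- sim$anchors$mode_truth[match(res$anchors$tf_id,
                                             sim$anchors$tf_id)]
  mode_accuracy <- mean(res$anchors$mode[done] == truth_mode[done])

  list(aupr_default = aupr_default, aupr_traditional = aupr_traditional,
       enrichment_p = enr$pvalue, mode_accuracy = mode_accuracy,
       n_predicted_tfs = sum(done), n_pairs = length(pair_id))
}

#' Null-calibration simulation of the five tests
#'
#' Draws `n_replicates` trios of mutually independent standard-normal
#' variables at `n` samples each, rank-normalizes them, and returns the
#' matrix of the five tests' p-values, which must be uniform under the null.
#'
#' @param n_replicates Number of independent trios.
#' @param n Samples per trio.
#' @param seed RNG seed.
#' @return `n_replicates` x 5 matrix of p-values (columns test 1..5).
#' @export
null_calibration <- function(n_replicates = 10000, n = 30, seed = 1) {
  set.seed(seed)
  out <- matrix(NA_real_, n_replicates, 5,
                dimnames = list(NULL, paste0("test", 1:5)))
  for (i in seq_len(n_replicates)) {
    e <- rank_normal_transform(stats::rnorm(n))
    a <- rank_normal_transform(stats::rnorm(n))
    b <- rank_normal_transform(stats::rnorm(n))
    out[i, ] <- trio_statistics(trio_correlations(e, a, b))$pvalue
  }
  out
}
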