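#' Combined causality score
#'
#' Default combination of the per-test posteriors into a single causal score
#' P = (P2 * P5 + P4) / 2, where P2 is the secondary-linkage posterior, P5
#' the controlled-test posterior and P4 the relevance posterior. The product
#' P2 * P5 demands both an anchor-target linkage and a residual TF effect
#' (robust against pleiotropy and hidden confounders); averaging with P4
#' retains sensitivity for weak regulations.
#'
#' @param p2,p4,p5 Posterior probabilities in \[0, 1\] for the secondary
#'   linkage, relevance and controlled tests.
#' @return Score in \[0, 1\], non-decreasing in each argument.
#' @export
combined_posterior <- function(p2, p4, p5) {
  check_unit_interval(p2, p4, p5)
  (p2 * p5 + p4) / 2
}

#' Traditional causal-inference score
#'
#' Baseline combination P2 * P3: secondary linkage AND conditional
#' independence (P3 is the posterior that the causal chain E -> A -> B
#' holds). Provided for comparison; it is vulnerable to hidden confounding
#' between a TF and its targets, which the default combination of
#' [combined_posterior()] is designed to tolerate.
#'
#' @param p2,p3 Posterior probabilities in \[0, 1\].
#' @return Score in \[0, 1\].
#' @export
traditional_posterior <- function(p2, p3) {
  check_unit_interval(p2, p3)
  p2 * p3
}

check_unit_interval <- function(...) {
  v <- c(...)
  if (anyNA(v) || any(v < 0 | v > 1)) {
    stop("domain error: posterior probabilities must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Predict causal targets of one TF from one anchor
#'
#' Runs the trio likelihood-ratio tests of one anchored TF against every
#' candidate target gene: the anchor E (continuous: rank-normalized eRNA;
#' binary: standardized on/off indicator) is tested once for primary linkage
#' with the TF, and tests 2-5 are evaluated for every candidate B. Each
#' test's p-values are pooled across all candidates for empirical-Bayes
#' posterior estimation, and posteriors are combined into the causality
#' score. The reported `P3` is the posterior that the causal chain holds
#' (the conditional-independence null), so that `P2 * P3` is the traditional
#' score; `P1`, `P2`, `P4`, `P5` are posteriors of the respective
#' alternatives.
#'
#' @param anchor Raw per-sample enhancer signal (non-negative eRNA TPM).
#' @param tf_expression Per-sample expression of the TF (any strictly
#'   monotone transform of TPM; rank-normalized internally).
#' @param targets_expression Matrix of candidate targets (genes x samples)
#'   with rownames as gene identifiers. A row named `tf_id` is excluded.
#' @param mode `"continuous"` or `"binary"` anchor treatment.
#' @param combination `"default"` ((P2*P5 + P4)/2) or `"traditional"`
#'   (P2*P3).
#' @param tf_id Optional identifier of the TF's own feature row, excluded
#'   from the candidate list.
#' @param min_candidates Pool size below which posterior estimation falls
#'   back to 1 - p (with a warning).
#' @return A data.frame with one row per candidate gene: `gene`, LLRs and
#'   p-values of tests 2-5, posteriors `P2`..`P5`, and `score`; attributes
#'   `primary` (llr, pvalue, posterior-free primary-linkage summary),
#'   `mode`, `combination`, `n`.
#' @export
predict_targets <- function(anchor, tf_expression, targets_expression,
                            mode = c("continuous", "binary"),
                            combination = c("default", "traditional"),
                            tf_id = NULL, min_candidates = 50) {
  mode <- match.arg(mode)
  combination <- match.arg(combination)
  n <- length(anchor)
  if (length(tf_expression) != n) {
    stop("dimension error: anchor and TF expression differ in length")
  }
  if (is.null(dim(targets_expression))) {
    targets_expression <- matrix(targets_expression, nrow = 1,
                                 dimnames = list("B1", NULL))
  }
  if (ncol(targets_expression) != n) {
    stop("dimension error: target matrix must have one column per sample")
  }
  if (is.null(rownames(targets_expression))) {
    rownames(targets_expression) <- paste0("B", seq_len(nrow(targets_expression)))
  }
  if (!is.null(tf_id)) {
    targets_expression <-
      targets_expression[setdiff(rownames(targets_expression), tf_id), ,
                         drop = FALSE]
  }
  if (nrow(targets_expression) == 0) stop("no candidate targets left")

  e <- if (mode == "binary") encode_binary_anchor(anchor)
       else rank_normal_transform(anchor)
  a <- rank_normal_transform(tf_expression)
  B <- normalize_rows(targets_expression, drop_constant = TRUE)
  genes <- rownames(B)
  m <- length(genes)

  rho_ea <- clamp_rho(pair_correlation(e, a))
  rho_eb <- clamp_rho(as.numeric(B %*% e) / n)
  rho_ab <- clamp_rho(as.numeric(B %*% a) / n)

  det3 <- pmax(trio_determinant(rho_ea, rho_eb, rho_ab), 1e-300)
  half_n <- n / 2
  llr1 <- -half_n * log1p(-rho_ea^2)
  llr2 <- -half_n * log1p(-rho_eb^2)
  llr4 <- -half_n * log(det3) + half_n * log1p(-rho_ea^2)
  llr3 <- llr4 + half_n * log1p(-rho_ab^2)
  llr5 <- llr4 + half_n * log1p(-rho_eb^2)
  # nested hypotheses guarantee >= 0 up to rounding
  llr2 <- pmax(llr2, 0); llr3 <- pmax(llr3, 0)
  llr4 <- pmax(llr4, 0); llr5 <- pmax(llr5, 0)

  p1 <- null_pvalue(llr1, n, 1)
  p2 <- null_pvalue(llr2, n, 2)
  p3 <- null_pvalue(llr3, n, 3)
  p4 <- null_pvalue(llr4, n, 4)
  p5 <- null_pvalue(llr5, n, 5)

  if (m < min_candidates) {
    warning("only ", m, " candidate targets; posterior estimation falls back ",
            "to the conservative 1 - p")
  }
  P2 <- posteriors_from_pvalues(p2, min_candidates)
  P3 <- 1 - posteriors_from_pvalues(p3, min_candidates)  # prob. chain null holds
  P4 <- posteriors_from_pvalues(p4, min_candidates)
  P5 <- posteriors_from_pvalues(p5, min_candidates)

  score <- if (combination == "default") combined_posterior(P2, P4, P5)
           else traditional_posterior(P2, P3)

  out <- data.frame(gene = genes,
                    llr2 = llr2, llr3 = llr3, llr4 = llr4, llr5 = llr5,
                    pval2 = p2, pval3 = p3, pval4 = p4, pval5 = p5,
                    P2 = P2, P3 = P3, P4 = P4, P5 = P5,
                    score = score,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "primary") <- c(llr = llr1, pvalue = p1, rho_ea = rho_ea)
  attr(out, "mode") <- mode
  attr(out, "combination") <- combination
  attr(out, "n") <- n
  out
}

#' Enumerate anchor candidates of one TF
#'
#' For each candidate enhancer of a TF, computes the primary-linkage p-value
#' in continuous mode (rank-normalized eRNA) and, where the binarized vector
#' is non-degenerate, in binary mode. Each enhancer thus yields at most two
#' candidates.
#'
#' @param enhancer_matrix Enhancers x samples matrix of raw eRNA values with
#'   rownames.
#' @param tf_expression Per-sample TF expression.
#' @return data.frame with columns `enhancer_id`, `mode`, `pvalue`, `llr`.
#' @export
anchor_candidates <- function(enhancer_matrix, tf_expression) {
  if (is.null(dim(enhancer_matrix))) {
    enhancer_matrix <- matrix(enhancer_matrix, nrow = 1,
                              dimnames = list("E1", NULL))
  }
  a <- rank_normal_transform(tf_expression)
  n <- length(a)
  rows <- lapply(rownames(enhancer_matrix), function(id) {
    raw <- enhancer_matrix[id, ]
    res <- list()
    for (mode in c("continuous", "binary")) {
      enc <- tryCatch(
        if (mode == "binary") encode_binary_anchor(raw)
        else rank_normal_transform(raw),
        error = function(e) NULL)
      if (is.null(enc)) next
      rho <- clamp_rho(pair_correlation(enc, a))
      llr <- llr_linkage(rho, n)
      res[[mode]] <- data.frame(enhancer_id = id, mode = mode,
                                pvalue = null_pvalue(llr, n, 1), llr = llr,
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(enhancer_id = character(0), mode = character(0),
                      pvalue = numeric(0), llr = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Adaptive anchor selection for one TF
#'
#' Picks, among a TF's candidate enhancers in both modes, the one with the
#' lowest primary-linkage p-value; its mode then determines whether targets
#' are predicted with the binary or continuous method. Exact p-value ties
#' are resolved in favor of the continuous mode (more information retained),
#' then by enhancer identifier.
#'
#' @param candidates data.frame as returned by [anchor_candidates()].
#' @return One-row data.frame (`enhancer_id`, `mode`, `pvalue`, ...).
#' @export
select_anchor_adaptive <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("no-anchor error: no usable anchor candidate for this TF")
  }
  mode_rank <- match(candidates$mode, c("continuous", "binary"))
  ord <- order(candidates$pvalue, mode_rank, candidates$enhancer_id)
  candidates[ord[1], , drop = FALSE]
}

#' Infer causal targets for a set of TFs
#'
#' Full per-TF orchestration: for every TF, the candidate enhancers are
#' scored for primary linkage (continuous and binarized treatment), the
#' anchor is chosen according to `anchor_mode` ("adaptive" picks the overall
#' best mode; "continuous"/"binary" restrict the choice to one mode), TFs
#' whose best primary-linkage p-value exceeds `primary_alpha` are skipped,
#' and targets are predicted with [predict_targets()].
#'
#' @param genes Genes x samples expression matrix (promoter/gene features,
#'   typically log2(TPM+1); any monotone scale works) whose rownames include
#'   the TF promoter features.
#' @param enhancers Enhancers x samples matrix of raw eRNA TPM values.
#' @param tf_table data.frame with columns `tf_id` and `promoter_id`
#'   (promoter feature row in `genes`).
#' @param candidates Optional data.frame with columns `tf_id`,
#'   `enhancer_id` restricting which enhancers anchor which TF (e.g. the
#'   50 kb assignment of [assign_candidate_enhancers()]); `NULL` uses every
#'   enhancer for every TF.
#' @param anchor_mode `"adaptive"`, `"continuous"` or `"binary"`.
#' @param combination `"default"` or `"traditional"` (see
#'   [combined_posterior()], [traditional_posterior()]).
#' @param primary_alpha Primary-linkage p-value cutoff a TF must pass to
#'   enter inference (default 0.05); `NULL` disables the gate.
#' @param min_candidates Passed to [predict_targets()].
#' @return Object of class `"anchor_scores"`: list with `scores` (long
#'   data.frame: tf_id, enhancer_id, mode, gene, P2..P5, score), `anchors`
#'   (per-TF selection metadata), `combination`, `n_samples`.
#' @export
infer_targets <- function(genes, enhancers, tf_table, candidates = NULL,
                          anchor_mode = c("adaptive", "continuous", "binary"),
                          combination = c("default", "traditional"),
                          primary_alpha = 0.05, min_candidates = 50) {
  anchor_mode <- match.arg(anchor_mode)
  combination <- match.arg(combination)
  stopifnot(is.matrix(genes), is.matrix(enhancers),
            all(c("tf_id", "promoter_id") %in% names(tf_table)))
  if (ncol(genes) != ncol(enhancers)) {
    stop("dimension error: gene and enhancer matrices differ in sample count")
  }

  score_rows <- list()
  anchor_rows <- list()
  for (i in seq_len(nrow(tf_table))) {
    tf <- tf_table$tf_id[i]
    prom <- tf_table$promoter_id[i]
    if (!prom %in% rownames(genes)) {
      warning("promoter ", prom, " of TF ", tf, " absent from gene matrix; skipped")
      next
    }
    enh_ids <- if (is.null(candidates)) rownames(enhancers)
               else candidates$enhancer_id[candidates$tf_id == tf]
    enh_ids <- intersect(enh_ids, rownames(enhancers))
    if (length(enh_ids) == 0) {
      anchor_rows[[tf]] <- anchor_row(tf, NA, NA, NA, "no_candidate_enhancer")
      next
    }
    cand <- anchor_candidates(enhancers[enh_ids, , drop = FALSE], genes[prom, ])
    if (anchor_mode != "adaptive") cand <- cand[cand$mode == anchor_mode, , drop = FALSE]
    if (nrow(cand) == 0) {
      anchor_rows[[tf]] <- anchor_row(tf, NA, NA, NA, "no_usable_anchor")
      next
    }
    sel <- select_anchor_adaptive(cand)
    if (!is.null(primary_alpha) && sel$pvalue > primary_alpha) {
      anchor_rows[[tf]] <- anchor_row(tf, sel$enhancer_id, sel$mode, sel$pvalue,
                                      "primary_linkage_not_significant")
      next
    }
    pred <- predict_targets(enhancers[sel$enhancer_id, ], genes[prom, ],
                            genes, mode = sel$mode, combination = combination,
                            tf_id = prom, min_candidates = min_candidates)
    score_rows[[tf]] <- data.frame(tf_id = tf, enhancer_id = sel$enhancer_id,
                                   mode = sel$mode, pred,
                                   stringsAsFactors = FALSE)
    anchor_rows[[tf]] <- anchor_row(tf, sel$enhancer_id, sel$mode, sel$pvalue,
                                    "predicted")
  }
  scores <- if (length(score_rows)) do.call(rbind, score_rows)
            else data.frame()
  rownames(scores) <- NULL
  anchors <- do.call(rbind, anchor_rows)
  rownames(anchors) <- NULL
  structure(list(scores = scores, anchors = anchors,
                 combination = combination, n_samples = ncol(genes)),
            class = "anchor_scores")
}

anchor_row <- function(tf, enh, mode, pvalue, status) {
  data.frame(tf_id = tf, enhancer_id = as.character(enh),
             mode = as.character(mode), primary_pvalue = as.numeric(pvalue),
             status = status, stringsAsFactors = FALSE)
}

#' @export
print.anchor_scores <- function(x, ...) {
  cat("anchor_scores:", length(unique(x$scores$tf_id)), "TF(s) with predictions,",
      x$n_samples, "samples,", nrow(x$scores), "scored pairs (",
      x$combination, "combination )\n")
  if (nrow(x$anchors)) {
    cat("anchor selection:\n")
    print(x$anchors, ...)
  }
  invisible(x)
}

#' Wide gene-by-TF score matrix
#'
#' @param x An `"anchor_scores"` object.
#' @return Numeric matrix genes x TFs of combined scores (NA where a gene
#'   was not scored for a TF, e.g. the TF's own promoter).
#' @export
score_matrix <- function(x) {
  stopifnot(inherits(x, "anchor_scores"))
  s <- x$scores
  if (nrow(s) == 0) return(matrix(numeric(0), 0, 0))
  genes <- sort(unique(s$gene))
  tfs <- unique(s$tf_id)
  m <- matrix(NA_real_, length(genes), length(tfs),
              dimnames = list(genes, tfs))
  m[cbind(match(s$gene, genes), match(s$tf_id, tfs))] <- s$score
  m
}

#' Write scored TF-target pairs as tab-separated text
#'
#' Emits the long score table with stable column order
#' (tf, enhancer_id, mode, gene, P2, P4, P5, combined), plus the traditional
#' components P3 for completeness.
#'
#' @param x An `"anchor_scores"` object.
#' @param file Output path.
#' @export
write_scores <- function(x, file) {
  stopifnot(inherits(x, "anchor_scores"))
  s <- x$scores
  out <- s[, c("tf_id", "enhancer_id", "mode", "gene",
               "P2", "P3", "P4", "P5", "score")]
  names(out) <- c("tf", "enhancer_id", "mode", "gene",
                  "P2", "P3", "P4", "P5", "combined")
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
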