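# Data-processing rules for CAGE promoter/enhancer expression tables:
# expression filters, log transform, promoter selection, candidate-enhancer
# assignment by genomic distance, binarization, and ground-truth derivation
# from ChIP-seq peaks or knock-out differential expression.

#' Filter expressed genes and log-transform
#'
#' Retains exactly the gene rows with a TPM value of 1 or more in at least
#' one sample, then (by default) log-transforms the retained rows as
#' log2(TPM + pseudocount). Sample order and the relative order of retained
#' features are preserved.
#'
#' @param m Genes x samples matrix of non-negative TPM values with rownames.
#' @param log2_transform Apply the log transform after filtering (default
#'   TRUE). The filtering step alone is idempotent.
#' @param pseudocount Pseudocount for the log transform (default 1).
#' @return Filtered (and possibly transformed) matrix.
#' @export
filter_expressed_genes <- function(m, log2_transform = TRUE, pseudocount = 1) {
  check_expression_matrix(m)
  keep <- apply(m, 1, max) >= 1
  if (!any(keep)) stop("empty result: no gene has TPM >= 1 in any sample")
  out <- m[keep, , drop = FALSE]
  if (log2_transform) out <- log2(out + pseudocount)
  out
}

#' Filter enhancers by expression breadth
#'
#' Retains enhancers with non-zero expression in strictly more than one
#' third of the samples. Enhancer values are not log-transformed: the
#' continuous anchor mode consumes untransformed eRNA values (and the rank
#' transform downstream makes any monotone rescaling immaterial).
#'
#' @param m Enhancers x samples matrix of non-negative TPM values.
#' @return Filtered matrix (possibly with zero rows).
#' @export
filter_enhancers <- function(m) {
  check_expression_matrix(m)
  n <- ncol(m)
  keep <- rowSums(m > 0) > n / 3
  m[keep, , drop = FALSE]
}

check_expression_matrix <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0 || ncol(m) == 0) {
    stop("empty or invalid expression matrix")
  }
  if (any(m < 0)) stop("expression matrix contains negative values")
  if (anyDuplicated(rownames(m))) stop("duplicate feature IDs in expression matrix")
  invisible(TRUE)
}

#' Select the representative promoter of a TF
#'
#' A TF may have several annotated promoters; the one with the highest
#' per-row median expression is used as the TF's expression feature. Exact
#' median ties break deterministically by lexicographic feature ID.
#'
#' @param promoter_rows Promoters x samples matrix restricted to one TF's
#'   promoter features (rownames required, >= 1 row).
#' @return The selected promoter feature ID (character scalar).
#' @export
select_tf_promoter <- function(promoter_rows) {
  if (is.null(dim(promoter_rows))) {
    stop("promoter_rows must be a matrix with rownames (use drop = FALSE)")
  }
  if (nrow(promoter_rows) == 0) stop("no promoter rows for this TF")
  med <- apply(promoter_rows, 1, stats::median)
  ids <- rownames(promoter_rows)
  best <- med == max(med)
  sort(ids[best])[1]
}

#' Assign candidate anchor enhancers to a TF by genomic distance
#'
#' Returns the enhancers on the same chromosome whose midpoint lies within
#' 50 kb (inclusive) of the TF's transcription start site, sorted by
#' distance (ties by enhancer ID). Coordinates follow the BED convention
#' (0-based, half-open); a TSS feature has end = start + 1 and strand is
#' ignored for distance.
#'
#' @param tss One-row data.frame (or list) with `chrom`, `start`, `end`
#'   describing the TF promoter TSS.
#' @param enhancers data.frame of enhancer regions with columns `id`,
#'   `chrom`, `start`, `end`.
#' @param window Distance window in bp (default 50000).
#' @return data.frame with columns `enhancer_id`, `distance` (bp), sorted
#'   by distance; zero rows if nothing is in range.
#' @export
assign_candidate_enhancers <- function(tss, enhancers, window = 50000) {
  tss_pos <- tss$start[1]
  if (nrow(enhancers) == 0) {
    return(data.frame(enhancer_id = character(0), distance = numeric(0)))
  }
  mid <- (enhancers$start + enhancers$end) / 2
  dist <- abs(mid - tss_pos)
  keep <- enhancers$chrom == tss$chrom[1] & dist <= window
  out <- data.frame(enhancer_id = enhancers$id[keep], distance = dist[keep],
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$enhancer_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Binarize enhancer expression
#'
#' Sets samples with zero expression to 0 and all others to 1 ("zero read
#' count" is interpreted as TPM == 0 exactly, since TPM is what CAGE tables
#' provide). All-zero or all-one vectors are returned as-is and flagged as
#' degenerate downstream (see [encode_binary_anchor()]).
#'
#' @param raw Non-negative numeric vector.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_enhancer <- function(raw) {
  if (any(raw < 0)) stop("value error: enhancer expression must be non-negative")
  as.integer(raw != 0)
}

#' Derive ChIP-seq ground-truth targets for a TF
#'
#' Genes whose TSS lies within 1 kb (inclusive) of any binding peak of the
#' TF are defined as its targets; a TSS inside a peak has distance 0.
#' Interval arithmetic is done with GenomicRanges.
#'
#' @param peaks data.frame of peak intervals (`chrom`, `start`, `end`, BED
#'   convention).
#' @param tss_table data.frame of gene TSS features (`id`, `chrom`,
#'   `start`, `end` with end = start + 1).
#' @param tf_id Identifier recorded in the result.
#' @param max_distance Distance cutoff in bp (default 1000).
#' @return List of class `"target_set"`: `tf_id`, `genes` (character
#'   vector), `source = "chipseq"`.
#' @export
derive_chip_targets <- function(peaks, tss_table, tf_id, max_distance = 1000) {
  if (nrow(peaks) == 0) {
    warning("empty peak list for TF ", tf_id)
    return(target_set(tf_id, character(0), "chipseq"))
  }
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  tss_gr <- GenomicRanges::GRanges(
    tss_table$chrom, IRanges::IRanges(start = tss_table$start + 1,
                                      end = tss_table$start + 1))
  hits <- GenomicRanges::distanceToNearest(tss_gr, peak_gr)
  q <- S4Vectors::queryHits(hits)
  d <- S4Vectors::mcols(hits)$distance
  genes <- unique(tss_table$id[q[d <= max_distance]])
  target_set(tf_id, genes, "chipseq")
}

#' Derive knock-out/over-expression ground-truth targets for a TF
#'
#' Genes differentially expressed after perturbation of the TF at
#' q-value < 0.05 (strict) are defined as its targets.
#'
#' @param de_table data.frame with columns `gene` and `qvalue`.
#' @param tf_id Identifier recorded in the result.
#' @param q_cutoff Strict q-value cutoff (default 0.05).
#' @return A `"target_set"` with `source = "knockout"`.
#' @export
derive_ko_targets <- function(de_table, tf_id, q_cutoff = 0.05) {
  if (nrow(de_table) == 0) {
    warning("empty differential-expression table for TF ", tf_id)
    return(target_set(tf_id, character(0), "knockout"))
  }
  q <- de_table$qvalue
  if (anyNA(q) || any(q < 0 | q > 1)) {
    stop("value error: q-values must lie in [0, 1]")
  }
  target_set(tf_id, unique(de_table$gene[q < q_cutoff]), "knockout")
}

#' Construct a target set
#'
#' @param tf_id TF identifier.
#' @param genes Character vector of target gene identifiers.
#' @param source One of `"predicted"`, `"chipseq"`, `"knockout"`,
#'   `"synthetic"` (simulated ground truth).
#' @return List of class `"target_set"`.
#' @export
target_set <- function(tf_id, genes,
                       source = c("predicted", "chipseq", "knockout", "synthetic")) {
  source <- match.arg(source)
  structure(list(tf_id = tf_id, genes = unique(as.character(genes)),
                 source = source),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("target_set:", x$tf_id, "-", length(x$genes), "genes (", x$source, ")\n")
  invisible(x)
}
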