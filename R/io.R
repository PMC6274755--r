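# Readers and writers for the plain-text dialects the pipeline consumes:
# tab-separated expression matrices (feature ID column + sample header,
# gzip transparent), BED4/BED6 interval tables, two-column knock-out
# differential-expression tables, and TF -> promoter maps.

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample IDs and a first column of feature IDs
#' (FANTOM5-style TPM tables); `.gz` files are read transparently.
#'
#' @param file Path to the TSV (optionally gzipped).
#' @return Numeric matrix features x samples with dimnames.
#' @export
read_expression_matrix <- function(file) {
  df <- utils::read.delim(file, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  check_expression_matrix(m)
  m
}

#' Write an expression matrix in the same TSV dialect
#'
#' @param m Numeric matrix with dimnames.
#' @param file Output path.
#' @param id_column Name of the feature-ID column header (default
#'   `"feature_id"`).
#' @export
write_expression_matrix <- function(m, file, id_column = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a BED4/BED6 interval table
#'
#' Columns: chrom, start, end, name, and optionally score and strand.
#' Coordinates stay in the BED convention (0-based, half-open).
#'
#' @param file Path to the BED file.
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `strand`
#'   (`"."` when absent).
#' @export
read_bed <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED file needs at least 4 columns (chrom/start/end/name)")
  out <- data.frame(id = as.character(df[[4]]), chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    strand = if (ncol(df) >= 6) as.character(df[[6]]) else ".",
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("BED intervals must satisfy start < end")
  out
}

#' Write intervals as BED6
#'
#' @param features data.frame with `id`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param file Output path.
#' @export
write_bed <- function(features, file) {
  strand <- if ("strand" %in% names(features)) features$strand else "."
  df <- data.frame(features$chrom, features$start, features$end,
                   features$id, 0L, strand)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a knock-out differential-expression table
#'
#' Two-column TSV (gene, q-value) with a header row.
#'
#' @param file Path to the TSV.
#' @return data.frame with columns `gene`, `qvalue`.
#' @export
read_ko_table <- function(file) {
  df <- utils::read.delim(file, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("knock-out table needs columns gene and q-value")
  data.frame(gene = as.character(df[[1]]), qvalue = as.numeric(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Read a TF-to-promoter mapping table
#'
#' TSV with header and two columns: TF identifier and promoter feature ID
#' (one row per promoter; a TF may have several).
#'
#' @param file Path to the TSV.
#' @return data.frame with columns `tf_id`, `promoter_id`.
#' @export
read_tf_promoter_map <- function(file) {
  df <- utils::read.delim(file, header = TRUE, stringsAsFactors = FALSE)
  data.frame(tf_id = as.character(df[[1]]),
             promoter_id = as.character(df[[2]]), stringsAsFactors = FALSE)
}

#' Read a ground-truth target list (one gene per line)
#'
#' @param file Path to the plain-text list.
#' @param tf_id TF identifier recorded in the result.
#' @param source Provenance label (default `"knockout"`).
#' @return A [target_set()].
#' @export
read_target_list <- function(file, tf_id, source = "knockout") {
  genes <- readLines(file)
  genes <- genes[nzchar(genes)]
  target_set(tf_id, genes, source)
}

#' Write a candidate-anchor table (TF, enhancer, distance)
#'
#' @param assignments data.frame with columns `tf_id`, `enhancer_id`,
#'   `distance`.
#' @param file Output path.
#' @export
write_candidate_table <- function(assignments, file) {
  utils::write.table(assignments[, c("tf_id", "enhancer_id", "distance")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
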