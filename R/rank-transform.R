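#' Rank-based inverse-normal transform
#'
#' Converts a continuous expression vector into a standard-normal variable by
#' rank: order statistics are mapped to normal quantiles at (r - 0.5)/n
#' (average ranks for ties) and the result is re-standardized exactly to mean
#' 0 and variance 1 (1/n convention). All downstream likelihood-ratio tests
#' operate on rank-normalized variables, which makes them invariant under any
#' strictly increasing transformation of the raw data (so it does not matter
#' whether TPM values were log-transformed beforehand).
#'
#' @param x Numeric vector of length >= 5, not all values identical.
#' @return Numeric vector of the same length with mean 0 and variance 1
#'   (computed with the 1/n convention).
#' @examples
#' z <- rank_normal_transform(c(3, 1, 2, 10, 4))
#' mean(z)            # 0
#' mean(z^2)          # 1
#' @export
rank_normal_transform <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 5) {
    stop("insufficient samples: rank_normal_transform needs n >= 5, got ", n)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("rank_normal_transform: input contains missing or non-finite values")
  }
  if (max(x) == min(x)) {
    stop("degenerate variable: all values identical, cannot rank-normalize")
  }
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 0.5) / n)
  z <- z - mean(z)
  z / sqrt(mean(z * z))
}

#' Sample correlation of two normalized vectors
#'
#' Computes rho = (1/n) * sum(x_i * y_i). For vectors produced by
#' [rank_normal_transform()] or [encode_binary_anchor()] (mean 0, variance 1
#' under the 1/n convention) this is the Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length, each standardized to mean 0
#'   and variance 1 (1/n convention).
#' @return Correlation in \[-1, 1\].
#' @export
pair_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("dimension error: vectors have lengths ", length(x), " and ", length(y))
  }
  mean(x * y)
}

#' Encode a zero-inflated enhancer as a standardized binary anchor
#'
#' Maps zero entries to the low group and non-zero entries to the high group,
#' then standardizes the 0/1 indicator to mean 0, variance 1 (1/n). Feeding
#' the encoded anchor into the continuous likelihood-ratio formulas
#' reproduces the two-category group-mean (ANOVA) model exactly, so binary
#' and continuous anchors share one code path and one null family
#' (D(1, n - 2) for the linkage tests).
#'
#' @param raw Non-negative numeric vector containing both zero and non-zero
#'   entries.
#' @return Two-valued numeric vector with mean 0 and variance 1.
#' @export
encode_binary_anchor <- function(raw) {
  raw <- as.numeric(raw)
  if (anyNA(raw)) stop("encode_binary_anchor: input contains missing values")
  ind <- as.numeric(raw != 0)
  if (all(ind == 0) || all(ind == 1)) {
    stop("degenerate anchor: binarized enhancer must contain both zero and non-zero samples")
  }
  ind <- ind - mean(ind)
  ind / sqrt(mean(ind * ind))
}

# Internal: rank-normalize every row of a features x samples matrix.
# Rows that cannot be normalized (constant) trigger an error unless drop_constant.
normalize_rows <- function(m, drop_constant = FALSE) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (drop_constant) {
    rng <- apply(m, 1, function(r) max(r) - min(r))
    bad <- which(rng == 0)
    if (length(bad) > 0) {
      warning(length(bad), " constant feature row(s) dropped before rank normalization")
      m <- m[-bad, , drop = FALSE]
    }
  }
  out <- t(apply(m, 1, rank_normal_transform))
  rownames(out) <- rownames(m)
  colnames(out) <- colnames(m)
  out
}

# Internal: keep correlations strictly inside (-1, 1) before taking logs.
# Duplicate features in real CAGE tables produce |rho| == 1 exactly.
clamp_rho <- function(rho, eps = 1e-12) {
  pmin(pmax(rho, -1 + eps), 1 - eps)
}
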