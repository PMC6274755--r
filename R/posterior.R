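# Empirical-Bayes posterior estimation from a pool of p-values.
#
# The p-values of one test, pooled across all candidate targets of a TF, are
# modelled as the two-group mixture f(p) = pi0 * 1 + (1 - pi0) * f1(p). The
# local false discovery rate pi0 / f(p) then gives the posterior probability
# of the alternative as 1 - pi0 / f(p).

# Grenander estimator of a non-increasing density on [0, 1]: slopes of the
# least concave majorant (LCM) of the empirical CDF, evaluated at each p.
grenander_fhat <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  xs <- c(0, ps, 1)
  ys <- c(0, seq_len(n) / n, 1)
  # collapse duplicate x, keeping the largest ecdf value
  keep <- c(diff(xs) > 0, TRUE)
  xs <- xs[keep]
  ys <- ys[keep]
  m <- length(xs)
  # upper-hull scan: pop while the last hull point lies on/below the chord
  hi <- integer(m)
  top <- 0L
  for (i in seq_len(m)) {
    while (top >= 2L) {
      a <- hi[top - 1L]; b <- hi[top]
      s_ab <- (ys[b] - ys[a]) / (xs[b] - xs[a])
      s_bi <- (ys[i] - ys[b]) / (xs[i] - xs[b])
      if (s_ab <= s_bi) top <- top - 1L else break
    }
    top <- top + 1L
    hi[top] <- i
  }
  hx <- xs[hi[seq_len(top)]]
  hy <- ys[hi[seq_len(top)]]
  slopes <- diff(hy) / diff(hx)        # non-increasing by construction
  seg <- findInterval(ps, hx, left.open = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg > length(slopes)] <- length(slopes)
  fhat <- numeric(n)
  fhat[o] <- slopes[seg]
  fhat
}

#' Empirical-Bayes posteriors from a pool of p-values
#'
#' Converts the p-values of one likelihood-ratio test, pooled over all
#' candidate targets of a TF, into posterior probabilities of the
#' alternative hypothesis via a local-FDR scheme: the null proportion is
#' estimated as pi0 = min(1, 2 * mean(p > 0.5)), the marginal p-value
#' density by the monotone (Grenander) estimator, and the posterior is
#' 1 - min(1, pi0 / f(p)), clipped to \[0, 1\] and non-increasing in p.
#'
#' With fewer than `min_candidates` p-values the mixture cannot be estimated
#' reliably and the conservative fallback 1 - p is returned.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param min_candidates Minimum pool size for mixture estimation
#'   (default 50).
#' @return Numeric vector of posteriors in \[0, 1\], same order as input.
#' @export
posteriors_from_pvalues <- function(pvalues, min_candidates = 50) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(!is.finite(pvalues))) {
    stop("value error: p-values contain NA or non-finite entries")
  }
  if (any(pvalues < 0 | pvalues > 1)) {
    stop("value error: p-values must lie in [0, 1]")
  }
  if (length(pvalues) < min_candidates) {
    return(1 - pvalues)
  }
  pi0 <- min(1, 2 * mean(pvalues > 0.5))
  fhat <- grenander_fhat(pvalues)
  lfdr <- pmin(1, pi0 / fhat)   # pi0/0 = Inf -> clipped to 1
  1 - lfdr
}
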