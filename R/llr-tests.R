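#' Correlation triple for a trio (E, A, B)
#'
#' Bundles the three pairwise correlations of a trio, computed from the same
#' n samples of rank-normalized (or binary-encoded) variables, together with
#' the sample count. The implied 3x3 correlation matrix is positive
#' semi-definite by construction when all three correlations come from the
#' same samples; its determinant
#' \deqn{(1-\rho_{EA}^2)(1-\rho_{EB}^2) - (\rho_{AB}-\rho_{EA}\rho_{EB})^2}
#' appears in the three trio-level likelihood-ratio tests.
#'
#' @param rho_ea,rho_eb,rho_ab Correlations in \[-1, 1\]: enhancer-TF,
#'   enhancer-target and TF-target.
#' @param n Sample count (>= 5).
#' @return An object of class `"correlation_triple"`.
#' @seealso [trio_correlations()] to compute one from data vectors.
#' @export
correlation_triple <- function(rho_ea, rho_eb, rho_ab, n) {
  for (r in c(rho_ea, rho_eb, rho_ab)) {
    if (!is.finite(r) || abs(r) > 1) stop("correlations must lie in [-1, 1]")
  }
  n <- as.integer(n)
  if (n < 5) stop("insufficient samples: n >= 5 required, got ", n)
  structure(list(rho_ea = rho_ea, rho_eb = rho_eb, rho_ab = rho_ab, n = n),
            class = "correlation_triple")
}

#' Compute the correlation triple of a trio from normalized vectors
#'
#' @param e,a,b Normalized sample vectors (see [rank_normal_transform()],
#'   [encode_binary_anchor()]) of equal length.
#' @return A [correlation_triple()].
#' @export
trio_correlations <- function(e, a, b) {
  correlation_triple(pair_correlation(e, a),
                     pair_correlation(e, b),
                     pair_correlation(a, b),
                     length(e))
}

# det of the 3x3 correlation matrix; equals the bracket inside the
# trio-level LLRs, which proves the nested-hypothesis bounds LLR >= 0.
trio_determinant <- function(rho_ea, rho_eb, rho_ab) {
  (1 - rho_ea^2) * (1 - rho_eb^2) - (rho_ab - rho_ea * rho_eb)^2
}

#' Linkage likelihood-ratio test (primary or secondary)
#'
#' LLR for the alternative "the anchor regulates the gene" (E -> A for the
#' primary linkage, E -> B for the secondary linkage) against independence:
#' \deqn{LLR = -\frac{n}{2}\ln(1 - \rho^2).}
#' Under the null, LLR/n follows D(1, n - 2) (see [null_pvalue()]).
#'
#' @param rho Correlation between the anchor and the gene, |rho| < 1.
#' @param n Sample count.
#' @return Non-negative log-likelihood ratio in nats.
#' @export
llr_linkage <- function(rho, n) {
  if (any(abs(rho) >= 1)) stop("singular correlation: |rho| must be < 1")
  -(n / 2) * log1p(-rho^2)
}

#' Conditional-independence likelihood-ratio test
#'
#' Tests whether E and B become independent after conditioning on A, i.e.
#' whether the causal chain E -> A -> B (the null) explains the data against
#' the alternative of a direct E -> B effect with residual A-B correlation.
#' Under the null, LLR/n follows D(1, n - 3).
#'
#' @param ct A [correlation_triple()] whose implied matrix is non-singular.
#' @return Non-negative log-likelihood ratio in nats; exactly 0 when
#'   rho_EB = rho_EA * rho_AB (the chain is saturated).
#' @export
llr_conditional_independence <- function(ct) {
  with(unclass(ct), {
    d <- checked_determinant(rho_ea, rho_eb, rho_ab)
    -(n / 2) * log(d) + (n / 2) * log1p(-rho_ea^2) + (n / 2) * log1p(-rho_ab^2)
  })
}

#' Relevance likelihood-ratio test
#'
#' Tests whether B is regulated by either E or A (alternative: E -> A with B
#' downstream of both) against the null in which B is unrelated to the trio.
#' Under the null, LLR/n follows D(2, n - 3) (two extra parameters).
#'
#' @inheritParams llr_conditional_independence
#' @return Non-negative log-likelihood ratio in nats.
#' @export
llr_relevance <- function(ct) {
  with(unclass(ct), {
    d <- checked_determinant(rho_ea, rho_eb, rho_ab)
    -(n / 2) * log(d) + (n / 2) * log1p(-rho_ea^2)
  })
}

#' Controlled (pleiotropy-excluding) likelihood-ratio test
#'
#' Tests whether E regulates B through A, partially or fully: the null is the
#' pleiotropic fork B <- E -> A, the alternative adds a direct A -> B effect.
#' A purely pleiotropic target (rho_AB = rho_EA * rho_EB) gives LLR exactly 0.
#' Under the null, LLR/n follows D(1, n - 3).
#'
#' @inheritParams llr_conditional_independence
#' @return Non-negative log-likelihood ratio in nats.
#' @export
llr_controlled <- function(ct) {
  with(unclass(ct), {
    d <- checked_determinant(rho_ea, rho_eb, rho_ab)
    -(n / 2) * log(d) + (n / 2) * log1p(-rho_ea^2) + (n / 2) * log1p(-rho_eb^2)
  })
}

checked_determinant <- function(rho_ea, rho_eb, rho_ab) {
  d <- trio_determinant(rho_ea, rho_eb, rho_ab)
  if (d <= 0) stop("singular correlation matrix for trio (determinant <= 0)")
  d
}

#' All five likelihood-ratio tests and p-values for one trio
#'
#' Convenience wrapper computing, for one (E, A, B) trio: the five LLRs
#' (1 primary linkage, 2 secondary linkage, 3 conditional independence,
#' 4 relevance, 5 controlled) and their exact null p-values. Posterior
#' probabilities require pooling p-values across all candidate targets of a
#' TF and are computed in [predict_targets()].
#'
#' @param ct A [correlation_triple()].
#' @return List with numeric length-5 vectors `llr` and `pvalue`.
#' @export
trio_statistics <- function(ct) {
  n <- ct$n
  llr <- c(llr_linkage(ct$rho_ea, n),
           llr_linkage(ct$rho_eb, n),
           llr_conditional_independence(ct),
           llr_relevance(ct),
           llr_controlled(ct))
  names(llr) <- c("primary_linkage", "secondary_linkage",
                  "conditional_independence", "relevance", "controlled")
  pvalue <- vapply(1:5, function(i) null_pvalue(llr[i], n, i), numeric(1))
  names(pvalue) <- names(llr)
  list(llr = llr, pvalue = pvalue)
}
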