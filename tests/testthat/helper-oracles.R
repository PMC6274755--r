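# Independent oracles used by the tests. These deliberately avoid the
# package's correlation-algebra implementation: likelihood ratios are
# rebuilt as differences of numerically maximized Gaussian regression
# log-likelihoods (QR-based OLS start, BFGS polish), p-values by adaptive
# quadrature of the null density written out directly, and the binary-anchor
# equivalence via an explicit two-group ANOVA fit.

# Maximized log-likelihood of y ~ Normal(X beta, sigma2), numeric fit.
oracle_reg_ll <- function(y, X = NULL) {
  n <- length(y)
  Xd <- if (is.null(X)) matrix(1, n, 1) else cbind(1, X)
  fit <- stats::lm.fit(Xd, y)
  beta0 <- fit$coefficients
  s20 <- sum(fit$residuals^2) / n
  nll <- function(par) {
    k <- length(par)
    r <- y - Xd %*% par[-k]
    0.5 * n * (log(2 * pi) + par[k]) + 0.5 * sum(r^2) / exp(par[k])
  }
  start <- c(beta0, log(s20))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  -min(opt$value, nll(start))
}

# The five LLRs as differences of fully spelled-out model log-likelihoods.
# Terms shared between null and alternative (the E marginal, and the A | E
# regression where it appears on both sides) cancel and are included
# explicitly where they differ between hypotheses.
oracle_llr <- function(e, a, b, test_id) {
  switch(test_id,
    oracle_reg_ll(a, e) - oracle_reg_ll(a),                          # 1
    oracle_reg_ll(b, e) - oracle_reg_ll(b),                          # 2
    (oracle_reg_ll(a, e) + oracle_reg_ll(b, cbind(e, a))) -
      (oracle_reg_ll(a, e) + oracle_reg_ll(b, a)),                   # 3
    (oracle_reg_ll(a, e) + oracle_reg_ll(b, cbind(e, a))) -
      (oracle_reg_ll(a, e) + oracle_reg_ll(b)),                      # 4
    (oracle_reg_ll(a, e) + oracle_reg_ll(b, cbind(e, a))) -
      (oracle_reg_ll(a, e) + oracle_reg_ll(b, e)))                   # 5
}

# Null density of LLR/n written directly from its closed form.
oracle_null_density <- function(z, k1, k2) {
  ifelse(z <= 0, 0,
         2 / beta(k1 / 2, k2 / 2) *
           (1 - exp(-2 * z))^(k1 / 2 - 1) * exp(-k2 * z))
}

oracle_pvalue_quad <- function(llr, n, k1, k2) {
  stats::integrate(oracle_null_density, llr / n, Inf, k1 = k1, k2 = k2,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Two-group ANOVA log-likelihood ratio for a binarized anchor.
oracle_anova_llr <- function(raw, a_norm) {
  g <- factor(raw != 0)
  rss_group <- sum(stats::resid(stats::lm(a_norm ~ g))^2)
  rss_total <- sum((a_norm - mean(a_norm))^2)
  -(length(a_norm) / 2) * log(rss_group / rss_total)
}

# Random correlated trio on the rank-normalized scale.
random_trio <- function(n) {
  e <- rank_normal_transform(stats::rnorm(n))
  a <- rank_normal_transform(0.7 * e + stats::rnorm(n))
  b <- rank_normal_transform(0.4 * a + 0.3 * e + stats::rnorm(n))
  list(e = e, a = a, b = b)
}
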