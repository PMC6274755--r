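test_that("score combinations follow their closed forms and bounds", {
  expect_equal(combined_posterior(1, 1, 1), 1.0)
  expect_equal(combined_posterior(0, 0, 0), 0.0)
  expect_equal(combined_posterior(1, 0.5, 1), 0.75)
  expect_equal(traditional_posterior(1, 1), 1.0)
  expect_equal(traditional_posterior(1, 0), 0.0)
  expect_equal(traditional_posterior(0.9, 0.5), 0.45)
  expect_error(combined_posterior(1.2, 0, 0), "domain")
  expect_error(traditional_posterior(-0.1, 0.5), "domain")
  # monotone non-decreasing in each argument
  set.seed(3)
  for (i in 1:50) {
    p <- runif(3); d <- runif(1, 0, 1 - max(p))
    expect_gte(combined_posterior(p[1] + d, p[2], p[3]),
               combined_posterior(p[1], p[2], p[3]))
    expect_gte(combined_posterior(p[1], p[2] + d, p[3]),
               combined_posterior(p[1], p[2], p[3]))
    expect_gte(combined_posterior(p[1], p[2], p[3] + d),
               combined_posterior(p[1], p[2], p[3]))
  }
})

test_that("predict_targets separates true targets of a strong causal chain", {
  set.seed(21)
  n <- 50; n_true <- 200; n_genes <- 2000
  e_raw <- rexp(n)
  e <- (e_raw - mean(e_raw)) / sd(e_raw)
  a <- 0.9 * e + 0.4 * rnorm(n)
  B <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%04d", 1:n_genes), NULL))
  for (i in 1:n_true) B[i, ] <- 0.8 * a + 0.5 * rnorm(n)
  res <- predict_targets(e_raw, a, B)
  truth <- rownames(B)[1:n_true]
  expect_gt(median(res$score[res$gene %in% truth]),
            median(res$score[!res$gene %in% truth]))
  expect_true(all(res$score >= 0 & res$score <= 1))
})

test_that("an anchor independent of everything scores near zero", {
  set.seed(22)
  n <- 50
  anchor <- rexp(n)
  a <- rnorm(n)
  B <- matrix(rnorm(500 * n), 500, n,
              dimnames = list(sprintf("g%03d", 1:500), NULL))
  res <- predict_targets(anchor, a, B)
  expect_lte(mean(res$score), 0.1)
})

test_that("predictions are bit-identical under monotone transforms of inputs", {
  set.seed(23)
  n <- 40
  anchor <- rexp(n)
  a <- rnorm(n)
  B <- matrix(rnorm(100 * n), 100, n,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  r1 <- predict_targets(anchor, a, B)
  r2 <- predict_targets(anchor^2,          # strictly increasing on positives
                        exp(a), 2^B)
  expect_identical(r1$score, r2$score)
  expect_identical(r1$llr5, r2$llr5)
})

test_that("small candidate pools warn and fall back to conservative posteriors", {
  set.seed(24)
  n <- 30
  B <- matrix(rnorm(10 * n), 10, n, dimnames = list(letters[1:10], NULL))
  expect_warning(res <- predict_targets(rexp(n), rnorm(n), B),
                 "candidate targets")
  expect_equal(res$P2, 1 - res$pval2)
})

test_that("the TF's own feature is excluded from its candidate list", {
  set.seed(25)
  n <- 30
  B <- matrix(rnorm(60 * n), 60, n,
              dimnames = list(c("TF_prom", sprintf("g%02d", 1:59)), NULL))
  suppressWarnings(res <- predict_targets(rexp(n), B["TF_prom", ], B,
                                          tf_id = "TF_prom"))
  expect_false("TF_prom" %in% res$gene)
  expect_equal(nrow(res), 59)
})

test_that("adaptive anchor selection follows the lowest-p rule with ties to continuous", {
  cand <- data.frame(enhancer_id = c("e1", "e1"),
                     mode = c("continuous", "binary"),
                     pvalue = c(1e-3, 1e-6), llr = c(1, 2))
  sel <- select_anchor_adaptive(cand)
  expect_equal(sel$mode, "binary")
  single <- cand[1, ]
  expect_equal(select_anchor_adaptive(single)$enhancer_id, "e1")
  tie <- data.frame(enhancer_id = c("e1", "e1"),
                    mode = c("binary", "continuous"),
                    pvalue = c(0.01, 0.01), llr = c(1, 1))
  expect_equal(select_anchor_adaptive(tie)$mode, "continuous")
  expect_error(select_anchor_adaptive(cand[0, ]), "no-anchor")
})

test_that("adaptive inference is bit-identical to the selected single-mode run", {
  sim <- simulate_dataset(scenario_spec(n_samples = 40, n_tfs = 2,
                                        n_genes = 300, targets_per_tf = 40,
                                        anchor_mode_truth = "mixed", seed = 31))
  res_a <- infer_targets(sim$genes, sim$enhancers, sim$tf_table)
  for (tf in res_a$anchors$tf_id[res_a$anchors$status == "predicted"]) {
    mode <- res_a$anchors$mode[res_a$anchors$tf_id == tf]
    res_m <- infer_targets(sim$genes, sim$enhancers,
                           sim$tf_table[sim$tf_table$tf_id == tf, ],
                           anchor_mode = mode)
    expect_identical(res_a$scores$score[res_a$scores$tf_id == tf],
                     res_m$scores$score)
  }
})

test_that("score matrix invariants hold after a pipeline run", {
  sim <- simulate_dataset(scenario_spec(n_samples = 30, n_tfs = 3,
                                        n_genes = 200, targets_per_tf = 30,
                                        seed = 32))
  res <- infer_targets(sim$genes, sim$enhancers, sim$tf_table)
  expect_true(all(res$scores$score >= 0 & res$scores$score <= 1))
  wide <- score_matrix(res)
  for (tf in colnames(wide)) {
    prom <- sim$tf_table$promoter_id[sim$tf_table$tf_id == tf]
    expect_true(!prom %in% rownames(wide) || is.na(wide[prom, tf]))
  }
  # long table round-trips through the TSV writer
  f <- tempfile(fileext = ".tsv")
  write_scores(res, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(res$scores))
  expect_equal(back$combined, res$scores$score, tolerance = 1e-12)
})

test_that("TFs without significant primary linkage are gated out", {
  sim <- simulate_dataset(scenario_spec(n_samples = 30, n_tfs = 2,
                                        n_genes = 150, targets_per_tf = 20,
                                        effect_ea = 0, confounder_strength = 0,
                                        seed = 33))
  res <- infer_targets(sim$genes, sim$enhancers, sim$tf_table,
                       primary_alpha = 1e-6)
  expect_true(all(res$anchors$status == "primary_linkage_not_significant"))
  expect_equal(nrow(res$scores), 0)
})
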