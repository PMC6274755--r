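test_that("simulation is bit-identical for equal seeds and differs across seeds", {
  sp <- scenario_spec(n_samples = 20, n_tfs = 2, n_genes = 100,
                      targets_per_tf = 10, seed = 71)
  s1 <- simulate_dataset(sp)
  s2 <- simulate_dataset(sp)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$enhancers, s2$enhancers)
  expect_identical(s1$truth, s2$truth)
  sp2 <- scenario_spec(n_samples = 20, n_tfs = 2, n_genes = 100,
                       targets_per_tf = 10, seed = 72)
  expect_false(identical(simulate_dataset(sp2)$genes, s1$genes))
})

test_that("spec validation rejects impossible scenarios", {
  expect_error(scenario_spec(n_samples = 4), "n_samples")
  expect_error(scenario_spec(n_genes = 50, n_tfs = 10, targets_per_tf = 10),
               "too small")
  expect_error(scenario_spec(pleiotropy_fraction = 1.4), "fractions")
  expect_error(scenario_spec(effect_ea = 0.9, confounder_strength = 0.6),
               "standardized scale")
})

test_that("enhancer zero-inflation is respected within sampling error", {
  for (mode in c("binary", "continuous")) {
    sim <- simulate_dataset(scenario_spec(
      n_samples = 200, n_tfs = 10, n_genes = 10, targets_per_tf = 1,
      enhancer_zero_inflation = 0.3, anchor_mode_truth = mode, seed = 73))
    zero_frac <- mean(sim$enhancers == 0)
    # 2000 Bernoulli(0.3) draws: 99.9% interval around 0.3
    expect_lt(abs(zero_frac - 0.3), 3.3 * sqrt(0.3 * 0.7 / 2000))
  }
})

test_that("a pure chain is accepted by the conditional-independence test", {
  # population limit: rho_EB = rho_EA * rho_AB makes the LLR exactly zero
  expect_lt(abs(llr_conditional_independence(
    correlation_triple(0.9, 0.9 * 0.8, 0.8, 40))), 1e-9)
  # finite-sample chain with weak noise: the chain null stays comfortably
  # un-rejected while the relevance test fires
  set.seed(74)
  n <- 40
  e <- rank_normal_transform(rexp(n))
  a <- rank_normal_transform(e + 0.2 * rnorm(n))
  b <- rank_normal_transform(a + 0.2 * rnorm(n))
  ct <- trio_correlations(e, a, b)
  st <- trio_statistics(ct)
  expect_gt(st$pvalue[["conditional_independence"]], 0.01)
  expect_lt(st$pvalue[["relevance"]], 1e-6)
})

test_that("with the causal path off, true and non-targets score the same", {
  # effect_ab = 0 with confounding and pleiotropy also off: any A-B or E-B
  # channel would otherwise separate the groups through the relevance test
  ks_p <- vapply(1:10, function(s) {
    sim <- simulate_dataset(scenario_preset("isolated-chain", seed = 700 + s))
    res <- infer_targets(sim$genes, sim$enhancers, sim$tf_table,
                         primary_alpha = NULL)
    sc <- res$scores
    truth_pairs <- unlist(lapply(names(sim$truth), function(tf)
      paste(tf, sim$truth[[tf]]$genes)))
    is_true <- paste(sc$tf_id, sc$gene) %in% truth_pairs
    suppressWarnings(ks.test(sc$score[is_true], sc$score[!is_true]))$p.value
  }, numeric(1))
  expect_gt(min(ks_p), 0.01)
})

test_that("fixtures round-trip and interoperate with preprocessing", {
  sim <- simulate_dataset(scenario_spec(n_samples = 12, n_tfs = 3,
                                        n_genes = 40, targets_per_tf = 5,
                                        seed = 75))
  dir <- tempfile()
  files <- write_fixture(sim, dir)
  genes_back <- read_expression_matrix(files$genes)
  expect_equal(genes_back, sim$genes, tolerance = 1e-6)
  enh_back <- read_expression_matrix(files$enhancers)
  expect_equal(enh_back, sim$enhancers, tolerance = 1e-6)
  # the enhancer BED places each TF's enhancer inside the 50 kb window
  tss <- read_bed(files$tss)
  enh_bed <- read_bed(files$enhancer_bed)
  tf_map <- read_tf_promoter_map(files$tf_promoters)
  for (i in seq_len(nrow(tf_map))) {
    cand <- assign_candidate_enhancers(tss[tss$id == tf_map$promoter_id[i], ],
                                       enh_bed)
    expect_true(sim$anchors$enhancer_id[i] %in% cand$enhancer_id)
  }
  # an enhancer moved 60 kb away falls outside the window
  far <- enh_bed[1, ]
  far$start <- far$start + 40000L; far$end <- far$end + 40000L
  cand_far <- assign_candidate_enhancers(tss[tss$id == tf_map$promoter_id[1], ],
                                         far)
  expect_equal(nrow(cand_far), 0)
  # truth lists round-trip
  t1 <- read_target_list(files$truth_TF01, "TF01")
  expect_setequal(t1$genes, sim$truth$TF01$genes)
})

test_that("an always-on enhancer forces the continuous mode in adaptive selection", {
  sim <- simulate_dataset(scenario_spec(n_samples = 30, n_tfs = 1,
                                        n_genes = 120, targets_per_tf = 20,
                                        enhancer_zero_inflation = 0,
                                        anchor_mode_truth = "continuous",
                                        seed = 76))
  expect_true(all(sim$enhancers > 0))       # binary candidate is degenerate
  res <- infer_targets(sim$genes, sim$enhancers, sim$tf_table)
  expect_equal(res$anchors$mode, "continuous")
  expect_equal(res$anchors$status, "predicted")
})
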