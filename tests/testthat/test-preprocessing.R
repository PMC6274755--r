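fixture <- function(f) system.file("extdata", f, package = "ernanet")

test_that("gene expression filter keeps TPM >= 1 rows and log-transforms", {
  m <- read_expression_matrix(fixture("toy_genes.tsv"))
  out <- filter_expressed_genes(m)
  expect_setequal(rownames(out), c("g_edge", "g_hi"))   # g_low max 0.9 removed
  expect_equal(out["g_edge", "S6"], log2(1 + 1))
  raw <- filter_expressed_genes(m, log2_transform = FALSE)
  expect_equal(raw["g_hi", ], m["g_hi", ])
  # filtering step is idempotent
  expect_identical(filter_expressed_genes(raw, log2_transform = FALSE), raw)
  expect_error(filter_expressed_genes(m * 0.01), "empty result")
})

test_that("enhancer filter uses a strict more-than-one-third rule", {
  m <- read_expression_matrix(fixture("toy_enhancers.tsv"))
  out <- filter_enhancers(m)
  expect_setequal(rownames(out), c("e_three", "e_all"))  # 2 of 6 is not > 2
  expect_identical(filter_enhancers(out), out)           # idempotent
  # boundary at n = 36: 12 non-zero removed, 13 retained
  m36 <- rbind(e12 = c(rep(1, 12), rep(0, 24)),
               e13 = c(rep(1, 13), rep(0, 23)))
  colnames(m36) <- sprintf("S%02d", 1:36)
  expect_equal(rownames(filter_enhancers(m36)), "e13")
  # n = 3: 2 > 1 retained (checked on a 3-sample slice, filter only)
  m3 <- matrix(c(1, 2, 0), 1, dimnames = list("e", c("a", "b", "c")))
  expect_equal(nrow(filter_enhancers(m3)), 1)
})

test_that("filters preserve sample order and input feature order", {
  set.seed(41)
  m <- matrix(rexp(8 * 6), 8, 6,
              dimnames = list(paste0("f", 8:1), paste0("S", 1:6)))
  out <- filter_expressed_genes(m, log2_transform = FALSE)
  expect_identical(colnames(out), colnames(m))
  expect_identical(rownames(out), rownames(m)[rownames(m) %in% rownames(out)])
})

test_that("promoter selection takes the highest median with lexicographic ties", {
  m <- rbind(p1 = c(5, 5, 5, 5, 5), p2 = c(9, 9, 9, 1, 9))
  expect_equal(select_tf_promoter(m), "p2")
  expect_equal(select_tf_promoter(m["p1", , drop = FALSE]), "p1")
  tie <- rbind(pB = rep(4, 5), pA = rep(4, 5))
  expect_equal(select_tf_promoter(tie), "pA")
  expect_error(select_tf_promoter(tie[0, , drop = FALSE]), "no promoter")
})

test_that("candidate enhancers within 50 kb are found and distance-sorted", {
  tss <- read_bed(fixture("toy_tss.bed"))
  enh <- read_bed(fixture("toy_enhancer_regions.bed"))
  tf_tss <- tss[tss$id == "tf_prom", ]
  out <- assign_candidate_enhancers(tf_tss, enh)
  expect_equal(out$enhancer_id, "enh_near")       # 49,999 in; 50,001 out
  expect_equal(out$distance, 49999)
  # different chromosome excluded even at coordinate distance 0
  expect_false("enh_chr2" %in% out$enhancer_id)
  # invariant to input row order; sorted by distance then ID
  enh2 <- rbind(enh, data.frame(id = "enh_close", chrom = "chr1",
                                start = 99000, end = 101000, strand = "."))
  o1 <- assign_candidate_enhancers(tf_tss, enh2)
  o2 <- assign_candidate_enhancers(tf_tss, enh2[rev(seq_len(nrow(enh2))), ])
  expect_identical(o1, o2)
  expect_equal(o1$enhancer_id, c("enh_close", "enh_near"))
  expect_equal(nrow(assign_candidate_enhancers(tf_tss, enh[0, ])), 0)
})

test_that("binarization maps zero to 0 and everything else to 1", {
  expect_equal(binarize_enhancer(c(0, 0.3, 7)), c(0L, 1L, 1L))
  expect_equal(binarize_enhancer(rep(0, 4)), rep(0L, 4))
  expect_equal(binarize_enhancer(c(1, 2, 3)), rep(1L, 3))
  expect_error(binarize_enhancer(c(-1, 2)), "non-negative")
})

test_that("ChIP targets are genes with a TSS within 1 kb of a peak", {
  peaks <- read_bed(fixture("toy_chip_peaks.bed"))
  tss <- read_bed(fixture("toy_tss.bed"))
  ts <- derive_chip_targets(peaks, tss, "TFX")
  expect_s3_class(ts, "target_set")
  expect_setequal(ts$genes, c("t_inside", "t_near", "t_edge"))  # 0, 300, 1000 bp
  expect_false("t_far" %in% ts$genes)                           # 1100 bp
  expect_false("t_otherchrom" %in% ts$genes)
  expect_warning(empty <- derive_chip_targets(peaks[0, ], tss, "TFX"), "empty")
  expect_length(empty$genes, 0)
})

test_that("knock-out targets require q strictly below 0.05", {
  ko <- read_ko_table(fixture("toy_ko.tsv"))
  ts <- derive_ko_targets(ko, "TFX")
  expect_setequal(ts$genes, c("k_in", "k_strong"))  # 0.049 in, 0.05 out
  expect_equal(ts$source, "knockout")
  expect_warning(empty <- derive_ko_targets(ko[0, ], "TFX"), "empty")
  expect_length(empty$genes, 0)
  ko$qvalue[1] <- 1.5
  expect_error(derive_ko_targets(ko, "TFX"), "value error")
})
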