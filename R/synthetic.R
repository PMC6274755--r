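# Seeded generator of CAGE-like datasets with known causal structure:
# trios E -> A -> B with hidden confounding and pleiotropic foils, zero-
# inflated enhancer expression and TPM-scale gene expression. Used by the
# test-suite as a benchmark bed where ground truth is known exactly.

#' Scenario specification for the synthetic generator
#'
#' Latent node values are standardized, so `effect_ea`, `effect_ab` and
#' `confounder_strength` are path coefficients in correlation units
#' (residual noise variance is set to 1 minus the squared coefficients;
#' `effect^2 + confounder_strength^2` must therefore not exceed 1).
#'
#' @param n_samples Samples per dataset (>= 5).
#' @param n_tfs Number of TFs, each with one enhancer.
#' @param n_genes Number of non-promoter genes
#'   (>= n_tfs * targets_per_tf).
#' @param targets_per_tf True targets per TF.
#' @param effect_ea Anchor -> TF path coefficient.
#' @param effect_ab TF -> target path coefficient.
#' @param confounder_strength Coefficient of the shared latent confounder
#'   added to both the TF and its true targets.
#' @param pleiotropy_fraction Fraction of non-target genes receiving a
#'   direct enhancer effect without a TF effect (controlled-test foils).
#' @param enhancer_zero_inflation Expected fraction of zero samples per
#'   enhancer.
#' @param anchor_mode_truth `"continuous"`, `"binary"`, or `"mixed"`
#'   (alternating per TF).
#' @param seed Integer RNG seed; equal seeds give bit-identical datasets.
#' @return List of class `"scenario_spec"`.
#' @export
scenario_spec <- function(n_samples = 50, n_tfs = 10, n_genes = 2000,
                          targets_per_tf = 100, effect_ea = 0.8,
                          effect_ab = 0.6, confounder_strength = 0.4,
                          pleiotropy_fraction = 0.1,
                          enhancer_zero_inflation = 0.3,
                          anchor_mode_truth = c("mixed", "continuous", "binary"),
                          seed = 1) {
  anchor_mode_truth <- match.arg(anchor_mode_truth)
  if (n_samples < 5) stop("value error: n_samples must be >= 5")
  if (n_tfs < 1 || n_genes < 1 || targets_per_tf < 0) {
    stop("value error: counts must be positive")
  }
  if (n_tfs * targets_per_tf > n_genes) {
    stop("value error: n_genes too small for n_tfs * targets_per_tf true targets")
  }
  for (f in c(pleiotropy_fraction, enhancer_zero_inflation)) {
    if (f < 0 || f > 1) stop("value error: fractions must lie in [0, 1]")
  }
  if (effect_ea^2 + confounder_strength^2 > 1 ||
      effect_ab^2 + confounder_strength^2 > 1) {
    stop("value error: effect^2 + confounder_strength^2 must be <= 1 ",
         "(path coefficients on the standardized scale)")
  }
  structure(list(n_samples = n_samples, n_tfs = n_tfs, n_genes = n_genes,
                 targets_per_tf = targets_per_tf, effect_ea = effect_ea,
                 effect_ab = effect_ab,
                 confounder_strength = confounder_strength,
                 pleiotropy_fraction = pleiotropy_fraction,
                 enhancer_zero_inflation = enhancer_zero_inflation,
                 anchor_mode_truth = anchor_mode_truth, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Packaged scenario presets
#'
#' `"confounded-network"` is the standard benchmark (50 samples, 10 TFs with
#' 100 true targets each among 2000 genes, effect_ea 0.8, effect_ab 0.6,
#' confounder 0.4, pleiotropy 0.1, mixed anchor modes).
#' `"binary-anchors"`/`"continuous-anchors"` fix the true anchor mode (used
#' to check adaptive mode selection), and `"isolated-chain"` switches off
#' the TF -> target path, the confounder and the pleiotropy so that true and
#' non-targets are exchangeable.
#'
#' @param name Preset name.
#' @param seed RNG seed for the returned spec.
#' @return A [scenario_spec()].
#' @export
scenario_preset <- function(name = c("confounded-network", "binary-anchors",
                                     "continuous-anchors", "isolated-chain"),
                            seed = 1) {
  name <- match.arg(name)
  switch(name,
    "confounded-network" = scenario_spec(seed = seed),
    "binary-anchors" = scenario_spec(anchor_mode_truth = "binary", seed = seed),
    "continuous-anchors" = scenario_spec(anchor_mode_truth = "continuous",
                                         seed = seed),
    "isolated-chain" = scenario_spec(effect_ab = 0, confounder_strength = 0,
                                     pleiotropy_fraction = 0, seed = seed))
}

#' Simulate a CAGE-like dataset with known causal structure
#'
#' For every TF an enhancer signal is drawn (binary truth: Bernoulli on/off;
#' continuous truth: log-normal with the lowest `enhancer_zero_inflation`
#' quantile floored to zero), the TF node is `effect_ea * E + confounder +
#' noise`, true targets are `effect_ab * A + confounder + noise`, and a
#' `pleiotropy_fraction` of the remaining genes receive a direct enhancer
#' effect with no TF contribution. Latent gene values are mapped to a
#' TPM-like non-negative scale by exponentiation (`2^(2 * latent + 5)`), so
#' the matrices pass through the standard preprocessing filters.
#'
#' @param spec A [scenario_spec()].
#' @return List of class `"erna_sim"` with elements `enhancers`
#'   (enhancers x samples TPM matrix), `genes` (promoters + genes x samples
#'   TPM matrix), `truth` (named list of [target_set()]s), `anchors`
#'   (data.frame tf_id, enhancer_id, mode_truth), `tf_table` (tf_id,
#'   promoter_id) and `spec`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  tf_ids <- sprintf("TF%02d", seq_len(spec$n_tfs))
  gene_ids <- sprintf("g%05d", seq_len(spec$n_genes))
  zi <- spec$enhancer_zero_inflation

  modes <- switch(spec$anchor_mode_truth,
                  mixed = rep_len(c("continuous", "binary"), spec$n_tfs),
                  rep(spec$anchor_mode_truth, spec$n_tfs))

  std <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  to_tpm <- function(latent) 2^(2 * latent + 5)

  enh <- matrix(0, spec$n_tfs, n,
                dimnames = list(paste0("enh_", tf_ids), samples))
  gene_latent <- matrix(NA_real_, spec$n_tfs + spec$n_genes, n)
  rownames(gene_latent) <- c(paste0(tf_ids, "_prom"), gene_ids)

  sd_a <- sqrt(1 - spec$effect_ea^2 - spec$confounder_strength^2)
  sd_b <- sqrt(1 - spec$effect_ab^2 - spec$confounder_strength^2)

  truth <- list()
  e_nodes <- matrix(0, spec$n_tfs, n)
  a_nodes <- matrix(0, spec$n_tfs, n)
  conf <- matrix(0, spec$n_tfs, n)
  next_target <- 1L
  for (j in seq_len(spec$n_tfs)) {
    if (modes[j] == "binary") {
      s <- stats::rbinom(n, 1, 1 - zi)
      while (sum(s) %in% c(0L, n)) s <- stats::rbinom(n, 1, 1 - zi)
      e_nodes[j, ] <- std(s)
      on_level <- exp(stats::rnorm(n, meanlog_enh(), 0.5))
      enh[j, ] <- s * on_level
    } else {
      z <- stats::rnorm(n)
      e_nodes[j, ] <- std(z)
      raw <- exp(0.8 * z + meanlog_enh())
      floor_val <- stats::qlnorm(zi, meanlog = meanlog_enh(), sdlog = 0.8)
      raw[raw < floor_val] <- 0
      enh[j, ] <- raw
    }
    conf[j, ] <- stats::rnorm(n)
    a_nodes[j, ] <- spec$effect_ea * e_nodes[j, ] +
      spec$confounder_strength * conf[j, ] + sd_a * stats::rnorm(n)
    gene_latent[j, ] <- a_nodes[j, ]

    if (spec$targets_per_tf > 0) {
      idx <- next_target:(next_target + spec$targets_per_tf - 1L)
      next_target <- next_target + spec$targets_per_tf
      tg <- gene_ids[idx]
      a_std <- std(a_nodes[j, ])
      for (g in idx) {
        gene_latent[spec$n_tfs + g, ] <- spec$effect_ab * a_std +
          spec$confounder_strength * conf[j, ] + sd_b * stats::rnorm(n)
      }
      truth[[tf_ids[j]]] <- target_set(tf_ids[j], tg, "synthetic")
    } else {
      truth[[tf_ids[j]]] <- target_set(tf_ids[j], character(0), "synthetic")
    }
  }

  # background genes; a fraction become pleiotropic foils (direct E effect,
  # no TF effect) attached round-robin to the TFs
  back_idx <- if (next_target <= spec$n_genes) next_target:spec$n_genes else integer(0)
  if (length(back_idx) > 0) {
    n_pleio <- round(spec$pleiotropy_fraction * length(back_idx))
    pleio_idx <- if (n_pleio > 0) sample(back_idx, n_pleio) else integer(0)
    sd_p <- sqrt(1 - spec$effect_ab^2)
    k <- 0L
    for (g in back_idx) {
      if (g %in% pleio_idx) {
        j <- (k %% spec$n_tfs) + 1L
        k <- k + 1L
        gene_latent[spec$n_tfs + g, ] <- spec$effect_ab * e_nodes[j, ] +
          sd_p * stats::rnorm(n)
      } else {
        gene_latent[spec$n_tfs + g, ] <- stats::rnorm(n)
      }
    }
  }

  genes <- to_tpm(gene_latent)
  colnames(genes) <- samples
  anchors <- data.frame(tf_id = tf_ids, enhancer_id = paste0("enh_", tf_ids),
                        mode_truth = modes, stringsAsFactors = FALSE)
  tf_table <- data.frame(tf_id = tf_ids, promoter_id = paste0(tf_ids, "_prom"),
                         stringsAsFactors = FALSE)
  structure(list(enhancers = enh, genes = genes, truth = truth,
                 anchors = anchors, tf_table = tf_table, spec = spec),
            class = "erna_sim")
}

meanlog_enh <- function() 1

#' @export
print.erna_sim <- function(x, ...) {
  cat("erna_sim:", nrow(x$enhancers), "enhancers,", nrow(x$genes),
      "gene features,", ncol(x$genes), "samples; anchor modes:",
      paste(unique(x$anchors$mode_truth), collapse = "/"), "\n")
  invisible(x)
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits the exact dialects the preprocessing readers consume: enhancer and
#' gene TSV matrices, a TSS BED (promoter TSS at 1 Mb intervals on chr1;
#' background gene TSS on chr2), an enhancer-region BED placing each TF's
#' enhancer 20 kb from its promoter TSS (inside the 50 kb window), the
#' TF -> promoter table, and one truth target list per TF.
#'
#' @param dataset An `"erna_sim"` object.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "erna_sim"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(directory, f)
  files <- list(
    enhancers = fp("enhancer_matrix.tsv"),
    genes = fp("gene_matrix.tsv"),
    tss = fp("tss.bed"),
    enhancer_bed = fp("enhancers.bed"),
    tf_promoters = fp("tf_promoters.tsv")
  )
  write_expression_matrix(dataset$enhancers, files$enhancers, "enhancer_id")
  write_expression_matrix(dataset$genes, files$genes, "feature_id")

  n_tfs <- nrow(dataset$anchors)
  prom_ids <- dataset$tf_table$promoter_id
  prom_pos <- seq_len(n_tfs) * 1000000L
  gene_ids <- setdiff(rownames(dataset$genes), prom_ids)
  tss <- data.frame(
    id = c(prom_ids, gene_ids),
    chrom = c(rep("chr1", n_tfs), rep("chr2", length(gene_ids))),
    start = c(prom_pos, seq_along(gene_ids) * 10000L),
    stringsAsFactors = FALSE)
  tss$end <- tss$start + 1L
  write_bed(tss, files$tss)

  enh_bed <- data.frame(
    id = dataset$anchors$enhancer_id, chrom = "chr1",
    start = prom_pos + 20000L - 500L, end = prom_pos + 20000L + 500L,
    stringsAsFactors = FALSE)
  write_bed(enh_bed, files$enhancer_bed)

  utils::write.table(dataset$tf_table, files$tf_promoters, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (tf in names(dataset$truth)) {
    f <- fp(paste0("truth_", tf, ".txt"))
    writeLines(dataset$truth[[tf]]$genes, f)
    files[[paste0("truth_", tf)]] <- f
  }
  invisible(files)
}
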