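# ernanet

Causal transcription-regulatory-network inference from enhancer RNA (eRNA)
activity.

Gene co-expression alone cannot tell whether a transcription factor (TF)
regulates a gene or merely co-varies with it. `ernanet` breaks that symmetry
with a *causal anchor*: the eRNA expression of an enhancer near the TF's
promoter, which is causally upstream of the TF it activates. For every trio
(enhancer *E*, TF *A*, candidate target *B*), five likelihood-ratio tests are
evaluated on rank-normalized expression:

1. primary linkage *E*→*A*: LLR = −(n/2)·ln(1 − ρ̂²EA)
2. secondary linkage *E*→*B*
3. conditional independence (the chain *E*→*A*→*B* as null)
4. relevance (*B* responds to *E* or *A*)
5. controlled test (*A*→*B* persists after conditioning on *E*, excluding
   pleiotropy *B*←*E*→*A*)

Under the null, LLR/n follows D(k₁,k₂) — a transformed Beta(k₁/2, k₂/2) via
x = 1 − e^(−2z) — giving exact p-values at small n. Per-test p-values pooled
over a TF's candidate targets are converted to empirical-Bayes posteriors
(local FDR with a Grenander density estimate), and combined into the
causality score

    P = ½ (P2·P5 + P4),

which is robust to hidden confounding between a TF and its targets; the
traditional score P2·P3 is available as a baseline. Enhancers can be treated
as continuous (dosage) or binary (on/off) anchors; the adaptive mode picks,
per TF, the enhancer × mode with the strongest primary linkage.

The package also implements the surrounding pipeline: CAGE-style expression
filters (TPM ≥ 1 gene filter with log2 transform, strict >n/3 enhancer
breadth filter), promoter selection by highest median, candidate-enhancer
assignment within 50 kb of the TF TSS, ground-truth derivation from ChIP-seq
peaks (TSS within 1 kb) or knock-out tables (q < 0.05), precision-recall and
BH-corrected hypergeometric evaluation, multi-enhancer consensus utilities,
and a seeded generator of CAGE-like synthetic datasets with known causal
structure.

## Worked example

```r
library(ernanet)

sim <- simulate_dataset(scenario_preset("confounded-network", seed = 11))
res <- infer_targets(sim$genes, sim$enhancers, sim$tf_table)
res$anchors[1:4, ]
#>   tf_id enhancer_id       mode primary_pvalue    status
#> 1  TF01    enh_TF01 continuous   1.368342e-08 predicted
#> 2  TF02    enh_TF02     binary   3.415606e-09 predicted
#> 3  TF03    enh_TF03 continuous   1.696256e-11 predicted
#> 4  TF04    enh_TF04     binary   3.289624e-10 predicted

pred <- threshold_predictions(res, 0.8)          # genes with score > 0.8
tab <- enrichment_table(pred, sim$truth, universe_n = nrow(sim$genes) - 1)
tab[1:4, c("tf_id", "overlap", "predicted_n", "truth_n", "pvalue", "qvalue")]
#>   tf_id overlap predicted_n truth_n        pvalue        qvalue
#> 1  TF01      71          71     100 1.136264e-107 2.272528e-107
#> 2  TF02      57          57     100  1.850528e-83  2.056142e-83
#> 3  TF03      87          87     100 4.335514e-139 4.335514e-138
#> 4  TF04      78          78     100 8.800073e-121 2.200018e-120
```

The adaptive selector chose the continuous mode for the dosage-acting
anchors and the binary mode for the on/off anchors (matching the simulated
truth for all 10 TFs), every predicted set is almost pure true targets, and
the BH-corrected hypergeometric q-values confirm the enrichment. On the same
seed, the pooled precision-recall area is 0.989 for the default combined
score versus 0.733 for the traditional conditional-independence score:

```r
bm <- scenario_benchmark(seed = 11)
#> AUPR default 0.989 vs traditional 0.733; mode accuracy 1.00
```

Real data enter through `read_expression_matrix()` (feature × sample TSV),
`read_bed()`, `read_tf_promoter_map()`, `read_ko_table()` and
`assign_candidate_enhancers()`; a thin command-line front end with
`simulate` / `infer` / `evaluate` subcommands lives at
`inst/cli/ernanet.R`.

## Documentation

The methods vignette (`vignettes/erna-causal-inference.Rmd`) describes the
model, the null family, the posterior scheme, the adaptive anchor selection,
every tunable parameter, what the synthetic generator does and does not
emulate, and the package's numerical choices.
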