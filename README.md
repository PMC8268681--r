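# switchscape

Antagonistic isoform-switch analysis for two-group RNA-seq cohorts — built
for the benign-versus-malignant design of melanocytic lesions (nevi versus
primary melanomas), usable for any transcript-level abundance matrix with
two sample groups.

## What it computes

Gene-level expression can hide complete rewiring of a gene's transcript
isoform composition. switchscape works on isoform fractions
`IF(i, s) = x(i, s) / Σ_{j ∈ gene} x(j, s)` and their group difference
`dIF = mean IF(tumor) − mean IF(benign)`, and covers four stages:

1. **Switch detection** — a label-permutation test on |dIF| per isoform
   (add-one p-values, BH FDR), then antagonistic pair calling: per gene,
   every (up, down) isoform pair with `dIF_up ≥ 0.1`, `dIF_down ≤ −0.1`,
   and `min(q_up, q_down) < 0.05`. Gene-level q by Bonferroni-scaled min-p
   plus BH.
2. **Consequence classification** — each pair is labelled from the
   up-isoform's perspective (ORF loss/gain, domain loss/gain, intron
   loss/gain, 3'/5'UTR shortening/lengthening ≥ 50 nt, length change), and
   genome-wide direction asymmetries are tested with exact binomial tests.
3. **Mutation association** — two length-controlled resampling statistics:
   a per-gene mutation-count-difference Z-score against 100 genes of
   similar median isoform length, and a per-isoform Jaccard index
   `J = |switched ∩ mutated| / |switched ∪ mutated|` over tumor samples,
   standardized against 200 length-matched switched isoforms. Both use the
   `z > 1.6` (90% band) significance rule.
4. **Enrichment and overlap** — hypergeometric overrepresentation of
   switched genes in GMT gene sets, and cross-contrast Venn counts.

A synthetic-cohort generator (`simulate_cohort()`) emulates the motivating
study design — 23 nevi vs 57 melanomas, 500 genes with 1–5 isoforms,
planted switches, length-dependent mutation burdens, planted
switch–mutation co-occurrence — with ground truth, so the whole pipeline is
testable offline.

## Worked example

```r
library(switchscape)
library(dplyr)

cfg <- sim_config(seed = 1, n_genes = 200, n_switch_genes = 20)
sim <- simulate_cohort(cfg)
fit <- detect_switches(sim$abundance, sim$samples,
                       contrast = c("nevus", "melanoma"),
                       n_perm = 999, seed = 2)
fit
#> Isoform switch fit: nevus vs melanoma
#>    428 testable isoforms in 200 genes
#>    20 switch pairs in 20 genes

tidy(fit) |> head(3)
#> # A tibble: 3 × 10
#>   gene_id up_isoform down_isoform dIF_up dIF_down  p_up p_down   q_up q_down
#>   <chr>   <chr>      <chr>         <dbl>    <dbl> <dbl>  <dbl>  <dbl>  <dbl>
#> 1 G0010   G0010.T1   G0010.T2      0.283   -0.283 0.001  0.001 0.0107 0.0107
#> 2 G0017   G0017.T1   G0017.T2      0.294   -0.295 0.001  0.001 0.0107 0.0107
#> 3 G0020   G0020.T1   G0020.T2      0.275   -0.277 0.001  0.001 0.0107 0.0107
```

All 20 planted switch genes are recovered, each as one antagonistic pair
with the usage change near the planted +0.3/−0.3 and both members
significant after FDR adjustment. Classifying their structural
consequences:

```r
features <- structural_features(sim$models, sim$domains)
rec <- classify_switch_consequences(tidy(fit), features)
summarize_consequences(rec) |>
  filter(category == "utr3_shortened")
#> # A tibble: 1 × 7
#>   category       opposite       genes_affected genes_opposite genes_tied fraction_of_genes asymmetry_p
#>   <chr>          <chr>                   <int>          <int>      <int>             <dbl>       <dbl>
#> 1 utr3_shortened utr3_lengthe…              11              7          0             0.611       0.481
```

11 of 18 UTR-classified switch genes shorten the up-isoform's 3'UTR — the
generator plants 60% shortening, and at n = 18 the exact binomial test is
(correctly) not yet significant. `autoplot(fit)` draws the
dIF-versus-significance volcano, `plot_consequence_summary()` and
`plot_jaccard()` the other result types, and `run_pipeline(config)` chains
every stage over files (GTF, expression/sample/mutation TSV, GMT) with
provenance headers and byte-reproducible outputs.

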