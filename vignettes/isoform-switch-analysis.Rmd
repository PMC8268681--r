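---
title: "Antagonistic isoform switches, their consequences, and mutation association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antagonistic isoform switches, their consequences, and mutation association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscape)
library(dplyr)
```

## The problem

Bulk RNA-seq of tumor and benign tissue is usually summarized at the gene
level, but a gene's total expression can stay flat while its transcript
isoform composition changes completely. In melanocytic lesions this matters:
a benign nevus and a primary melanoma can express the same gene through
different isoforms, with different untranslated regions, domains or even no
open reading frame at all. switchscape implements a complete analysis of
this phenomenon for a two-group cohort design (here: benign nevi versus
primary melanomas, 23 versus 57 samples): detection of antagonistic isoform
switches, classification of their structural consequences, gene-set
overrepresentation, and two resampling statistics linking switches to
somatic mutation burden.

## The switch model

For transcript $i$ of gene $g$ in sample $s$, the isoform fraction is

$$\mathrm{IF}_{i,s} = \frac{x_{i,s}}{\sum_{j \in g} x_{j,s}},$$

with $x$ a transcript-level abundance (TPM or comparable). The effect size
of differential transcript usage is
$\mathrm{dIF}_i = \overline{\mathrm{IF}}_i^{(B)} - \overline{\mathrm{IF}}_i^{(A)}$,
the difference of group-mean fractions. Because fractions sum to one within
a gene, $\sum_i \mathrm{dIF}_i = 0$: any upregulated isoform must be
balanced by downregulation elsewhere in the gene. An *isoform switch* is a
pair of isoforms of one gene with large opposite usage changes
($\mathrm{dIF}$ beyond $\pm 0.1$ by default) where at least one member is
statistically significant at FDR $q < 0.05$.

### Significance by permutation

Significance of each isoform's $|\mathrm{dIF}|$ is assessed by permuting
the group labels across samples (default 1000 permutations, explicit seed)
and applying the add-one estimator
$p = (1 + \#\{|\mathrm{dIF}^{\text{perm}}| \ge |\mathrm{dIF}^{\text{obs}}|\})/(n_{\text{perm}} + 1)$.
Ties count as exceedances, so $p$ is never 0 and the test is valid (a
constant isoform gets exactly $p = 1$). Missing fractions stay attached to
their samples during permutation, and permutations that leave a group with
fewer than two usable samples are excluded from that isoform's count. The
test assumes only group-label exchangeability under the null; its
calibration is itself part of the test suite (2000 simulated null isoforms
at the cohort's group sizes keep the empirical rejection rate at the
nominal level). This permutation design was chosen over a parametric
exon-usage GLM because it is self-contained, assumption-light, and its
calibration is directly testable.

Gene-level significance aggregates by a min-p statistic Bonferroni-scaled
by the gene's testable isoform count, then Benjamini-Hochberg adjustment
across genes. The provenance of a gene-level q in this kind of analysis is
generally tool-specific; min-p with Bonferroni scaling is the conservative
standard choice.

### Per-sample switch calls

The mutation co-occurrence statistic needs to know *which* tumor samples
carry a switch, a notion a group-level test does not define. We call sample
$s$ (in the second group) a carrier of isoform $i$'s switch when its
fraction deviates from the first group's mean in the direction of the
group-level $\mathrm{dIF}$ by at least $\tau = 0.1$. The threshold mirrors
the $\mathrm{dIF}$ threshold; it is a design decision (this quantity has no
canonical definition), and it is exposed as `tau_switch` everywhere.

## Consequence classification

Each switch pair is compared feature-by-feature from the perspective of the
up-regulated isoform: ORF loss/gain (coding flag), domain loss/gain (set
differences of the annotated domains — both can co-occur when the isoforms
carry disjoint domains), intron loss/gain (exon-count difference), 3'/5'UTR
shortening/lengthening and overall length change. UTR and length categories
require a minimum difference of 50 nt; annotation boundaries jitter by tens
of nucleotides between releases, and a smaller difference is not a
biologically meaningful shortening. UTR categories are only emitted when
both isoforms code: a non-coding transcript has UTR length 0 by convention,
and that 0 reflects the missing ORF (already captured as `ORF_loss`), not a
UTR change. "Length" is spliced transcript length; genomic span would count
introns and is not what microRNA-binding-site loss arguments care about.

Genome-wide asymmetries (e.g. "switches shorten 3'UTRs more often than they
lengthen them") are summarized per opposing category pair by counting genes
by their majority direction (ties dropped from the directional counts, kept
in the denominator) and testing with a two-sided exact binomial against
0.5. The exact test is chosen because the per-category gene counts are
small in realistic cohorts.

## Mutation association

Two bespoke resampling statistics link switches to somatic mutations, both
of which must control for gene length because mutation burden scales with
it:

1. **Gene mutation-count-difference Z-score.** For gene $g$,
   $\delta_g = c_g^{(B)}/n_B - c_g^{(A)}/n_A$ is the difference in average
   per-sample mutation count between groups. Each query gene is compared
   with $k = 100$ genes of similar median isoform length (within a
   multiplicative $\pm 20\%$ window, topped up with nearest genes by
   log-length distance when the window is sparse):
   $z = (\delta_g - \bar\delta_{\text{bg}})/s_{\text{bg}}$, significant at
   $z > 1.6$ (one-sided, matching a 90% confidence band; the threshold is
   kept verbatim rather than rounded to 1.645). The background is drawn
   from all annotated genes excluding the query — drawing from switched
   genes only would condition the null on the signal being tested.
2. **Jaccard co-occurrence.** For each switched isoform,
   $J = |S \cap M| / |S \cup M|$ where $S$ is the set of tumor samples
   carrying the per-sample switch and $M$ the set carrying a qualifying
   mutation in the isoform's gene ($J = 0$ for an empty union). The null
   distribution is the set of $J$ values of $k = 200$ other switched
   isoforms of similar transcript length (each isoform's own switch and
   mutation sets — the reading of a resampled-isoform null — rather than
   permuted sample labels), and $z$ and the 1.6 threshold are as above.
   The analysis is run once with coding mutation classes (missense,
   nonsense, splice site, synonymous) and once with 3'UTR mutations.

Both statistics are location- and scale-invariant in the deltas and
bit-reproducible given their seeds (each query uses `seed + i`).

## The synthetic cohort generator

`simulate_cohort()` produces annotation, expression, mutations and gene
sets with the statistical structure the analysis assumes, plus ground
truth, so every stage can be scored without external data. What it
emulates, and the defaults chosen once for the package:

- **Design**: 23 nevi, 57 melanomas; 500 genes with 1-5 isoforms
  (probabilities 0.25/0.3/0.2/0.15/0.1), spliced lengths roughly 0.5-2.5
  kb.
- **Expression**: gene totals are negative binomial (dispersion 0.3)
  around log-normal means (median 50, log-sd 1); per-sample isoform usage
  is Dirichlet with concentration 30 around group proportions, giving
  within-group isoform-fraction standard deviations of 0.07-0.09 —
  variability typical of bulk cohorts. In the 50 switch genes the melanoma
  proportions move `dIF_effect = 0.3` of usage mass from the down- to the
  up-isoform; all other genes share proportions across groups.
- **Consequences**: switch pairs are planted with exact counts — 10%
  ORF-loss pairs and, among the coding rest, exactly 60% with the
  up-isoform's 3'UTR shorter by 100-300 nt. Exact counts (rather than
  independent Bernoulli draws) make the planted asymmetry a fixed property
  of the dataset instead of a random variable, so recovery checks test the
  classifier, not the binomial noise of the plant.
- **Mutations**: per gene and sample, Poisson with mean 0.2 per kb of
  median isoform length (per-gene per-sample means of roughly 0.1-0.5, so
  per-gene mutated-sample fractions land in the tens of percent, the
  regime reported for RNA-seq-derived calls in such cohorts); 20 genes get
  a 3-fold melanoma rate. For 20 planted co-occurrence isoforms, melanoma
  samples carrying the ground-truth switch are mutated in that gene with
  probability exactly `cooccur_rho = 0.8` (their baseline draw is
  overridden so the co-occurrence level is interpretable); all other
  samples keep the baseline.

What it does **not** emulate: realistic splice-graph sharing of exons
between isoforms, mutation signatures and hotspots, expression-coupled
mutation calling sensitivity (RNA-seq calls depend on coverage),
batch/purity effects, or correlated genes. Passing recovery tests
therefore demonstrates that the statistics behave as designed under their
own assumptions — not that those assumptions hold in any real cohort.

## Numerical choices and degenerate inputs

- Isoform fractions are undefined (`NA`) where gene expression falls below
  `epsilon` (default 1 TPM): a ratio of noise to noise carries no usage
  signal. Low-expression transcripts (mean below 1 TPM) are removed
  outright.
- Permutation ties are counted as exceedances with a `1e-12` float guard.
- A degenerate Z background (`bg_sd = 0`) yields $z = \infty$ when the
  query exceeds the background mean and $z = 0$ otherwise, and is flagged.
- Length-matched sampling breaks ties in the nearest-neighbor top-up
  lexicographically by id, so selections are reproducible across platforms.
- BH adjustment runs over non-missing p-values only; untestable isoforms
  stay `NA` and do not count toward the number of tests.
- `run_pipeline()` caps the resampling sizes `k` at the available pool
  when a small cohort cannot supply 100 genes or 200 switched isoforms,
  with a message.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 200, n_switch_genes = 20)
sim <- simulate_cohort(cfg)
fit <- detect_switches(sim$abundance, sim$samples,
                       contrast = c("nevus", "melanoma"),
                       n_perm = 999, seed = 2)
glance(fit)
tidy(fit) |> head()
autoplot(fit)

features <- structural_features(sim$models, sim$domains)
rec <- classify_switch_consequences(tidy(fit), features)
summarize_consequences(rec) |> filter(genes_affected > 0)
```

Problem sizes in the package's own checks were chosen at desk scale: 2000
null isoforms for test calibration, 500-gene cohorts for switch and
co-occurrence recovery, 2000 genes for mutation-Z calibration. These are
large enough for the acceptance bands to be stable across seeds while a
full run of the suite stays in the minutes range.

## Known limitations

- The permutation test is exchangeable-null only; confounded designs
  (batch, purity) need covariate-aware methods upstream.
- Gene-level q-values inherit min-p conservatism for genes with many
  isoforms.
- The per-sample switch notion (`tau_switch`) is one reasonable reading of
  an under-specified quantity; Jaccard results should be interpreted
  relative to it.
- Domain annotations are consumed as given (e.g. precomputed Pfam scans);
  the package performs no sequence-level prediction of ORFs, domains or
  signal peptides.
- Multi-group designs are handled as pairwise contrasts, not jointly.
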