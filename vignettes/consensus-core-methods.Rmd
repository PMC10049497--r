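---
title: "Consensus core DEG analysis: models, parameters and design choices"
author: "concore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus core DEG analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concore)
```

## The problem

A single RNA-seq contrast — one knockout-versus-wild-type comparison in one
tissue, one cell fraction, one lab — gives a noisy and often irreproducible
list of differentially expressed genes (DEGs), especially for regulators
like MeCP2 whose transcriptomic footprint is broad but shallow (most
changes well under two-fold). When dozens of such contrasts exist across
public studies, a gene that is significant *repeatedly*, in a *consistent
direction*, is far better evidence of genuine regulation than any single
FDR cutoff. `concore` implements that consensus logic end to end, together
with the downstream characterisation and power analyses such a compendium
supports, and ships synthetic-data generators with planted ground truth so
every step can be validated against known answers.

## The consensus core model

Given per-contrast DE summaries (gene, log2 fold change, FDR), the pipeline
is:

1. **Masking.** Fold changes with FDR above a threshold $\alpha$ are set to
   0, giving a genes $\times$ contrasts matrix $M$ with
   $M_{gc} = \mathrm{LFC}_{gc}\,\mathbf{1}[\mathrm{FDR}_{gc} \le \alpha]$.
   A gene absent from a contrast's table is treated as non-significant
   there (entry 0), so the union gene universe keeps support counts
   well-defined.
2. **Direction harmonisation.** Gain-of-function contrasts (overexpression
   or duplication models) are expected to move targets in the opposite
   direction to loss-of-function models, so their columns are negated
   before aggregation. The operation is an involution and is applied
   before empty-contrast removal.
3. **Pruning.** Contrasts with no significant genes at $\alpha$ carry no
   information and are dropped.
4. **Support thresholding.** A gene's *support* is its number of non-zero
   entries; genes with support $\ge k$ form the core.
5. **Up/down split.** Each core gene's mean fold change over its
   *significant* entries only determines its direction. Masked zeros mean
   "not significant", not "no change": averaging them in would shrink
   means toward zero by an amount that depends on support, biasing the
   split.

Defaults are $\alpha = 0.01$ and $k = 4$, the operating point used by
large MeCP2 compendia (4 of ~40 contrasts, i.e. roughly 10% support).

### Choosing k from a fraction

When `min_fraction` is given instead of `min_contrasts`, we convert with
round-half-down: $k = \max(1, \lfloor f\,n + 0.5 - \varepsilon \rfloor)$.
Ceiling would turn "10% of 43" into 5 and miss the operating point such
analyses actually use (4); round-half-down reproduces 4-of-43 while still
flooring at 1 so small metadata subgroups (e.g. 3 nucleus contrasts at
10%) keep a usable threshold.

### Ties and degenerate cases

A core gene whose mean significant fold change is exactly 0 is assigned
"up" — a deterministic tie-break on a measure-zero event, messaged when it
fires. If every contrast is empty after masking, the pipeline stops with
an error rather than returning an empty core silently.

## Threshold grids, concordance, subgroups

`grid_core_counts()` reruns the full pipeline over an
$\alpha \times k$ grid; core size is non-increasing in $k$ and
non-decreasing in $\alpha$, which the tests assert on random fixtures.
`concordance_profile()` reports, per gene, the fraction of its significant
appearances that are upregulated — 0 or 1 means complete directional
consistency. `subgroup_core()` restricts to contrasts matching one
metadata value (cell fraction, tissue, ...) and re-derives $k$ from the
fraction on the selected subset.

## Biotype composition and positional analysis

Gene annotations are condensed into eight broad categories
(`gene_categories()`); `composition()` reports exact counts and fractions
of a gene set against that closed set, with unannotated genes tallied in a
flagged bucket.

For positional structure, core-up, core-down and background genes on a
chromosome are encoded as levels 6, 0 and 3 at their TSS (a spacing that
makes an up-enriched stretch raise the local mean and a down-enriched
stretch lower it, with background in the middle). `cbs_segment()` then
performs a simplified circular-binary-segmentation style search: within
each interval the candidate boundary maximising the pooled two-sample
t statistic is found, and the split is accepted when its within-interval
label-permutation p-value is at most `alpha_split`. The permutation null
re-maximises over all candidate boundaries in every permutation, so the
search itself is accounted for, and accepted parts are re-segmented
recursively. We deliberately do not reproduce the full production CBS
machinery (hybrid p-value pruning, undo steps): the target use is
detecting contiguous stretches of directional enrichment, for which the
permutation-t recursion suffices, and an exhaustive-search oracle in the
test suite guarantees the chosen split is exactly the maximal one.
Defaults: `alpha_split = 0.01`, `n_perm = 1000`, `min_len = 5`, linear
candidate boundaries (`circular = TRUE` enables true arc enumeration; a
linear split is the special case of an arc ending at the interval edge).
Constant intervals are never split (the t statistic is undefined there); a
perfect step yields an infinite t, which the permutation comparison
handles by counting ties.

## Pre-ranked enrichment

Genes are ranked by $-\log_{10}(\mathrm{FDR}) \times \mathrm{LFC}$, with
the FDR clamped at `pseudocount` ($10^{-300}$) so reported zero FDRs stay
finite, and score ties broken lexicographically by gene id so the ordering
is deterministic. Gain-of-function contrasts are harmonised by negating
scores *before* enrichment (`invert_scores()`); this flips the enrichment
score sign exactly (asserted in tests), so it is equivalent to flipping
reported scores afterwards while keeping the permutation null coherent.

The enrichment score is the weighted Kolmogorov-Smirnov running-sum
statistic: at set members the sum rises by $|s|^w / \sum_{hits} |s|^w$, at
non-members it falls by $1/(N - N_{hit})$; the ES is the signed maximum
deviation, and the walk always returns to zero. Weight $w = 1$ is the
conventional pre-ranked default; $w = 0$ gives the classic KS statistic.
If all hit scores are zero the hit increments fall back to equal weights
rather than dividing by zero. A set covering the whole list has no misses
and is rejected as degenerate.

Significance uses a gene-label permutation null of matched size
(`n_perm` draws), sign-stratified: $p = (1 + \#\{\text{same-sign nulls at
least as extreme}\}) / (1 + \#\text{same-sign nulls})$, so
$p \ge 1/(n_{perm}+1)$. NES divides the ES by the mean |null ES| of the
same sign, and FDR is the usual ratio of null-vs-observed NES tail
fractions pooled across sets, clipped to $[0,1]$. The null is evaluated
with a hits-only $O(|S|)$ formula that computes the identical statistic as
the full walk (equality asserted to $10^{-12}$ in tests), keeping
hundreds of calibration runs cheap.

## Overlap tests

`overlap_test()` partitions the stated universe into the 2x2 table and
reports the two-sided Fisher exact p, the upper-tail hypergeometric p, and
the sample cross-product odds ratio (Haldane 0.5 correction only when a
cell is zero; an overlap of zero reports an odds ratio of 0). The universe
is a required argument: whether "all genes" or "expressed genes" is the
right reference depends on how both sets were called, and defaulting it
silently would invite inflated significance.
`directional_overlap()` additionally stratifies by direction, testing
up-regulated DEGs against the up core and down against down — genes
changed the same way in both sets.

## The desk-scale DE caller

`nb_wald_test()` is a deliberately simple negative-binomial caller,
self-consistent across the power analysis (it is not, and does not try to
be, a re-implementation of a production DE package):

- **Normalisation** by median-of-ratios size factors, rescaled to unit
  geometric mean. With a doubled column the factors are exactly
  $(1/\sqrt2, \sqrt2)$, which the tests assert to $10^{-12}$, and the
  estimates match the reference implementation in DESeq2 up to that
  rescaling convention.
- **Dispersion** per gene by moments,
  $\hat\alpha = (s^2_{pooled} - \bar\mu \overline{1/s_j})/\bar\mu^2$
  floored at $10^{-8}$, then shrunk toward a fitted $a_0 + a_1/\mu$ trend
  with weight 0.4 on the per-gene estimate. Moment estimates at small n
  are noisy; the trend stabilises them enough for calibrated Wald tests
  (the null simulation in the test suite checks the type-I rate lands in
  [0.03, 0.08] at p = 0.05).
- **Effect and test:** log2 ratio of prior-count-damped group means
  (prior 0.5 on the normalised scale; identical groups give exactly 0),
  Wald z under the NB variance of each group mean, two-sided normal p,
  BH adjustment over filter-passing genes only.
- **Expression filter:** count $\ge$ 10 in at least half the samples, the
  common loose pre-filter; both knobs are exposed because the phrasing of
  such filters varies across pipelines and any variant is reachable via
  `min_count` / `min_fraction`.

## Down-sampling power analysis

`downsampling_experiment()` draws `n_reps` subsets of each per-group size
without replacement, renormalises within each drawing (size factors are
depth statistics of the drawn samples, so reusing full-data factors would
leak information), reruns the DE caller, and records DEG counts at the
FDR threshold for each fold-change ratio cutoff (1 = any change; 1.1 and
1.2 mean $|\mathrm{LFC}| \ge \log_2 1.1, \log_2 1.2$) plus the Rand index
against the full-data DEG calls. Per-(size, replicate) RNG sub-streams are
derived from the master seed, so extending `n_reps` never perturbs earlier
drawings. The Rand index treats the DEG indicator over all genes as a
two-cluster partition: the fraction of gene pairs whose co-membership
agrees, which is symmetric and invariant to complementing both vectors.

## What the synthetic data emulates — and what it does not

`generate_multi_contrast()` plants a fixed up/down core whose members are
significant in a Bernoulli(concordance) subset of contrasts with effects
$\pm\mathcal N(0.6, 0.2)$ in log2 units (mostly under two-fold),
background genes significant sporadically, and a configurable set of
contrasts generated sign-flipped to emulate gain-of-function models.
Defaults — 5,000 genes, 40 contrasts, 150 up + 120 down, concordance 0.6,
background rate 0.03, two inverted contrasts — mirror the scale and
noise regime of a real multi-study compendium at desk scale. FDR values
are drawn Uniform($10^{-6}$, $\alpha$) for significant entries and
Uniform($\alpha$, 1) otherwise: the pipeline only thresholds the FDR, so
only the mass on either side of $\alpha$ matters to recovery.

One deliberate design constraint: each background gene's support is capped
at 5% of the contrasts (excess significant entries are demoted at random).
Without the cap, independent per-contrast background significance at 3%
would give a few percent of background genes support $\ge 4$ purely by
chance — but a "background" gene significant in a tenth of all contrasts
*is* a consensus gene under the model's own definition, so the planted
truth labels would be incoherent rather than the pipeline wrong. The cap
makes the ground truth identifiable; it also means the generator does not
model a pathological scenario where spurious significance is both frequent
and recurrent (e.g. shared batch artefacts across studies). Recovery tests
passing here therefore show the pipeline correctly aggregates sparse,
independent noise — not that it is immune to correlated cross-study
artefacts, which no support threshold can distinguish from biology.

`generate_counts()` draws log-normal baselines (meanlog 4, sdlog 1.5),
inverse-gamma dispersions (mean 0.005, typical of high-count genes in
isogenic mouse bulk RNA-seq), log-normal size factors (sd 0.15) and NB
counts, planting DE in 10% of genes with signed half-normal (sd 0.3)
log2 effects. These defaults put the detection frontier at 10 replicates
near a 15-20% fold change, reproducing the regime in which no-cutoff DEG
counts keep rising with replicate number while a 20% fold-change cutoff
visibly flattens the curve. The generator does not simulate batch effects,
GC/length biases, or outlier samples; power conclusions transfer to real
data only to the extent that those artefacts are handled upstream.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while completing quickly on one
CPU: the 5,000-gene x 40-contrast compendium for recovery; 200-point
tracks with 300 permutations (50 replicates) for segmentation; 4,000 genes
x 10 + 10 samples for the null calibration; 5,000 genes x 20 + 20 samples,
sizes 10 down to 3 with 20 drawings each, for the power analysis; 200
random gene sets with 100 permutations each for enrichment calibration.
Exhaustive oracles (brute-force split search, hypergeometric enumeration,
literal running-sum walks) back the stochastic checks at small n.

## Known limitations

- The consensus support count weights every contrast equally; a study
  contributing many correlated contrasts is over-represented, and no
  meta-analytic effect-size model (weighting by precision) is attempted.
- The segmentation p-values are per-split and unadjusted across the
  recursion; they are acceptance gates, not genome-wide error rates.
- The NB caller's normal Wald reference is anticonservative at very small
  n and very low counts; the calibration checks cover the sizes used
  here, not n = 2.
- Ortholog translation keeps one row per target gene (minimum FDR,
  deterministic tie-breaks); many-to-many orthology is reduced, not
  modelled.
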