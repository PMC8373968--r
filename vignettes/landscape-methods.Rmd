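---
title: "Methods: cross-dataset lncRNA expression landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dataset lncRNA expression landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncLandscape)
```

## The problem

Tumour cohorts profiled on different platforms rarely cover the same
histological subtypes. In the thyroid-neoplasm setting this package is
built around, a deep RNA-seq cohort covers normal tissue (NT),
follicular adenoma (FA), follicular carcinoma (FTC) and the follicular
and classical variants of papillary carcinoma (fvPTC, clPTC); a second
RNA-seq cohort covers only NT and the two PTC variants; and a microarray
cohort is the only source of anaplastic carcinoma (ATC) samples, with
some genes simply absent from its probe set. The scientific questions —
which long noncoding RNAs are dysregulated *across* the benign-to-
malignant spectrum and which are *specific* to one subtype, and what
those lncRNAs plausibly do — therefore require combining
platform-specific differential expression, a cross-dataset validation
rule, a set-intersection classification, and guilt-by-association
functional inference. `lncLandscape` implements that pipeline as
tested, reusable stages and ships a synthetic-data generator with
planted ground truth so every stage can be scored.

## Preprocessing

**RNA-seq.** Genes are kept when at least `min_count` reads are seen in
at least as many samples as the smallest group ("detected in enough
samples to matter in the weakest comparison"). The phrase this rule is
usually stated with is ambiguous; we adopt the standard reading — keep
gene *g* iff `#{samples with count >= min_count} >= min(group sizes)` —
and expose both knobs. The default is `min_count = 2` for the deep
primary cohort and `1` for the shallower second cohort.

Scaling factors are trimmed means of M-values (TMM). The reference
sample is the one whose 75th-percentile count fraction is closest to
the mean of those fractions; per-sample M and A values are formed on
genes positive in both sample and reference; 30% of each M tail and 5%
of each A tail are trimmed; the factor is 2 to the inverse-variance
weighted mean of the surviving M values, and factors are rescaled to
geometric mean 1. All four constants are arguments. A consequence worth
stating because it is often guessed wrong: a sample in which a dominant
gene absorbs, say, 10% of the library gets a factor *below* 1 — its
remaining genes are under-represented relative to the reference.

Counts enter linear modelling as `log2 CPM` with a 0.5 pseudo-count,
and each observation receives a precision weight from the mean-variance
trend: per-gene residual standard deviations from a group-means fit are
square-rooted, smoothed against average log count by lowess with span
0.5 (the method's customary default; the trend is smooth and a wider
span only blurs it), and each fitted observation's predicted
square-root standard deviation is raised to the power −4. Predictions
are clamped to the lowess curve's endpoints so weights cannot blow up
by extrapolation at the abundance extremes.

**Microarray.** The package takes probe-level (or gene-level) log2
intensities as input and quantile-normalizes them: each column's sorted
values are replaced by the across-column means of sorted values, ties
receiving the mean of the reference values at their tied ranks.
Platform-specific background correction of raw probe intensities (e.g.
GC-content models fitted to CEL files) is deliberately out of scope:
the input contract is already-summarised log2 intensities, and quantile
normalization is the distribution-equalising step appropriate at that
level. This is a documented fidelity deviation from a full
CEL-file-based preprocessing chain. Probes are then collapsed to genes
by the per-sample **median** of a gene's probes. No collapse rule is
canonical; the median is robust to a single aberrant probe and
deterministic, which we value for reproducibility. Whether to normalize
before or after collapsing is equally open; we normalize at the level
supplied, then collapse. Genes with no probe are recorded per dataset —
the validation rule needs them.

## Differential expression

One group-means linear model is fitted per dataset per gene, by
weighted least squares when precision weights exist; every two-group
contrast is read off that single fit rather than refitting pairs. The
residual variances `s2_g` (df `n − k`) are moderated by an
empirical-Bayes scaled inverse chi-square prior estimated by the
closed-form method of moments on `log s2`: with
`e_g = log(s2_g) − digamma(df_g/2) + log(df_g/2)`, the excess of
`var(e)` over `mean(trigamma(df_g/2))` determines the prior degrees of
freedom `d0` through the inverse trigamma, and `s0^2` follows from
`mean(e)`. If the observed spread does not exceed pure sampling
variation, `d0 = Inf` and all genes share the prior variance. The
moderated t uses the posterior variance
`(d0 s0^2 + df s2) / (d0 + df)` on `d0 + df` degrees of freedom.
Forcing `d0 = 0` recovers the classical per-gene t exactly; forcing
`d0 = Inf` pools completely — both limits are exercised by tests.
`d0` is estimated once per dataset fit, not per contrast.

A gene is called differentially expressed when its Benjamini–Hochberg
adjusted p-value is at most 0.01 **and** `|log2FC| >= 1`. The
fold-change gate is two-sided: result tables in this literature list
strongly down-regulated genes (negative log fold change) as
differentially expressed, so "fold change at least 2" is read as
magnitude. Log fold changes are base 2 throughout, the convention of
the modelling framework used. FDR is computed per contrast over the
lncRNA universe of the dataset in question (the gene set actually under
study after biotype filtering); adjusting within each dataset rather
than globally mirrors how multi-cohort studies report per-dataset DE
censuses, and is recorded as an assumption.

lncRNAs are selected by biotype whitelist: lincRNA, antisense, 3-prime
overlapping ncRNA, bidirectional promoter lncRNA, misc RNA, processed
transcript, sense intronic, sense overlapping. Annotation exports mix
spelling dialects (`Sense_intronic`, `sense intronic`, hyphens), so
labels are canonicalised — lower case, separators stripped — before
matching; unknown labels are preserved and flagged, never silently
dropped.

## Cross-dataset validation and the category cascade

For the two subtypes covered by all three datasets (clPTC, fvPTC), a DE
call is **validated** when the gene is DE in all three datasets, or DE
in both RNA-seq datasets while absent from the microarray's probe set.
Measured-but-not-DE on the array fails validation. The rule is
presence-based: direction consistency across datasets is *not*
required (a stricter direction-consistent mode can be imposed by the
caller by pre-filtering calls). Validation is monotone — removing a DE
call can never validate a gene — which the tests verify exhaustively.

Each lncRNA is then assigned at most one category by a strict decision
cascade on its vs-NT DE pattern `P ⊆ {FA, FTC, fvPTC, clPTC}` in the
primary RNA-seq dataset (the only one covering all four), from most to
least inclusive:

1. `P` = all four, validated in both PTC variants → **common to FA and
   WDTC**.
2. `P` = {FTC, fvPTC, clPTC}, validated in both PTC variants, and each
   PTC variant DE vs FA → **common to WDTC**. The vs-FA requirement is
   imposed on both PTC variants but not on FTC.
3. `P` = {fvPTC, clPTC}, validated, and each variant DE vs FA and vs
   FTC → **common to papillary carcinomas**.
4. `P` a single PTC variant, validated, DE vs the three other subtypes
   → **specific to clPTC / fvPTC**.
5. `P` = {FTC}, DE vs both PTC variants → **specific to FTC**. No
   validation is possible for FTC (only one dataset covers it) and no
   vs-FA requirement applies; FTC-specific genes are typically
   indistinguishable from FA, which is biologically expected for a
   carcinoma whose benign counterpart FA is.
6. Anything else → none. A pattern with no category (say {FA, clPTC})
   falls through; clause failures never cascade into a *different*
   category.

Between-subtype significance uses the same thresholds as vs-NT calls
(FDR ≤ 0.01, |log2FC| ≥ 1); nothing in the design motivates a separate
threshold, and one fewer knob is one fewer way to overfit. Between-
subtype contrasts for differentiated subtypes are computed in the
primary RNA-seq dataset; ATC-vs-PTC contrasts on the microarray, the
only platform with ATC.

**ATC** is handled as a three-stage funnel: genes DE in ATC vs NT on
the array; minus genes DE in any differentiated subtype in any dataset;
intersected with genes DE in ATC vs both PTC variants. The stages are
returned so the monotone shrinkage can be inspected, and ATC-specific
genes are disjoint from every differentiated category by construction.

## Functional inference

Per category, the `k = 5` most differentially expressed lncRNAs are
selected by largest `|log2FC|` in the defining vs-NT contrast, ties
broken by smaller FDR then gene id. "Most differentially expressed" has
no canonical ranking statistic; magnitude-first matches how such tables
are usually presented, and the tie rules make the selection
deterministic. For each selected lncRNA, Pearson correlation against
every coding gene is computed across *all* samples of the designated
dataset (primary RNA-seq for differentiated categories, microarray for
ATC); whether tumours only or tumours plus normals is the better
universe is genuinely open, and all-samples is the default because the
anchor lncRNAs are themselves group-structured, so partners sharing
that structure are part of the association signal. Partners must pass
both gates: `|r| >= 0.7` and `p < 0.05` from the t transform
`t = r sqrt((n−2)/(1−r^2))`. The correlation p-values are **not**
multiplicity-adjusted — the gate mirrors the common practice it
emulates and is anticonservative; treat partner lists as candidate
sets, not inferences.

Enrichment of a partner list against a GMT collection is one-sided
over-representation: the hypergeometric upper tail `P(X >= overlap)`
with term members intersected with the universe first, BH-adjusted
within the collection (mirroring per-library adjustment of enrichment
services), significant at adjusted p ≤ 0.05. The universe is all coding
genes present post-filter in the designated dataset.

## The synthetic-data generator

The generator emulates the *structure* of the multi-cohort study: three
datasets with overlapping but non-identical subtype coverage, counts
for the RNA-seq cohorts, probe-level log2 intensities with incomplete
gene coverage for the array. Defaults (all `sim_config()` arguments):

| parameter | default | why |
|---|---|---|
| genes | 1200 coding + 800 lncRNA | desk scale; enough for stable variance moderation |
| groups | A: NT 20/FA 10/FTC 10/fvPTC 12/clPTC 15; B: NT 15/fvPTC 12/clPTC 15; array: NT 15/fvPTC 10/clPTC 10/ATC 10 | miniature of the real cohorts' coverage pattern |
| planted per category | 20, `log2FC ~ ±U(1.5, 3)` | clearly-expressed effects above the FC gate |
| NB dispersion | 0.1 | typical biological CV ~0.3 for human bulk tissue |
| array sigma | 0.5 | log2-scale noise of a well-behaved array experiment |
| baseline log2 mean, sd | 7, 1.5 | moderately expressed genes, wide abundance range |
| library-size lognormal sd | 0.15 | mild depth variation between libraries |
| probe-missing fraction | 0.1 | exercises the missing-probe validation branch |
| probes per gene | 1–3 | multi-probe collapse is actually exercised |
| module size / target r | 20 partners, r = 0.8 | detectable at ~60 samples with the 0.7 gate |
| GMT | 0.6 overlap, 40 background terms of 20–80 genes | planted terms detectable, background calibratable |

Planted effects are additive on the array's log2 scale and
multiplicative on count means, so "true log2FC" means the same thing on
both platforms. Each category's effect pattern is the archetype the
cascade should recover (e.g. a clPTC-specific gene has nonzero effect
in clPTC only), with one sign per gene across its affected subtypes.
One coexpression module per category is anchored on the category's
strongest lncRNA; its coding partners inherit the anchor's group-effect
profile (co-regulated genes track their regulator) and all members
share a per-sample latent factor `z ~ N(0,1)` with per-gene loading
`lambda_g = sd_g sqrt(r/(1−r))`, where `sd_g` approximates the gene's
log2-scale noise standard deviation (`sqrt(1/mu + phi)/ln 2` for
counts, the collapse-adjusted `array_sigma` for probes). Two module
genes then correlate at about the target `r` within a sample group, and
slightly above it across groups.

Probe-missing genes are drawn only from genes with no planted role that
exists *solely* on the array: ATC effects and the array-designated
module live nowhere else, so a study of them is by construction
confined to probe-covered genes, whereas losing the array probe of a
PTC-planted gene is exactly what the missing-probe validation branch is
for.

Determinism: every stochastic stage draws from a named substream
(`truth`, `rnaseq:<id>`, `array:<id>`, `module:<dataset>:<module>`,
`gmt`, `annotation`) derived from the master seed by an exact integer
hash, so identical configurations reproduce byte-identical studies and
adding a dataset does not shift the sampling of existing ones.

What the generator does **not** emulate: batch effects between array
experiments, GC or probe-sequence bias, aligner and counting artefacts,
correlated gene-gene background structure beyond the planted modules,
and the long-tailed annotation mess of real genomes. Passing tests
therefore demonstrate that the pipeline's logic and statistics recover
structure *of the kind planted, at the planted magnitudes*; they are
not evidence about robustness to real-data pathologies outside that
envelope.

## Numerical and testing choices

- Quantile-normalization ties take the mean of the reference values at
  the tied ranks; the "identical sorted columns" invariant is exact
  only in the absence of ties.
- TMM returns factor 1 for a sample whose trimmed M values are all
  below 1e−6 in magnitude; all-zero samples are a hard error.
- Moderation excludes genes with zero residual df; variances below
  1e−5 of the median are floored before taking logs.
- Zero posterior variance with a nonzero effect yields p = 0 (a
  "certain" call) rather than NaN; this only arises in degenerate
  noiseless fixtures.
- The decision cascade is evaluated per gene and is order-independent;
  between-subtype DE flags are orientation-symmetric, so either
  contrast direction satisfies a rule's requirement.
- The test suite runs the full pipeline on ten replicate studies at the
  default configuration (2000 genes, ~150 samples across three
  datasets), plus closed-form oracle checks: brute-force BH step-up,
  exhaustive hypergeometric tails, a hand-enumerated validation truth
  table, and the classical-t and pooled-t limits of the moderated
  statistic. Reference implementations of TMM, precision weights and
  variance moderation from the established differential-expression
  packages serve as independent cross-checks, never as the
  implementation.

## Limitations

- No covariate adjustment, paired designs, or between-dataset batch
  correction: datasets are analysed separately and only DE *calls* are
  merged, so systematic between-platform differences never touch the
  statistics, at the price of ignoring shared samples if any existed.
- The correlation gate's unadjusted p-values and the all-samples
  correlation universe make partner lists anticonservative by design.
- The validation rule is presence-based; a gene DE up in one dataset
  and down in another can validate.
- Array preprocessing starts from supplied log2 intensities; raw-file
  background correction is out of scope.
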