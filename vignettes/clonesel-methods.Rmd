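---
title: "Quantifying somatic selection in UV-exposed epidermis and tumors"
author: "clonesel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic selection in UV-exposed epidermis and tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chronically UV-exposed skin becomes a dense patchwork of somatic mutant
clones long before any tumor appears. Deep targeted sequencing of small
tissue samples (1–2 mm² epidermal grids, 50 µm tumor cryosections at
roughly 930x) reveals these clones as low-frequency variant reads. Two
questions drive the analysis this package implements:

1. **Which mutant genes are under selection?** Measured two ways: a
   trinucleotide-context-normalized dN/dS per gene and mutation class, and
   the ratio of summed variant allele frequencies of nonsynonymous to
   synonymous mutants (VAF~ns~/VAF~s~).
2. **How much tissue have mutants taken over, and how do tumors relate to
   the epidermis they arose from?** Answered with summed-VAF colonization
   estimates, copy-number profiles from binned off-target coverage, and a
   rule-based multi-region clonality classifier.

Everything is exercisable on a bundled synthetic-data generator with known
ground truth, so each estimator's calibration and power can be verified
without any sequencing data.

## Variant calling: a site-specific beta-binomial error model

Subclonal calling at ~930x requires separating real 0.5–2% VAF clones from
context-specific sequencing error. `fit_background_panel()` pools a panel
of normal samples per site and substitution and fits a beta-binomial by
the method of moments — mean error `mu` from the pooled alt fraction,
overdispersion `rho` from the between-sample variance of proportions,
floored at 1e-9 so clean sites degrade gracefully to a binomial.
`call_variants()` computes a one-sided upper-tail p-value for each
observed alt count, applies Benjamini–Hochberg across all tested
site-substitutions, and emits calls at `q <= fdr_alpha` (default 0.05)
with at least one supporting read on each strand. On synthetic panels
matching the study depth the detection limit is a VAF of about 1%, i.e. a
heterozygous clone occupying ~2% of cells.

Five post-calling filters are applied in a fixed order by
`apply_filters()`:

1. sites with depth < 100 are dropped;
2. germline variants of the same animal are removed;
3. FDR and both-strand support are re-checked;
4. adjacent SNV pairs in one sample merge into a double-base substitution
   (DBS) when at least 90% of the reads covering either site carry both;
5. identical mutations in contiguous biopsies merge into one clone record
   (summed alt and depth) so a clone spanning several grids is not
   counted repeatedly.

Read-level co-occurrence is not recoverable from a count table, so rule 4
bounds the joint-read fraction by `min(alt1, alt2) / max(alt1, alt2)` —
the value obtained when the overlapping reads are nested maximally — and
accepts an explicit `joint` column when the caller can supply one.
"Contiguous" is an explicit adjacency map supplied with the sample table;
no geometry is inferred from sample names.

## Selection: context-normalized dN/dS

For gene *g* and class *c* (missense; nonsense + essential splice,
pooled; indel):

$$\mathrm{dN/dS}_{g,c} = \frac{n_{g,c} / E_{g,c}}{n_{g,\mathrm{syn}} / E_{g,\mathrm{syn}}}$$

Expected counts come from exhaustive enumeration of every possible
substitution in the coding sequence (plus the two intronic bases flanking
each exon boundary, classed essential splice), weighted by a 96-channel
trinucleotide spectrum fitted from synonymous calls only
(`fit_spectrum()`). Synonymous sites are the neutral reference: their
channel counts divided by channel opportunities estimate the local
mutation rate free of selection. Zero-count channels receive a 0.5
pseudocount; channels with no synonymous opportunity in the panel borrow
their substitution type's average rate rather than the global mean —
borrowing the global mean would leak the dominant C>T channels' rate into
rare contexts and bias expected counts upward by several percent, which
we verified on neutral simulations.

Significance uses a Poisson likelihood-ratio test of ratio = 1, with
Benjamini–Hochberg correction per class across genes. This is a
deliberate simplification of dNdScv's negative-binomial gene-rate model:
the panel here is small (74 genes), the mutation counts are large, and
per-gene rate covariates are out of scope. Only the nonsense/essential
splice ratio drives labels — missense dN/dS is reported but unlabeled,
since a gene harbouring both gain- and loss-of-function missense mutants
can show a misleading missense ratio. The label thresholds are the
study's: positive when dN/dS > 1.3 and q < 0.01, negative when
dN/dS < 0.6 and q < 0.01.

Genes with no synonymous calls fall back to the panel-wide synonymous
rate (flagged `syn_zero`); classes with zero enumerated opportunity are
flagged `no_opportunity` rather than divided by.

Calibration and power, verified by the test suite on neutral and selected
simulations: per-gene dN/dS mean within ±0.1 of 1 across 200 neutral
genes with type-I error ≤ 1% at q < 0.01; genes simulated with 3-fold
nonsense enrichment (~400 mutations/gene over a 20-gene panel) are
labeled positive in ≥ 80% of replicates, and 5-fold depleted genes
negative in ≥ 80%.

## Selection: the VAF ratio

The second metric compares clone sizes directly:

$$\mathrm{VAF_{ns}/VAF_{s}} = \frac{\sum \mathrm{VAF\ of\ nonsynonymous\ clones}}{\sum \mathrm{VAF\ of\ synonymous\ clones}}$$

per gene, with a two-tailed Wilcoxon rank-sum test on the per-clone VAF
lists (exact when both classes have ≤ 25 clones and no ties, normal
approximation with continuity correction otherwise; the exact branch is
validated against full permutation enumeration in the tests).

One subtlety is documented here because it matters for interpretation:
the *raw* summed ratio is only centred at 1 under neutrality when the two
classes have equal mutation counts. A typical gene offers roughly three
nonsynonymous sites per synonymous site, so neutral passengers give a raw
sum ratio near 3 — mutational opportunity, not selection. `vaf_ratio()`
therefore also reports `ratio_per_clone` (mean VAF~ns~ / mean VAF~s~),
whose neutral expectation is 1 regardless of the count imbalance; this is
the neutrality-calibrated statistic the acceptance script reports. Even
this ratio carries a small positive finite-sample skew (Jensen's
inequality applied to the synonymous denominator: with $k$ synonymous
clones of exponential size the expectation is $k/(k-1)$, e.g. 1.11 at
k = 10), which is visible in the neutral replicate simulations and is not
corrected away.

## Colonization and tumor stratification

In a diploid tissue each heterozygous mutant cell contributes half its
reads, so the summed VAF of protein-altering mutations in a gene is
proportional to the mutant area. `colonized_fraction()` reports, per
aggregation unit, the area-weighted mean summed VAF with bounds
reflecting copy-number and nesting uncertainty: point and upper =
min(100, 2·ΣVAF·100) (heterozygous, disjoint clones); lower =
min(100, ΣVAF·100) (homozygous and/or fully nested clones). The ×2/×1
convention is the standard diploid reading and is configurable in spirit
— the bounds' ordering, not their exact arithmetic, is the robust claim.

`trp53_stratify()` labels a tumor low for a gene when its summed
nonsynonymous VAF is strictly below the same-animal epidermis value; ties
go to high, because "lower than" is a strict comparison.
`compare_gene_groups()` contrasts two tumor groups per gene with a
two-tailed Z-test (group variances from per-tumor values) and
Benjamini–Hochberg correction; genes with q < 0.05 are outliers.
`cohort_test()` wraps the routine cohort statistics (Wilcoxon,
Kruskal–Wallis, nested ANOVA with the animal as error stratum, two-group
F test, linear regression with r²) by delegating to the standard R
implementations.

## Copy number

`compute_logr()` forms log2(tumor/normal) per 100 Kb bin, median-centres
it and removes GC bias by subtracting the median logR within GC deciles
(bins with zero normal coverage are masked). `segment_logr()` minimises

$$\sum_{\mathrm{segments}} \sum_{i \in \mathrm{seg}} (x_i - \bar{x}_{\mathrm{seg}})^2 \;+\; \gamma\, \hat\sigma^2\, (\#\mathrm{changepoints})$$

by exact dynamic programming per chromosome, with segments of at least
`k_min` bins and $\hat\sigma$ a robust MAD-of-first-differences noise
estimate, so γ is expressed in units of noise variance and transfers
across tracks of different depth. The default γ = 30 with `k_min` = 3
favours chromosome-scale events; γ = 10 admits noticeably more short
segments. The DP is validated against exhaustive enumeration of all
segmentations on small tracks, and segment counts are non-increasing in γ
by construction of the penalty.

`call_segments()` classes a segment by its median logR (less
outlier-sensitive than the mean) against ±0.2 — between noise and a
one-copy gain at log2(3/2) ≈ 0.585 in pure tumor, configurable — and
reports the fraction of genome altered. `sweep_segmentation()` reruns the
same track across γ ∈ {10, 30, 50, 100} (plus `k_min` = 2) and summarises
each run by segment counts, length-class composition
(<1 / 1–10 / 10–50 / >50 Mb as percent of summed length) and
gain/loss/normal composition by summed length; on chromosome-scale
simulated events the class composition is stable within ±2 percentage
points across the sweep, which is the robustness property the sweep is
designed to demonstrate.

Sub-bin events are invisible by construction; fraction-altered estimates
are lower bounds.

## Tumor clonality

`classify_tumor()` applies the priority-ordered rules to per-slice SNV
sets and CNA segment lists. Monoclonal, in order: (M1) ≥ 5 shared SNVs
and a shared CNA > 10 Mb in all slices; (M2) ≥ 20 shared SNVs; (M3) ≥ 5
shared SNVs after dropping edge slices with no detected SNVs or CNAs
(a slice cut beyond the tumor boundary is entirely normal tissue);
(M4) ≥ 5 shared SNVs with a CNA-quiet genome. Multifocal: (F1) no shared
SNVs or CNAs, and two slices with separate (pairwise-disjoint) ≥ 5-SNV
sets and separate CNAs > 10 Mb; (F2) two slices with separate ≥ 5-SNV
sets and no CNA > 10 Mb anywhere. Remaining tumors with two separate
≥ 5-SNV expansions but conflicting CNA evidence are assigned multifocal
by a deterministic fallback — replacing a manual-review step — and carry
the rule tag `F-fallback` so a human can revisit them.

Design choices: a shared SNV is an exact (chrom, pos, ref, alt) match in
every informative slice with no extra VAF threshold; a shared CNA is a
same-class segment with ≥ 50% reciprocal overlap in every slice, since
exact breakpoint matching is unrealistic at 100 Kb resolution. All rules
are symmetric in the slices, so slice order never changes the label.

## The synthetic-data generator

`sim_params()` defaults encode the study conditions: mean depth 931,
a 74-gene panel of 300-codon genes, 30 SBS/Mb with 85% C>T (dipyrimidine
contexts preferred 4:1 within the C>T class), 0.7 DBS/Mb of which 35%
are CC>TT, 0.15 indels/Mb, per-substitution error 1e-4 with mild
overdispersion (rho 1e-3), and 1–2 mm² grids. Clone cell fractions follow
Exponential(mean 0.01), the simplest monotone fitness-to-size law; a
selection coefficient *s* on a gene class multiplies both the detected
mutation rate and the mean clone size by exp(s). Reads are binomial at
Poisson depth with an unbiased Binomial(alt, 1/2) strand split plus
independent error reads. Tumors plant one founder (monoclonal) or two
founders with disjoint SNV sets and CNAs on different chromosomes
(multifocal) across slices, plus private subclones, and emit binned
coverage with a linear GC confound for the CNA chain.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: spatially explicit clone competition and
merging, UV dose–response kinetics, mapping artefacts and alignment
error, purity gradients within a slice, and the empirical clone-size
distribution of real epidermis (the exponential is a stand-in, not an
inference). Parameter-recovery results should be read as verifying the
estimators' statistical behaviour under the stated generative law, not as
biological claims.

## Numerical choices and problem sizes

- All in-memory coordinates are 0-based half-open; every file written or
  read is 1-based inclusive. Conversion happens only at the IO boundary.
- Beta-binomial tails are exact sums (depths ≤ a few thousand), with a
  binomial shortcut below rho = 1e-12.
- Stage seeds derive deterministically from the master seed, so any stage
  can be rerun in isolation and two runs of `run_pipeline()` with one
  configuration are byte-identical.
- The test and acceptance simulations use desk-scale sizes chosen to make
  the Monte-Carlo error comfortably smaller than the tolerance being
  checked: 20 genes × 300 codons and 5,000 mutations for neutral dN/dS
  calibration; 8,000 mutations (~400/gene) for the selection power
  checks; 200 replicate samples per spiked VAF for caller sensitivity;
  500 replicates for VAF-ratio neutrality; 600-bin chromosomes for
  segmentation.

## Known limitations

- The caller is a simplified one-sided tail test, not ShearwaterML's full
  likelihood-ratio formulation; indels are accepted as already-typed
  records, not called from reads.
- dN/dS omits gene-level rate covariates; strong regional mutation-rate
  variation would inflate both tails.
- Colonization bounds assume a diploid genome outside declared CNAs.
- The Wilcoxon on VAF ratios pools clones per timepoint across animals;
  pooling per animal would be the alternative reading and is not
  implemented.
- The CNA chain estimates total copy state only — no allele-specific
  state, purity or ploidy fitting.
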