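---
title: "Methods: characterizing and filtering false-positive bacterial variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing and filtering false-positive bacterial variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpfilter)
```

## The problem

Variant calling from bacterial short-read data is routinely post-processed
with *hard filters*: fixed thresholds on per-call statistics intended to
discard false-positive (FP) calls while sparing true positives (TPs). The
choice of filter is entangled with the choice of pipeline, because callers
differ in which INFO/FORMAT tags they report and in what those tags mean.
`fpfilter` implements the full benchmarking loop needed to evaluate such
filters on a haploid genome:

1. build a truth set and a confident-region BED from the consensus of
   whole-genome-alignment call sets (plus pileup-based assembly masking);
2. normalize and label pipeline calls as TP/FP against that truth;
3. extract nine positional characteristics across caller tag dialects;
4. apply hard filters, either independently or with proximity filters
   ("thinning") deferred to a second stage;
5. summarize filter efficacy: percent of FPs removed, percent removable by
   no other filter, and the value-added ratio.

A seeded synthetic generator replaces the sequencing data, so every stage is
testable offline.

## Truth sets from alignment consensus

Aligning a closed assembly to a reference under *n* different parameter
settings yields *n* VCFs. Variants present in all *n* (matched allele-aware
on (chrom, pos, ref, alt) after left-alignment and decomposition) form the
consensus truth set; variants present in some but not all are
parameter-sensitive. The reference footprints of the latter define the
*ambiguous positions*; their complement over the contigs is the
*confident regions* BED, and only calls inside it are scored.

Two numerical conventions matter here:

* **Coordinates.** VCF records are 1-based; all emitted BED intervals are
  0-based half-open. Internally every interval is a 1-based closed
  `GRanges`.
* **Masking boundary.** Pileup masking discards positions with no coverage
  or where the modal base is *strictly* below 99 % of depth: a site at
  exactly 0.99 is kept. Discordant negative-control calls are masked over
  their full reference footprint (anchor through last deleted base).

One corner case is resolved in favour of the partition invariant: with
allele-aware matching, a site can carry a consensus allele *and* a
discordant alternative allele seen in only some VCFs. Such a site is
parameter-sensitive, so the consensus variant is dropped and the site stays
ambiguous; every truth variant therefore lies inside the confident regions,
and `tp + fn` always equals the confident-region truth count.

## Comparison semantics

Comparison is exact key matching on a haploid genome — all study-type data
are haploid and calls are effectively homozygous, so no haplotype-graph
reconstruction is needed. Calls with FILTER other than `PASS` are ignored
(a `.` FILTER counts as pass: the column, *if populated*, must be PASS).
Calls overlapping ambiguous positions are excluded from every count.
Precision is TP/(TP+FP), recall TP/(TP+FN), F-score their harmonic mean;
0/0 is reported as unavailable, never as 0.

The *characterization subset* — the calls whose characteristics feed the
efficacy analysis — additionally requires: biallelic source record (a
multi-ALT record excludes all of its split calls), class SNP/INS/DEL, not
derived from decomposing an MNP, and ACGT-only alleles. False negatives are
counted for metrics but carry no evidence and never enter the efficacy
analysis.

## The nine characteristics

| characteristic | definition | unavailable when |
|---|---|---|
| `qual` | Phred-scaled QUAL | QUAL is `.` |
| `qd` | quality by depth: QD-style tag, else `qual/alt_reads` | neither route available |
| `vaf` | `alt_reads/depth`, else a VAF tag | counts and tag missing |
| `depth` | total reads at the locus (dialect tag) | tag unmapped |
| `alt_reads` | variant-supporting reads | tag unmapped |
| `dist_snp` | bp to nearest *other* SNP call | no SNP neighbour on contig |
| `dist_indel` | bp to nearest indel call | no indel neighbour |
| `strand_min_pct` | `100*min(F,R)/(F+R)` over variant-supporting reads | strand tags unmapped |
| `direction_min_pct` | same over left/right placement counts | placement tags unmapped |

Unavailability is a first-class state distinct from zero: a filter is simply
*not applicable* to a call whose characteristic is unavailable, which is why
every efficacy column carries its own denominator.

Design choices where the field leaves room:

* **QD fallback.** When no QD-style tag exists, `qual/alt_reads` is used
  (average quality per variant-supporting read). GATK's own QD divides by
  *filtered* depth; the fallback route is recorded in `qd_source` so the two
  are never silently conflated.
* **Strand/direction percentages** are computed over variant-supporting
  reads (the Freebayes `SAF/SAR`, `RPL/RPR` convention), not all mapped
  reads; 50 % means perfectly balanced support, and the statistic is ≤ 50
  by construction.
* **Distances** are measured between anchor positions of the normalized
  (left-aligned) records, over neighbours of the relevant class at a
  *distinct* position — split alleles of one multi-allelic site are not
  each other's neighbours, keeping distances ≥ 1.

## Hard filters and thinning

All filters are inclusive minimum-threshold rules (`value <= threshold`
discards). The default SNP set: qual ≤ 30, qd ≤ 1, vaf ≤ 0.95 (fraction,
not percent), depth ≤ 5, alt reads ≤ 5, dist to SNP ≤ 3 bp, dist to indel
≤ 10 bp, strand and direction minima ≤ 5 %. Indels use qual ≤ 20, vaf
≤ 0.95, depth ≤ 10, both proximity rules, and strand ≤ 5 %, with no qd,
alt-read or direction filter. These defaults are illustrative, not
optimized, and are fully config-overridable.

Two application modes:

* **independent** — every filter sees the raw call set; this is the mode
  efficacy report tables assume (the OR-combined row's provenance in the
  source report is not stated, so independent is the default for
  table-style reports);
* **sequential** — proximity filters run after all others, on distances
  *recomputed over the survivors* (within one VCF). This is the
  recommended practice: a TP next to a low-quality FP is not thinned away
  once the FP has already been removed. When stage 1 removes nothing the
  two modes coincide, and sequential mode never removes more calls than
  independent mode.

## Efficacy statistics

Per filter and label stratum, over the calls the filter applies to:
removed count and percentage; *uniquely* removed count (removed by this
filter and by no other applicable filter — the denominator is the filter's
own applicable total); and the **value-added ratio**, %FP-removed divided
by %TP-removed. The `"any"` row OR-combines all filters with the full
stratum totals as denominators.

Report mode rounds percentages half-up to 2 decimals and computes ratios
from the *rounded* percentages, because published tables of this kind print
quotients of rounded values (e.g. 26.70/1.19 = 22.44); an exact mode
(`digits = NA`) is also provided. One published composition figure
(FP indels as a share of all indel calls) reproduces from its own printed
totals only under truncation: 246852/463386 = 53.2714 %, printed as 53.2 %.
The package reports the exact quotient.

## The synthetic generator

The generator emulates exactly the statistical structure the analysis
consumes — VCF tag values, not reads. Defaults, and what they model:

| parameter | default | rationale |
|---|---|---|
| genome | 1 contig, 100 kb, uniform ACGT | desk-scale stand-in for a ~4 Mb bacterial chromosome |
| truth density | 300 SNPs + 30 indels / 100 kb | middle of the benchmarked range (19–83 385 SNPs, 13–381 indels per genome) after scaling |
| recall | 0.95 SNP / 0.90 INDEL | high-performing pipelines; indel calling is harder |
| FP rate | 5e-4 SNP / 5e-5 INDEL per base | tens of FPs per 100 kb, enough signal at desk scale |
| TP depth | NB(mean 60, size 10) | high-depth sequencing after downsampling |
| TP qual | Gamma(4, scale 50), VAF = 1 | confident haploid calls, well above the 30 threshold |
| deficient FP | depth ~ max(1, Pois(3)), qual ~ U(0, 40), VAF ~ U(0.5, 1), strand bias 0.9 | "data-deficient" class: caught by minimum thresholds |
| surfeit FP | depth ~ TP mean + (4–10) sd, qual ~ U(500, 2000), VAF = 1 | "data-surfeit" class: reference copy-number artefacts with abundant clean evidence |
| FP mix | 80 % deficient / 20 % surfeit | deficient class is the larger one |
| clustering | p_near = 0.3 within 10 bp of a truth indel | FPs concentrate near indels |
| ambiguous fraction | 1 % of the genome, 50 bp blocks | small parameter-sensitive remainder |

Three generator decisions are conventions, not claims about data:

* the deficient/surfeit split point (`depth > mean + k·sd`) is a labeled
  convention — the field offers no quantitative definition;
* only deficient FPs cluster near indels; surfeit FPs are placed with a
  > 10 bp margin from every other call, because the class models reference
  errors rather than alignment turbulence, and because by construction they
  must be invisible to *all* minimum-threshold filters, proximity included;
* all calls are placed inside confident regions at distinct, non-truth
  positions, so the comparator must recover the generator's sidecar labels
  exactly — this label-recovery identity is what oracle-checks the
  comparator.

What a green synthetic test does **not** establish: realism of read-level
error processes (none are modelled), caller-specific depth bookkeeping,
linked errors from a common misassembly, or performance on real divergence
between sample and reference. The generator's job is to make the
*bookkeeping* falsifiable, not to imitate a sequencer.

## Numerical and degenerate-input choices

* Half-up rounding (`round_half_up`) with a 1e-9 nudge against binary
  representation error; base R's banker's rounding would not reproduce
  printed report values.
* Left-alignment follows the standard trim-suffix / extend-left / trim-prefix
  algorithm and refuses to shift past the contig start; it is idempotent.
* Empty call sets flow through: empty efficacy table, empty histograms,
  all-`NA` distances; zero-variant configs give a full-genome confident BED.
* `value_added_ratio` is unavailable when the (rounded) TP percentage is 0
  rather than infinite.
* Multi-contig truth densities are apportioned by contig length with
  rounding; the single-contig default is exact.

## Limitations

* The comparator is an exact key matcher; complex representational overlap
  between query and truth beyond normalization is out of scope.
* No learned (SVM/VQSR-style) classification and no default maximum-depth
  filter: the data-surfeit class is deliberately left uncaught, mirroring
  the blind spot of minimum-threshold filtering.
* Dialect configs cover tag *location*; they cannot reconcile semantic
  differences in how callers count depth.
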