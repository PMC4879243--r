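---
title: "islandmark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{islandmark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandmark)
```

## Scope

islandmark implements a window-based ChIP-seq analysis chain for a
promoter-binding factor profiled together with a knockout background:
island calling against dual controls, genome feature annotation,
tag-density metaprofiles, interval-overlap accounting, and integration of
binding with WT/knockout expression fold changes into a direct-target gene
list. A synthetic-data generator with planted truth makes every stage
testable at desk scale; nothing in the package depends on downloaded
sequencing data.

## The island-calling model

Tags are the 5' positions of uniquely mapped reads. For a ChIP sample with
$T$ tags on a genome of $L$ bp, tags are summarized in non-overlapping
$w$-bp windows (default $w = 200$). Under the background model the count in
a window is Poisson with mean $\lambda = T w / L$, estimated genome-wide
from the ChIP sample itself. A window with count $c$ is *eligible* when
$P(X \ge c \mid \lambda) < p_0$ (default $p_0 = 0.2$); eligibility is only
a pre-filter, significance always comes from the controls.

Runs of eligible windows in which consecutive eligible windows are at most
$g$ bp apart (default $g = 200$, one intervening window) are merged into a
candidate island spanning whole windows. The island score is
$\sum -\ln P(X \ge c_i \mid \lambda)$ over its eligible windows; gap
windows contribute nothing, so the score is exactly additive over eligible
windows.

Each candidate island is tested against every control sample. With $n$
ChIP tags and $m$ control tags in the island, and depth ratio
$r = T_\mathrm{chip}/T_\mathrm{ctrl}$, the ChIP count is referred to a
Poisson law with mean

$$\mu = r \cdot \max(m,\; b/r,\; 1), \qquad
  b = T_\mathrm{chip} \cdot \mathrm{len}/L ,$$

i.e. the scaled control count floored at the genome-wide ChIP background
expectation $b$ for the island's length (and at one control tag, so an
empty control cannot produce a zero expectation). The background floor is
the same device sharp-peak callers use for their local lambda: a control
count that randomly fluctuates low would otherwise make the Poisson test
anti-conservative, and at an island FDR of $10^{-5}$ even a small
anti-conservative bias produces false islands on pure background. With the
floor, pure-Poisson data (two 5-Mb chromosomes, $2\times10^5$ tags per
sample, two controls) yields zero islands in essentially every run — the
behavior the test suite asserts.

P-values are Benjamini–Hochberg adjusted across all candidate islands,
separately per control. In the default control mode (`"each"`) an island
must pass `q <= fdr` (default $10^{-5}$) against *every* control — the
stricter reading of calling against both an input sample and a knockout
ChIP — and a pooled mode is available that combines the controls into one
sample first.

Parameters worth knowing, all in `caller_params()`:

* `window` (bp, 200) and `gap` (bp, 200): resolution/merging granularity;
  `gap` must be a multiple of `window`. These are conventional settings
  for sharp promoter-proximal marks.
* `p0` (0.2): eligibility pre-filter; looser values add candidates but
  rarely change the significant set, because significance is
  control-driven.
* `fdr` ($10^{-5}$): island-level BH threshold.
* `shift` (bp, 0): optional fragment shift applied 3'-ward to each tag
  before counting. The default of zero keeps counting reproducible; a
  caller-conventional half-fragment shift can be set when fragment size is
  known.

## Feature annotation

`build_partition()` tiles each chromosome with exactly one label per base:
promoter (strand-relative `[TSS - promoter_len, TSS)`, default 2 kb), exon
(union of exon blocks), intron (rest of the gene span), intergenic
(everything else). Collisions — including overlapping genes — are resolved
per base by the fixed precedence promoter > exon > intron, which makes the
partition order-independent. Peaks are classified by the
highest-precedence label they overlap by at least one base (any-overlap
rather than midpoint: deterministic and directly testable against a
per-base oracle).

## Metaprofiles

Both profile modes use the pooled-base normalization: a bin's density is
its total tag count divided by the total number of in-bounds bases the bin
covers across all profiled regions and by the library size, scaled by
$10^6$ (tags per base per million tags). This fixes profile shape
independent of depth — duplicating every tag leaves densities unchanged —
and regions truncated at chromosome edges contribute only their in-bounds
bases to the denominator. A tag under two profiled regions is counted once
per region, matching per-region averaging semantics.

`reference_point_profile()` bins fixed flanks (default 5 kb) around points
such as TSSs or CpG-island centres, flipping bin order for minus-strand
points. `gene_body_profile()` uses fixed-width flank bins (3 kb of 100-bp
bins in the conventional layout) plus 20 percentile bins along each gene
body, i.e. 5% of that gene's length per bin; bin boundaries use floor
arithmetic with remainder bases going to the last bin, a deterministic
tie-break for lengths not divisible by 20. Genes shorter than the bin
count are skipped and tallied. An alternative normalization — averaging
per-gene profiles rather than pooling bases — exists in the literature;
the pooled form is the one implemented.

## Overlap accounting

`overlap_query()` counts, for each side independently, intervals sharing
at least `min_bp` bases with the other side (default 1 bp — the weakest
"colocalized" criterion, exposed so stricter variants are expressible),
plus the number of merged shared regions, since region-level and
input-interval-level counts answer different questions and reports of
colocalization are ambiguous between them. `venn_regions()` merges each
set and returns base-exact A-only/shared/B-only region lists.

## Expression integration and the direct-target rule

Counts are depth-normalized to CPM with a pseudocount (default 1) —
deliberately simple and swappable. Two fold-change orientations are
reported: `fc = WT/KO` (so "a 6.9-fold reduction in the knockout" reads as
`fc = 6.9`) and `log2fc = log2(KO/WT) = -log2(fc)`, the conventional
differential-expression sign where knockout down-regulation is negative.
Classification uses `log2fc`: down when `log2fc <= -1`, up when
`log2fc >= 1` at the default twofold threshold (inclusive, both
directions).

A gene is *bound* when any called island overlaps its extended gene body —
10 kb strand-relative upstream of the TSS plus the gene span — by at least
one base. Direct targets are bound genes whose class is not unchanged. No
dispersion-based test is applied: the rule is a fold-change filter by
design, and the summary reports the fraction of changed-and-bound genes
that are down-regulated.

## The synthetic-data generator

`sim_config()` defaults define the study conditions used throughout the
tests: 2 chromosomes of 5 Mb, 500 non-overlapping genes (2–20 kb, random
strands, 2–6 compact exons of 100–300 bp so the exon fraction of the
genome stays realistically small), 200 CpG islands of 1 kb (half centred
on gene TSSs), $2\times10^5$ tags per sample, 50 planted 1-kb enriched
islands at 10-fold over background placed at gene promoters, and 40
planted direct-target genes (85% down-regulated) plus 10 bound-unchanged
genes. Four designated target genes carry 6.9-, 2.8-, 4.2- and 3.7-fold
knockout reductions; remaining planted fold magnitudes are drawn
log-uniform from [2.8, 6.9], the span of those designated values.
Expression counts are negative-binomial with mean 1000 and shared
dispersion $\phi = 0.05$ (`Var` $= \mu + \phi\mu^2$), the minimal
overdispersed noise model. This scale keeps every pipeline stage under a
few seconds on one CPU while leaving dozens of islands of statistical
power.

Background tags are a uniform Poisson process — no mappability, GC or
fragment-length structure — and treatment samples simply raise the rate
inside planted intervals. Passing tests therefore demonstrate correct
error control and recovery under the model's own assumptions, not
robustness to the artefacts of real libraries (duplicated fragments,
blacklist regions, copy-number variation). The reader should treat the
planted-truth benchmarks as verification, not as evidence about any
particular real dataset.

A single root seed drives everything: per-stage seeds are derived
deterministically from it (salted by sample name), so one integer
reproduces a full pipeline run byte-for-byte, which
`run_pipeline()` verifies via MD5 checksums in its manifest.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; 1-based containers are
  built only transiently inside interval set arithmetic (IRanges).
  TSS of a minus-strand gene is `end - 1`; "upstream" is always
  strand-relative.
* Poisson tails use the exact survival function (`ppois(..., lower.tail =
  FALSE)`); island scores are `-ln` of those tails, so scores are finite
  and non-negative for eligible windows.
* Tags shifted off a chromosome end are clamped to the terminal base, so
  window counting conserves totals exactly.
* An empty candidate list, an empty peak set, or an all-background genome
  return empty (not errors); an empty control sample, an empty
  reference-point list, zero library sizes and negative folds are errors.
* Duplicate tags are kept by default; `read_tags(dedup = TRUE)` collapses
  identical (chromosome, position, strand) triples, since whether the
  original pipeline deduplicated is unknown.

## Known limitations

* Single-pair fold-change noise. With one unreplicated WT/KO pair at mean
  1000 and dispersion 0.05, the log2 ratio of two negative-binomial draws
  has standard deviation $\approx \sqrt{2(1/\mu + \phi)}/\ln 2 \approx
  0.48$. No estimator can recover a planted log2 fold change to within
  ±0.25 with high per-gene probability under that noise; the package
  reports the raw estimate and leaves replicate-aware inference out of
  scope. The same noise floor makes genes planted near the twofold
  threshold individually unrecoverable a noticeable fraction of the time,
  which bounds achievable direct-target sensitivity.
* Broad domains. The gap-merge at 200 bp targets sharp, promoter-proximal
  islands; dispersed marks spanning tens of kilobases would need larger
  windows/gaps and are untested territory.
* No input-normalized signal tracks, no duplicate-aware modelling, no
  overlap-significance permutation tests — all natural extensions, none
  implemented.

## Problem sizes used in the shipped checks

The test suite runs the generator at its default scale (10 Mb genome,
$2\times10^5$ tags per sample) for the end-to-end checks, 20 null seeds
for error control, 10 seeds for planted-island recovery, $10^4$ intervals
per side against the brute-force overlap oracle, $10^6$ uniform tags for
profile flatness, and 100 seeds for fold-change recovery; smaller
configurations are used for unit-level oracles. These sizes were chosen so
the whole suite completes in about a minute while keeping at least
dozens of events behind every statistical assertion.
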