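---
title: "Methods: amplicon indel classification and bisulfite window statistics"
author: "rdnaedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon indel classification and bisulfite window statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaedit)
```

# Scope and model

`rdnaedit` quantifies two read-derived signals from a multi-guide CRISPR
editing study of the zebrafish maternal 45S ribosomal DNA (45S-M) promoter:

1. **Editing outcomes** from paired-end deep sequencing of a 317-bp PCR
   amplicon that spans all three guide target sites, classified per read
   pair into a seven-category indel-variant taxonomy. The proportion of
   unedited pairs is the sample's *reference conformity*.
2. **Germline rDNA amplification** from shallow PBAT-style bisulfite
   sequencing, summarized as the proportion of CpG methylation calls
   falling in the fixed 21-kb genome window containing 45S-M. Because the
   female germline amplifies 45S-M extrachromosomally, an elevated window
   proportion is a proxy for femaleness.

Both arms are exercised end to end on synthetic data whose generating
parameters are known, so every statistic the package reports is validated
by parameter recovery rather than by comparison to any external dataset.

# Amplicon coordinate model

Coordinates on the amplicon are 0-based and half-open; a *cut site* is a
between-base index. For an NGG-class guide whose protospacer occupies
`[s, s+20)` with PAM at `[s+20, s+23)` on the protospacer strand, the blunt
Cas9 cut sits 3 bp 5' of the PAM, i.e. at between-base index `s+17`. The
*indel-detection window* is the ten between-base positions flanking the
cut, `[cut-5, cut+5)`. An indel is "at the site" when its reference
footprint intersects this window: intersection rather than containment,
because Cas9 repair products commonly extend asymmetrically from the cut.
The first PAM base is treated as a wildcard (`N`).

The built-in `syntheticAmplicon()` fixture is a 317-bp sequence (not a
genomic sequence; shipped as plain FASTA + TSV under `extdata/`) with three
guides at realistic spacing — cut sites 57, 156 and 247, the middle guide
on the minus strand — flanked by 20-bp primer sites.

## The seven-category taxonomy

The category set is instantiated from the guide geometry by
`variantCategories()`. Localized-indel testing defaults to the two *outer*
guides (the first and last cut site): with three guides this yields

* I — reference (unedited),
* II, III — a localized indel at the first or last tested site,
* IV — localized indels at two or more tested sites,
* V, VI, VII — a large deletion between each pair of cut sites.

That is seven categories, six of them edited, which is the only
instantiation of "reference + singles + multi-site + inter-site spans"
consistent with a three-guide design and a seven-class spectrum; it also
mirrors a common practice of scoring local lesions at the outermost guides
while attributing inter-site deletions by their endpoints. `localSites =
"all"` widens the taxonomy (8 classes for 3 guides) for designs that test
every guide.

## Precedence

When a read pair supports several classes, the final call is resolved by a
configurable precedence order, default **large deletion > multi-site >
single-site > reference** — larger lesions subsume smaller ones. Mates
supporting *different* deletion spans are flagged discordant and resolved
toward the larger net length change. The order is an explicit argument
(`precedence=`) so an alternative scheme can be dropped in without touching
the classifier.

# Read processing

**Trimming.** 3' quality trimming uses the BWA-style running-sum rule at
phred 20: the kept prefix maximizes the sum of `(threshold − q)` accumulated
from the 3' end; ties resolve to minimal trimming, and reads may become
empty (the pair is then classified from the surviving mate).

**Alignment.** Each mate is anchored by its 5' 20-mer (the primer region):
the anchor must match the reference, on either strand, uniquely with at
most one mismatch; reads failing this are off-target. The full read is then
aligned by semi-global affine-gap alignment (read fully consumed, reference
suffix free) in a small C++ core. Costs (×10): match 0, mismatch 10, gap
open 25, deletion extension 1, insertion extension 10. Three choices
matter:

* *Cheap deletion extension* makes a d-bp inter-site deletion (cost
  ≈ 25 + d) far cheaper than the mismatch run it would otherwise become
  (cost ≈ 7.5·tail), so large deletions are recovered as single deletion
  operations. A plain unit-cost edit distance fails here — a 99-bp deletion
  would cost 99 against ~70 for mismatches.
* *Expensive insertion extension* (priced like mismatches) prevents the
  free reference suffix from absorbing the read tail as one long spurious
  insertion.
* *A single substitution (10) is cheaper than any indel pair (≥ 50), and
  ties prefer the diagonal*, so sequencing errors never create indel
  events.

Indels are left-aligned after traceback (an indel shifts left while its
last base equals the reference base 5' of it). A deletion is only
recoverable when the read continues long enough past the junction
(roughly d/7 bases); every inter-site span of the study geometry (≤ 190 bp)
is far inside this limit.

**Event detection.** Indel operations whose footprint intersects a guide
window become localized events tagged with that site. Separately, the
split-read displacement rule: if the reference span of the read
(`refEnd − refStart`) exceeds the read length (151 bp), a large-deletion
event fires, attributed to the guides whose cut sites fall within ±5 bp of
the deleted interval (the ±5 tolerance absorbs left-aligned placement of
junction-homologous deletions). A large-deletion event spanning fewer than
two cut sites is "span ambiguous" and never maps to an inter-site deletion
class — this is what keeps a 3-bp localized deletion (which also displaces
the 3' end by 3 bp) in its localized class.

**Category-I mismatch tolerance.** A pair with no events is category I only
if each mapped mate has at most 2 substitutions; pairs above tolerance with
no events are excluded from the on-target count rather than misassigned.

# Sample summaries and inclusion gates

Per sample: category proportions over classified pairs; conformity
(= proportion of category I); the binomial margin of error
ε = z·sqrt(p(1−p)/n) at p = conformity, n = on-target pairs; and the
Shannon entropy −Σ p·log₂ p of the category spectrum (0·log 0 = 0).

The default z = 2.326348 is used verbatim as the study's printed "99%
confidence" constant, although it is numerically the one-sided 99%
(two-sided 98%) normal quantile; the package does not silently "correct"
it. Inclusion gates are strict as printed: **more than 150** on-target
pairs and **ε below 5%**; a sample at exactly 150 pairs is excluded.

The rank-sum comparison (`wilcoxonRankSum()`) wraps `stats::wilcox.test`:
exact when both groups have ≤ 8 tie-free observations, otherwise the
tie-corrected normal approximation with continuity correction; identical
groups give p = 1. The test suite checks it against a full-enumeration
oracle and an independently coded normal approximation. The exact and
approximate routes agree to 0.011 over every achievable statistic at
n = 8 vs 8 (the worst case, 0.0109, sits at W = 24). Significance labels
use the printed inclusive boundaries (\*, \*\*, \*\*\*, \*\*\*\* at 0.05,
0.01, 0.001, 0.0001).

# The methylome arm

**Genome model.** `syntheticGenome()` builds one contig of
`nWindows × windowWidth` bp (default 10 × 21 kb). CpG dinucleotides are
placed on a regular 150-bp grid — identical count per window — and all
accidental CpGs are removed. This equalizes per-window CpG density, so the
CpG-call proportion of a window is an unbiased estimate of its read
sampling share and parameter recovery can be judged against the closed
form cf/(cf + nWindows − 1). Real genomes have heterogeneous CpG density;
the synthetic model deliberately does not, and recovery results here do
not speak to density-driven biases in real data.

**Simulation.** Fragments (320 ± 30 bp, uniform) are sampled entirely
within one window, window-weighted: the target window carries
`copyFactor`-fold weight. The fragment's top strand is bisulfite-converted:
a CpG cytosine stays C with probability m + (1−m)·f, any other cytosine
with probability f (m = methylation rate, f = conversion-failure rate).
R1 is the converted fragment's 5' 151 bp, R2 the reverse complement of its
3' 151 bp. One original-strand orientation per fragment is a deliberate
simplification of real PBAT strand chemistry. Fragment-length jitter
exists because real libraries have it — and because with fixed-length
fragments, distinct fragments collide into identical read pairs often
enough to contaminate the duplicate-fraction QC metric.

**Mapping and calling.** Reads are mapped by unique exact matching in
C→T-collapsed (three-letter) space against both genome strands, in both
read orientations; any ambiguity leaves the read unmapped. Mismatch-
tolerant bisulfite alignment is out of scope — the synthetic genomes are
error-free by construction. For every reference cytosine under a mapped
read, read base C ⇒ methylated, T ⇒ unmethylated, anything else is
skipped; context (CpG vs non-CpG) comes from the reference dinucleotide on
the mapped strand.

**Summary statistics.** Conversion efficiency = converted fraction of
non-CpG cytosine calls (the standard definition). Duplicate fraction =
fraction of read pairs whose (R1, R2) sequences duplicate an earlier pair.
The genome is tiled into fixed-width windows (last window per contig may
be short) and the *target-window proportion* is CpG calls in the target
window over all CpG calls — methylated and unmethylated both count, since
the statistic is a copy-number proxy, not a methylation level. Inclusion
gates, strict as printed: conversion efficiency > 97%, more than 10,000 CG
calls, and rejection above 1% duplicates.

**Amplification call.** The study draws a baseline line (median unamplified
proportion 0.214% on the real genome) but states no numeric decision rule;
the package calls "amplified" when the target proportion exceeds
`foldThreshold × baseline` with `foldThreshold = 3` by default. Three-fold
cleanly separates the study's printed amplified (≥ 1.3%) and baseline
(0.214%) values with margin on both sides, and is exposed as an argument.
On synthetic cohorts the baseline defaults to the uniform expectation
1/nWindows.

# Numerical and degenerate-input choices

* ε = 0 exactly at p ∈ {0, 1}; `marginOfError()` refuses n = 0.
* Entropy refuses negative masses and spectra not summing to 1 (1e-9).
* A sample with zero on-target pairs fails QC with reason
  `"no on-target pairs"`; proportions are NA, not 0.
* Zero CpG calls make the window proportion undefined (error + QC fail).
* Guide location demands exactly one protospacer+PAM match over both
  strands; primers likewise.
* Overlapping edits in a variant spec are an error; at most one
  inter-site span per molecular species.
* All simulators take an integer seed and are byte-reproducible
  (Mersenne-Twister, fixed normal/sample kinds).

# Problem sizes

The validation suite runs at sizes chosen to make the statistical checks
sharp but the runs quick on a laptop: classifier truth-recovery on 5,000
pairs (error-free: 100% required; at 0.5% substitution error: ≥ 99% of
classified pairs); interval-coverage of the conformity estimate over 200
replicate samples of 500 pairs at true conformity 0.455 (coverage ≥ 97%
at the z = 2.326348 margin, consistent with its two-sided 98% nominal
level); and methylome parameter recovery at 20,000 read pairs against the
closed form 50/59 within three binomial standard errors. Unit tests use a
miniature 10 × 2.1-kb genome with the same structure.

# Known limitations

* The aligner assumes reads start at a primer site; amplicons with
  internal priming or adapters are out of scope.
* Large deletions whose post-junction read tail is shorter than ~d/7
  bases are not recoverable from that mate (and deletions removing a
  primer site entirely are invisible to both mates).
* The taxonomy attributes each large deletion to one span; molecules
  carrying both a span and an additional localized lesion are classified
  as the span (precedence), losing the secondary lesion.
* The bisulfite mapper is exact-match only and the strand model is
  simplified; neither is adequate for real PBAT libraries, which is why
  the methylome arm documents but does not process genome-scale data.
* Chance read-pair collisions still contribute (negligibly) to the
  duplicate fraction at very high local coverage.
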