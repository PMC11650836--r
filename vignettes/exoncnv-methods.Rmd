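---
title: "Methods: exon-resolution CNV filtering with exoncnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exon-resolution CNV filtering with exoncnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoncnv)
```

## The model

Read-depth CNV callers summarize coverage over target bins — for exome
data, essentially one bin per exon — and report, per bin, a bias-corrected
log2 ratio of the sample's coverage against a pooled reference. Under the
diploid null the ratio sits near 0; one lost copy gives an expectation of
log2(1/2) = −1, a complete loss drives it strongly negative (bounded only
by noise and the caller's flooring), and one gained copy gives
log2(3/2) ≈ +0.585. All of exoncnv is built on this one quantity plus the
raw per-bin depth.

### Call thresholds

A ratio x is classified into exactly one of four categories:

| category | rule |
|---|---|
| homozygous deletion | x < `hom_del_log2` (−1.1) |
| heterozygous deletion | `hom_del_log2` ≤ x ≤ `het_del_log2` (−0.4) |
| normal | `het_del_log2` < x ≤ `dup_log2` (0.3) |
| duplication | x > `dup_log2` |

The defaults (0.3 / −0.4 / −1.1) are the conventional screening cutoffs
for exon-level dosage: −0.4 is roughly halfway between the diploid
expectation and the single-copy expectation of −1, so it trades a small
false-positive rate against sensitivity to partially affected bins; 0.3 is
the symmetric choice below the three-copy expectation of +0.585. Data
grids additionally mark bins with x < −0.65 (`grid_highlight_log2`) — a
"clearly less than two copies" visual flag stricter than the call cutoff.

Boundary convention: the heterozygous-deletion interval is **closed at its
upper edge**, so x = −0.4 exactly is still a deletion, while x = 0.3
exactly is normal (duplication is strictly greater). A value exactly at a
deletion cutoff has, in practice, been pushed there by a real dosage loss
far more often than by upward noise from the diploid cluster, so the
inclusive edge errs toward sensitivity; the choice matters only on a
measure-zero set and keeps the partition exhaustive and exclusive, which
the test suite checks on a dense grid. The same convention is reused by
the consecutive-run detector (deletion predicate x ≤ −0.4) so that every
bin *called* a deletion also qualifies for deletion runs.

The integer copy number is the diploid-anchored closed form
`round(2·2^x)` with half-up rounding, floored at 0. It reproduces the
anchors 0 → 2, −1 → 1, +0.585 → 3 and is monotone in x.

### The cohort exon reference

Exon identity is positional: within each (gene, chromosome) group, bins
are sorted by start coordinate and numbered 1..n. The input tables carry
no exon annotation, only target names; labels of the form `GENE_3` (a
trailing all-numeric suffix) are collapsed to the gene symbol before
grouping, and background/antitarget bins (label `Antitarget` or `-`) are
excluded from indexing but kept for scatter plots. Because the ordinal is
derived from a sort, it is invariant under row permutation — but it is
**only comparable between files produced from the same target design**;
this is a deliberate limitation, not a defect, and the reference TSV
records the denominator per exon so partially overlapping designs degrade
visibly (smaller `n_samples`) rather than silently.

Per exon the reference stores the fraction of cohort samples classifying
as het-del / hom-del / duplication (exclusive categories over the same
denominator, so the three frequencies plus the normal fraction sum to 1
exactly), and the boxplot statistics of log2 and depth: mean, median,
standard deviation (n−1 denominator, defined as 0 for a single sample),
quartiles by linear interpolation between order statistics (the common
default in numeric libraries, stated so independent recomputations
match), and min/max. Exons absent from some samples use the carrying
samples as denominator.

### The bin-wise z-test

The single-bin test asks whether one bin's ratio is extreme relative to
the cohort at that exon: z = (x − mean_ref)/sd_ref, two-sided p-value from
the standard normal, Benjamini–Hochberg step-up across all tested bins,
significance at adjusted p ≤ α (default 0.05, the conventional FDR
level). The step-up is implemented directly (sort, scale by m/i, running
minimum from the largest rank, cap at 1, restore order); the test suite
cross-checks it against `stats::p.adjust` and a brute-force oracle to
1e−12. Bins without a reference entry or with zero reference spread are
untestable and are dropped with a count — a zero-spread exon means the
cohort is constant there and any deviation would be infinitely
significant, which is a statement about the cohort, not the sample. Under
the null (bins drawn from the reference's own parameters) the flagged
fraction stays at or below α; the suite checks ≤ α + 3·SE over 10,000
bins and five seeds.

### Trio mode

The index sample is left-joined with each parent on the exact bin key
(chromosome, start, end, gene) — not on the exon ordinal, so trio mode
tolerates slight reference-design drift between family members, at the
price of requiring exact coordinates. Duplicate keys within a parent keep
the first occurrence (counted); a left join guarantees one output row per
index bin. The de novo rule is: index call aberrant, both parental calls
normal, complete parental data required — bins with missing parental data
are excluded and counted separately rather than passed through, because
"parent not measured" is not evidence of "parent normal".

### BAF and LOH

The B-allele frequency of an SNV is alt/(ref+alt) from the per-sample
allelic-depth field; records lacking allelic depths but carrying a
genotype fall back to depths (1,1)/(1,0)/(0,1) for het/hom-ref/hom-alt,
so the downstream balance is exactly 0.5/0/1 — only the three balance
classes matter downstream. Multiallelic and non-SNV records are skipped
with a count.

LOH is visually a stretch of SNVs dispersing to balance 0 and 1 with no
heterozygous band. The operational flag is a sliding window of 25
consecutive SNVs, flagged when at most 10 % of them fall strictly inside
the 0.3–0.7 band, with overlapping flagged windows merged per chromosome.
25 SNVs is small enough to resolve arm-level events at typical exome SNV
density while keeping the false-flag probability of a genuinely
heterozygous window negligible (a het SNV rate of ~50 % would need to
drop to ≤ 10 % in 25 draws); the band 0.3–0.7 is symmetric around 0.5 and
wide enough to absorb binomial depth noise at ~30×. Boundary resolution
is inherently ± one window; the acceptance checks assert containment
within that slack. Chromosomes with fewer than 25 points are never
flagged. The heuristic does not attempt to distinguish somatic LOH from
uniparental disomy.

## The synthetic generator

`synth_cohort()` emulates the quiet diploid exome slice the analysis is
designed for: per bin and sample, log2 ~ Normal(0, 0.15) — a typical
well-behaved exome noise level — with injected events shifting the ratio
by −1.0 (het del), −3.3 (hom del) or +0.58 (dup), and depth coupled
multiplicatively (`round(200 · 2^log2)`) so depth- and log2-based views
agree. Everything is deterministic per seed, down to the emitted bytes.

What it does **not** emulate: GC/mappability bias and its correction,
bin-size and weight structure (weights are plain uniform draws),
segmentation noise, sex-chromosome ploidy, or correlated batch effects.
Passing tests therefore demonstrate the *logic* of counting, filtering,
joining and windowing — not robustness to real-world bias. One
consequence worth stating: at the default noise (sd 0.15) a het-del
shifted bin (centered at −1.0) lands below the hom-del boundary (−1.1)
about a quarter of the time; that is realistic — single-copy losses do
blur into the hom-del tail in noisy data — but it means exact
category-count recovery is only a theorem under tighter noise. Tests that
assert exact integer-count recovery of injected events therefore generate
their fixtures at sd 0.02–0.05, where every injected event classifies as
intended with near certainty; tests of the generator's own tail behavior
use the default.

## Numerical and design choices

- **Coordinates.** Bin tables are 0-based half-open (the BED convention of
  the source format); VCF positions are 1-based. Region *strings* typed by
  a user ("chr1:1000-2000") and IGV loci are 1-based inclusive display
  coordinates and converted at the boundary.
- **Chromosome order.** Natural order 1..22, X, Y, MT, then lexicographic;
  "chr" prefixes are ignored for comparison and preserved on output.
- **Serialization.** All TSVs write floats at 6 decimal places; a
  write→read→write cycle is byte-identical, which the suite checks by
  checksum. Missing cells read as "" or "."; written as "".
- **In-house frequency filter.** The ceiling applies to the *maximum* of
  the three per-exon frequencies — a conservative "any recurrent event"
  rule, chosen over per-category thresholds to keep the filter a single
  intuitive dial; bins absent from the reference pass, since no evidence
  of commonness is not evidence of commonness.
- **Consecutive runs** are defined on exon ordinals (strictly consecutive
  `exon_index`), not genomic distance: "consecutively deleted exons" is an
  ordinal notion, and intron length is irrelevant to it. Default minimum
  run length 2 (user-settable).
- **Degenerate inputs.** Empty tables parse to empty collections (not
  errors); an empty cohort, an empty panel and an empty testable set are
  content errors; single-sample references collapse quartiles to the
  observation and define sd = 0.
- **Error taxonomy.** All user-facing failures are classed conditions
  (`exoncnv_io_error`, `_schema_error`, `_parse_error`, `_config_error`,
  `_content_error`, `_value_error`, `_lookup_error`); the CLI maps them to
  exit code 1 and anything unexpected to 2, and writes outputs via a
  temp-file-and-rename step so failures never leave partial files.

## Problem sizes

The shipped suite runs entirely on generated data: cohorts of 4–20
samples over a handful of genes (tens of bins), 10,000-bin null panels
for the z-test calibration, 600-SNV chromosomes for LOH, 1000 random
p-vectors for the step-up cross-check, and 50 random generator specs for
reference recovery — sizes chosen so each property is exercised across
its edge cases while the whole suite completes in well under a minute of
compute; every quantity scales linearly if larger checks are wanted.

## Known limitations

- Exon ordinals are design-relative; references built on different target
  designs must not be mixed (no coordinate-level exon matching).
- chrX/chrY frequencies are not sex-stratified; interpret allosomal
  frequencies with the cohort's sex composition in mind.
- The z-test assumes approximate normality of per-exon cohort log2; for
  very small cohorts the reference sd is unstable and the test is better
  left to the caller's own bintest output, which the readers ingest as-is.
- The LOH flag is a screening heuristic, not a genotype-likelihood model.
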