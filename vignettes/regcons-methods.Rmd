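---
title: "Methods: comparative binding-region analysis and target conservation"
author: "regcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative binding-region analysis and target conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`regcons` implements the downstream half of a comparative ChIP-seq/RNA-seq
study of a transcription factor (the motivating case is SOX9 in developing
limb buds versus male gonads, in mouse and chicken). Peak calling, read
alignment, FPKM estimation and conservation-model fitting are all upstream:
the package consumes their outputs (peak tables, gene models, genome FASTA,
per-base conservation scores, expression tables, ortholog maps) and produces
the comparative summaries — genomic position classification, motif
frequencies, conservation distributions, regulated gene sets and their
cross-species conservation.

This vignette records the model choices, the tunable parameters and the
numerical conventions, including the places where the underlying procedure
is genuinely underdetermined and a deterministic convention had to be fixed.

## Coordinates and input formats

Internally every interval lives in a `GRanges` (1-based, closed), the
Bioconductor convention. Conversions happen once, at the I/O boundary:
BED and bedGraph are 0-based half-open; GTF/GFF3 and wiggle are 1-based.
The packaged MACS-style TSV dialect stores `start`, `end`, and a summit
*offset* from the start; `readPeakTable(..., oneBased = TRUE)` accommodates
genuine MACS 1.4 `.xls` exports whose start column is 1-based. BED peak
tables carry no summit, so the summit defaults to the interval midpoint —
the only coordinate-free fallback. Chromosome names are matched verbatim;
no silent "chr" aliasing.

Gene models may carry several transcripts per gene; the analysis needs
exactly one. The rule is: **longest genomic span wins, ties broken by
lexicographically smallest transcript id**. Any deterministic rule would do;
this one needs no external annotation of canonical transcripts. Exons of
the chosen transcript are merged and sorted; genes without CDS are flagged
non-coding, and their exons count as the exon category during
classification (a warning is emitted; `includeNoncoding = FALSE` drops them).

## Seven-category classification

The genome is partitioned, per gene, into: up to 10 kb upstream of the TSS
(strand-aware), 5′UTR, coding exon, intron, 3′UTR, up to 10 kb downstream of
the transcript end, and OTHER for everything unlabeled. A peak is classified
by its **summit**, not by whole-interval overlap: summit classification
guarantees each peak exactly one category, which the category fractions
(pie-chart style summaries) require; the summit is also the best estimate of
the binding point.

Overlaps between labels are resolved by a fixed precedence:

> UTR5 > UTR3 > CODING_EXON > INTRON > UPSTREAM_10KB > DOWNSTREAM_10KB,
> then nearest TSS, then smallest gene id.

UTRs are subsets of exons, so they must outrank the exon label or they could
never be reported; gene-internal labels outrank flanks so that a summit
inside a gene is never attributed to a neighbor's flank. The source
procedure is silent on ties, so the remaining two tie-breaks (TSS distance,
gene id) exist purely for determinism. Tests verify the classifier against
an independent per-base painter that colors every base of small genomes in
increasing precedence order and reads off the summit's color.

Tunables: `upstreamBp` and `downstreamBp` (bases, default 10 000, the
published flank size).

The fold-enrichment histogram uses fixed-width bins `[k·w, (k+1)·w)` and
moment-based shape statistics: skewness `g1 = m3/m2^1.5` and **Pearson
kurtosis** `g2 = m4/m2²` (normal → 3), the convention of the classical
moments summaries.

## Motif model

PWMs are per-position **base counts** over aligned sites (a frequency
matrix, as produced by EMBOSS prophecy). A window's relative score is

```
relative = 100 * raw / max_score,   raw = sum_i W[w_i, i]
```

so the consensus scores 100. The alternative — min–max rescaling — was
rejected because count weights are nonnegative, making percent-of-maximum
the natural reading of a "relative profile score"; the exact formula inside
the scanning tool the procedure names is unpublished behavior, so this is a
documented stand-in and motif frequencies on real data may deviate from
published values by this implementation detail. The threshold comparison is
**strict** (`> 75` by default, following the published "> 75%" wording).
Both strands are scanned; a minus-strand hit at offset *o* means the
reverse complement of the window starting at *o* (plus-strand coordinates)
exceeds the threshold. Windows containing non-ACGT characters are skipped;
soft-masked lower-case bases are case-folded rather than skipped, the less
destructive default given that the repeat-masking policy of the original
data is unstated.

The palindromic homodimer motif is composed from a half-site of length
*L* as a `2L + spacer` composite: the half-site, `spacer` columns (default
4 bp) of uniform weights (each base gets max column total / 4, so every
window receives the same spacer contribution — the spacer is
score-neutral), and the reverse-complemented half-site. Consequently
`half-site + any spacer + inverted half-site` always scores exactly 100,
and a sequence containing only one half-site scores strictly below 100.

Scanning windows: the per-peak motif frequency scans the **full peak
interval** by default (the published frequency analysis scans "the
regions"); a `summit50` window (summit ± 50 bp, the de novo discovery
input window) is available for sensitivity analysis.

Short boxes like `CCAAT` are counted by IUPAC matching on both strands,
overlapping occurrences allowed, ambiguity codes literal in the subject.

## Conservation

Per-peak conservation is the mean score over `summit ± flank`
(`2·flank + 1` bases; 201 for the default ±100), clipped at chromosome
bounds. Positions with no stored score contribute **0 while still counting
in the denominator**: unaligned bases have no conservation value, and
treating them as missing-at-random would inflate the means of poorly
aligned regions. Distributions use 0.2-wide bins, left-closed with the top
bin `[0.8, 1.0]` closed, so that "> 0.8" and "between 0.6 and 0.8" partition
cleanly; `boundary = "right"` flips the convention since the original
binning is not documented. Bin indices are computed with a 1e-9 tolerance
so that values like 0.6 land deterministically despite binary
representation of the edges.

The Mann–Whitney U test uses midranks, a tie-corrected variance, and a 0.5
continuity correction in the normal approximation (standard for two-sided
rank tests at moderate n). For small untied samples (`min(n) ≤ 8`,
`n1 + n2 ≤ 20`) an exact enumeration over all rank assignments is used
automatically; the two-sided exact p is `min(1, 2·min(P(U ≤ u), P(U ≥ u)))`,
matching the base-R reference implementation. Two constant, equal samples
are a degenerate case with `p = 1` by convention. The normal approximation
is only expected to track the exact p closely for `min(n) ≥ 5`: exhaustive
enumeration over all achievable U shows worst-case deviations of ~0.09 at
`n = (2, 2)` and ~0.03 at `(4, 4)`, falling below 0.02 from `min(n) = 5` —
an intrinsic property of the approximation, not of this implementation.

## Targets, expression and cross-species conservation

The cis-regulatory span of a gene runs from 10 kb upstream of the TSS
(strand-aware) through the end of the transcript, i.e. through the 3′UTR. A
gene is a putative target when **at least one peak summit** lies in its
span — summit membership keeps the target caller consistent with the
classifier; `mode = "overlap"` (any overlapping base) is available for
sensitivity analysis since the original definition of a peak "corresponding
to" a region is not precise. When biotypes are available the universe is
protein-coding genes.

The expression filter is `FPKM_cell > 1.0` AND `FPKM_cell /
FPKM_whole_embryo > 1.5` AND `q < 0.05`, all strict per the published
"more than"/"smaller than" wording. A zero whole-embryo denominator with
positive cell FPKM passes (infinite induction: the gene is maximally
cell-specific). q-values are consumed, never computed. The regulated set is
the exact intersection of targets and highly expressed genes.

Cross-species conservation maps regulated sets through an ortholog pair
table (many-to-many allowed, duplicates dropped). Conserved counts are
reported both as distinct genes per side and as pairs, since the two differ
under many-to-many homology; no homology-type filter is applied by default
(`homologyType = "ortholog_one2one"` restricts). GO tallies are flat
membership counts against the provided annotation file — no ontology-graph
propagation.

## The synthetic-data generator

`generateDataset()` emulates the complete two-species input bundle at desk
scale with every analysis-relevant property planted and recorded in a
manifest. Defaults are the standard study conditions used throughout the
tests: per species 5 chromosomes × 200 kb, 100 genes, 300 peaks of 500 bp;
category fractions dominated by upstream (30%) and intronic/intergenic
binding; 20% of peaks carry a planted palindromic site (4 bp spacer), a
further 30% a single half-site, 25% a CCAAT box; conservation window means
of 0.6 ("high") versus 0.3 ("low") with sd 0.15; 30 truly expressed genes
per species with expression noise off; 80 one-to-one ortholog pairs and 10
planted conserved regulated genes. Background sequence is i.i.d. uniform
ACGT (GC = 0.5, configurable, since PWM false-positive rates depend on
composition).

**Gene layout.** Genes sit on a fixed 9 kb pitch with a 5 kb three-exon
body and alternating strands. The pitch is deliberately smaller than the
10 kb flank, so flanks overlap — the realistic, "crowded" regime — and
planted summit positions are chosen only where the intended category
provably wins under the classification precedence. Alternating strands
create two kinds of intergenic gap: divergent gaps (two TSS-facing flanks)
that are upstream-everywhere, and convergent gaps whose central zone is
more than 10 kb from every TSS-facing flank and therefore purely
downstream. The 9 kb pitch is the smallest multiple-of-1000 spacing at
which that downstream-safe zone exists (at 8 kb the upstream flanks of
genes one and two slots away blanket every convergent gap). A gene-free
chromosome tail supplies OTHER positions more than 10 kb from any gene.
All planted summits are at least 520 bp apart so the 500 bp peak intervals
never overlap. Plans that exceed a category's candidate capacity (e.g. more
intron peaks than intron sites) fail with an "infeasible plan" error before
any file is written.

**Motif planting.** Instances are centered on summits: the palindrome as
`consensus + random 4 bp spacer + inverted consensus`, single half-sites and
CCAAT boxes directly, each on a random strand (CCAAT is offset +40 bp when
it shares a peak with a SOX site so plants never overlap). Because a
palindrome contains two half-sites, palindrome-positive peaks are by
construction single-site-positive; the manifest records the implied flag.
With `cleanBackground = TRUE` (default) each peak's background is
rejection-sampled until scanning reports exactly the planted content at the
75% threshold — this is what makes motif frequencies recoverable *exactly*
rather than up to a false-positive margin; with a 7 bp half-site at a 75%
relative threshold, random 500 bp backgrounds produce spurious hits at an
appreciable rate, so exact recovery is impossible without it.

**Conservation, expression, orthologs.** Each peak's window
(summit ± 100) gets a constant score drawn from its group's truncated
normal; windows are disjoint by the spacing guarantee, so per-peak means
recover the drawn values. Expressed genes receive FPKM, fold-change and q
values that pass all three filters with margin; every null gene
deliberately fails exactly one criterion (cycling through low-FPKM, low
fold-change, high-q modes), so with noise off the filter recovers the
planted set exactly. Conserved regulated genes are chosen among
ortholog-linked genes that are targets in *both* species (an infeasible
request errors); the remaining expressed genes are drawn outside that
candidate set so no accidental conserved pair can arise. A single seeded
RNG stream drives every draw in a documented order: the same configuration
yields byte-identical bundles.

**What the generator does not emulate** — and therefore what passing
recovery tests do and do not show: peak width/shape variation, non-uniform
genomic background composition, overlapping gene bodies and nested genes,
multi-transcript isoform structure, phylogenetically realistic conservation
(real phastCons tracks are autocorrelated and patchy, not
constant-per-window), correlated expression noise, and many-to-many
homology. Recovery tests certify the pipeline's bookkeeping and the
correctness of each operation's logic on unambiguous inputs; they do not
certify robustness to the messiness of real annotation, and real-data motif
frequencies additionally depend on the unpublished scoring details noted
above.

## Problem sizes used by the test suite

Module tests run on genomes of tens of kilobases with handfuls of genes.
The oracle-equivalence suites use 100 random genomes up to 100 kb for the
classifier-versus-painter check and 1 000 random sequences up to 2 kb for
the scanner-versus-enumeration check; rank-test calibration uses 200 random
small-sample cases (n between 5 and 8, see above); full-pipeline recovery
uses the default desk scale (2 species × 5 chromosomes × 200 kb, 100 genes,
300 peaks); the planted-effect power check uses 100 replicates of 200
windows per group. These sizes keep the whole suite to a few minutes while
exercising every code path the desk scale can reach.

## Known limitations

* Real-data motif frequencies depend on the unpublished relative-score
  formula of the original scanning tool; the percent-of-maximum convention
  here is a documented stand-in.
* The classifier is single-transcript by design; isoform-aware annotation
  is out of scope.
* bigWig conservation tracks must be converted to wiggle/bedGraph text
  first; BAM/SAM inputs are out of scope (peaks are the entry point).
* GO tallies do not propagate over the ontology graph.
* The exact Mann–Whitney mode enumerates all assignments and is
  intentionally restricted to `n1 + n2 ≤ 20`.
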