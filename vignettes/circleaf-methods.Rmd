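---
title: "Profiling circular RNAs across a leaf lifespan time course"
author: "circleaf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling circular RNAs across a leaf lifespan time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circleaf)
```

## The problem

Circular RNAs (circRNAs) arise by back-splicing, in which a downstream
5′ splice donor joins an upstream 3′ acceptor so the transcript closes
on itself. In plants they are sparse — a back-splice junction (BSJ) is
typically supported by a handful of reads, and many circRNAs are seen
at only one time point — yet they show developmental-stage-specific
expression and can act as miRNA sponges, sequestering a miRNA away from
its mRNA targets.

`circleaf` implements the full desk-scale analysis for a developmental
time course of leaf tissue: one RNA-seq library per time point, 14
points at 2-day intervals from day 4 to day 30 after emergence. The
course is split into two windows, growth-to-maturation (`G-to-M`, days
4–18, reference day 4) and maturation-to-senescence (`M-to-S`, days
16–30, reference day 16). Days 16 and 18 belong to both windows by
construction; every stage computation uses its own reference day.

The pipeline has four stages:

1. **classify** — place each BSJ against a genome annotation;
2. **quantify** — normalize supporting reads, compute stage-wise fold
   changes, call differential expression (DE), summarize detection, and
   test host-gene concordance;
3. **targets** — score miRNA binding sites on circular and messenger
   sequences and filter them by expression anti-correlation;
4. **network** — assemble circRNA–miRNA–mRNA triplets under per-molecule
   fold-change gates.

## Classification model

A BSJ is a breakpoint pair `(start, end)` on one chromosome, 1-based
inclusive (BED-dialect files are converted on read). A breakpoint *hits*
an exon when it lies inside the exon interval, and is
*boundary-matched* when it is within `boundary_tolerance` nucleotides
(default 0, i.e. exact) of the appropriate exon edge — the acceptor
edge for the transcript-upstream breakpoint, the donor edge for the
downstream one, mirrored on the minus strand. With tolerance 0 the
donor/acceptor distinction is cosmetic (both reduce to comparing
`start` with an exon start and `end` with an exon end); with a positive
tolerance it decides *which* edge a breakpoint is forgiven against.

If both breakpoints hit exons of one gene on the junction's strand the
record is exonic: both, neither, or exactly one matched edge give
`EXONIC_BOTH_BOUNDARY`, `EXONIC_BOTH_INTERNAL` and
`EXONIC_ONE_BOUNDARY`. Both breakpoints inside one strand-matched gene
but in introns give `INTRONIC`; neither breakpoint inside any gene span
gives `INTERGENIC`. Everything else — cross-strand, cross-gene, one
genic and one intergenic breakpoint, exon/intron mixtures, host-gene
ties — is reported as `AMBIGUOUS` rather than being forced into a
category. When several same-strand genes could host the junction, the
gene whose span overlaps the junction interval most wins; exact ties
are `AMBIGUOUS`. These conservative choices keep unusual configurations
visible instead of silently reassigning them.

`exon_span` counts the host-gene exons overlapping the junction
interval. Novelty is a coordinate comparison against a catalogue of
known circRNAs: a record is known when an entry matches chromosome and
strand with both breakpoints within `slack` nucleotides (default 0;
the catalogue-matching precision of public databases is not published,
so the slack is exposed as a parameter).

Summary percentages are printed to one decimal using largest-remainder
allocation, the convention behind published tables whose rows partition
a total: raw percentages are floored to a tenth and the remaining
tenths are given to the rows with the largest remainders, so a column
always sums to exactly 100.0 and a subtotal equals the sum of its
printed rows.

## Quantification model

Supporting reads are normalized as

$$E_{fs} = \frac{n_{fs} + 1}{N_s} \times 10^6$$

with `N_s` the sample's library size — the sequencing-run total
supplied alongside the counts, never a column sum, since most reads of
a library are linear and the table holds only BSJ-supporting reads.
Whether the total is "sequenced" or "mapped" reads is up to the
provider; the pipeline uses whatever the sidecar states. The
pseudocount keeps `E > 0`, so every log fold change is defined; the
per-million scale cancels in every ratio (a scale-invariance property
the test suite asserts).

For each stage, `log2` fold changes are computed for every
non-reference day against the stage reference day. A feature is DE when
any stage day reaches `|log2FC| >= 2` (a 4-fold change, inclusive); the
plural "fold changes over the stage" reading is the default, with a
final-day-only mode available. The direction is the sign at the day of
maximum `|log2FC|`, ties resolving to the latest day — a deterministic
rule that favors the senescence end of a window. No multiple-testing
machinery is involved: with one library per time point there are no
replicates to estimate dispersion from, and the method is a pure
fold-change threshold, not a test.

Detection is minimal by design: a feature counts as detected in a
sample at one supporting read (configurable), and features detected in
fewer than two samples are excluded from DE analysis. Stage membership
("detected during a stage") includes the shared days 16/18 in both
stages, per the stage definitions; because that overlap is partly an
artifact of the shared days, the stage Venn is also reported with the
shared days excluded. "Detected in more than 10 samples" is strict
(`> 10`, i.e. at least 11).

Host-gene concordance asks whether up-regulated circRNAs simply follow
their host transcript: for each stage it counts up-regulated DE
circRNAs whose host gene is also up-regulated DE under the identical
normalization and threshold applied to the gene counts (self-contained,
rather than importing externally published DE lists), and reports
per-pair Spearman correlations over the full 14-point course.

## Target scoring and the sponge network

The scorer is a gapless plant-style penalty scheme. The target window
is read 3′→5′ against the miRNA 5′→3′; each position costs 0 for a
Watson–Crick pair, 0.5 for a G:U wobble and 1 for a mismatch, doubled
at miRNA positions 2–13 (the seed region; configurable). `S = 0` holds
exactly for perfect full-length complementarity. One scoring scheme is
implemented; the cutoffs are inclusive and per molecule type — `S <= 4`
for mRNAs, `S <= 4.5` for circRNAs, circRNAs being granted slightly
more slack as sponges. Gapless scoring keeps the scheme deterministic
and exactly checkable against brute-force window enumeration, which the
test suite does; bulged alignments and thermodynamic (free-energy)
scoring are out of scope. T and U are interchangeable on input.

Scanning slides a miRNA-length window over the target and keeps the
minimum-score window, ties resolving to the smallest start coordinate
with linear windows before junction-spanning ones. For circular
sequences the scan continues across the back-splice junction (the last
`k − 1` bases joined to the first `k − 1`), so sites created by
circularization itself are found.

A candidate interaction must also be anti-correlated in expression:
Spearman's rank correlation (average ranks for ties) between the miRNA
and target normalized profiles over all 14 points must be at most
−0.5, inclusive. An undefined correlation — a constant profile — fails
the filter explicitly. Spearman is used deliberately: the logistic-like
trajectories of the time course make rank correlation appropriate, and
it is invariant under monotone transforms such as the normalization
itself.

Triplets join a miRNA to one circRNA and one mRNA it targets, with all
three molecules passing stage fold-change gates: 2-fold for the miRNA
(`|log2FC| >= 1`) and 4-fold for circRNA and mRNA (`|log2FC| >= 2`), at
any day within the stage, each molecule gated independently (the gates
are fold factors converted literally to log2 thresholds; requiring all
three to peak at the same day would be a stricter, undocumented
variant). Triplet sets are deduplicated, deterministically sorted, and
exported as TSV (full scores and correlations) or SIF edge lists that
graph tools can load directly.

## The synthetic-data generator

Real raw sequencing data is deliberately outside the package's scope —
the generator (`simulate_dataset()`) produces every input the pipeline
consumes with the statistical structure the analysis assumes:

* a genome of two nuclear chromosomes plus a chloroplast and a
  mitochondrial sequence, with regular multi-exon gene models;
* circRNAs placed to realize a target category mixture, defaulting to
  proportions typical of leaf tissue (roughly 80/5/10/6% exact /
  internal / one-boundary / intergenic), with some intergenic circRNAs
  on the chloroplast;
* counts drawn negative-binomially (dispersion 0.05, `size = 20`)
  around logistic time-course means — with one library per time point
  the noise acts across time, not across replicates;
* planted DE circRNAs in the senescence stage: up-regulated features
  rise from a near-zero baseline (mean 0.1 reads — circRNA reads are
  sparse, and senescence-induced circRNAs are typically undetected
  early), down-regulated ones fall from a moderate baseline (mean 10);
* planted miRNA target sites embedded as exact, strand-aware
  complements inside exons covered by the target, and planted miRNAs
  declining gradually over the course as the anti-correlation partner
  of their rising targets.

The planted fold is defined on the pseudocounted scale,
`mu_hi + 1 = fold × (mu_lo + 1)`, and the logistic is anchored at the
stage reference day: the trajectory is renormalized between the
reference day and the course end, so the planted contrast equals the
declared fold exactly for any midpoint and steepness. Without the
anchoring, part of the rise leaks into the reference day and the
realized contrast is quietly smaller than declared.

What the generator does *not* emulate: read-level errors and alignment
artifacts, expression-dependent detection biases, isoform complexity
within circRNAs, and replicate structure. Passing tests on synthetic
data therefore demonstrate the correctness and statistical behavior of
the implementation under the stated model, not performance on raw
sequencing data.

A power property ships with the package: with 4-fold planted effects
and dispersion 0.05, DE recovery across 100 simulations is expected
around 92% (the threshold equals the planted fold, so recovery is
bounded by the chance the reference draw is low — near-zero baselines
are exactly the regime where the rule has power), and planted
anti-correlated pairs pass the −0.5 filter in about 97% of cases. The
problem sizes used in the shipped checks (20 circRNAs and 10 genes per
simulated dataset, 100 and 200 replicate simulations) were chosen so
the whole suite runs comfortably on a laptop.

## The deterministic benchmark fixture

`make_benchmark_fixture()` is not a sampler but a constraint-satisfaction
construction: explicit count profiles and coordinates that jointly
realize the benchmark summary statistics the package is built
around —
168 circRNAs in categories 134/8/16/10; 40 novel against the shipped
catalogue; 142 of 158 exonic records spanning 1–5 exons; 104
single-sample circRNAs, 7 in more than 10 samples, 64 retained; stage
sets of 66 and 144 sharing 42; 6 and 35 DE circRNAs (5+1 and 34+1
up/down, 3 shared); 9 of 34 senescence-up circRNAs host-concordant and
0 of 5 growth-up; and a sponge network of exactly 20 and 220 triplets
per stage. Library sizes are equal within each assay so fold changes
reduce to count ratios, which makes the planted thresholds exact (a
fold change of precisely 2.0 at the boundary is part of the
construction and doubles as an inclusivity test). The fixture is
internally seeded and byte-stable across calls.

```{r fixture}
fx <- make_benchmark_fixture()
report <- run_pipeline_data(fx)
report
```

## Numerical and design notes

* Internal coordinates are 1-based inclusive everywhere; BSJ files on
  disk are BED-dialect 0-based half-open. The conversion is
  self-inverse and round-trip tested.
* Exons of multiple isoforms are collapsed to their per-gene union on
  GFF3 import, so the stored exon set is non-overlapping and ordinals
  are well defined.
* Chromosome lengths come from `##sequence-region` pragmas when
  present, falling back to the largest feature end.
* Library sizes must be supplied; they are never recomputed from
  column sums.
* Tie-breaks are deterministic throughout: latest day for DE direction,
  smallest start (linear before junction-spanning) for equal-score
  windows, largest overlap then `AMBIGUOUS` for host-gene ties.
* Degenerate inputs have defined behavior: empty record sets summarize
  to totals of zero, constant profiles yield an undefined (failing)
  correlation, targets shorter than the miRNA yield no hit, and
  missing library sizes, malformed annotation lines and infeasible
  simulation parameters raise immediate errors.

## Limitations

The package consumes BSJ tables and does not detect junctions from
reads; de-novo detection, isoform reconstruction inside circRNAs,
consensus across multiple target predictors, thermodynamic site
scoring, enrichment analysis against external databases and graph
layout are all out of scope. The DE rule is a fold-change threshold
with no error control, appropriate for a single-library-per-time-point
design but not a replacement for replicated count models.
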