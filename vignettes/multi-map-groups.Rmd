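---
title: "Two-stage RNA-seq quantification with multi-map groups"
author: "MMGcount authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage RNA-seq quantification with multi-map groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(MMGcount)
  library(SummarizedExperiment)
})
```

## The problem

Gene-level RNA-seq counting pipelines built on htseq-count discard every
fragment the aligner reports at more than one locus.  For most genes this
is harmless, but paralogous gene families and processed pseudogene copies
share long stretches of near-identical sequence, so essentially *all* of
their reads are multi-mapped: the counter reports zero, and downstream
differential expression silently treats these genes as unexpressed.
Because human disease genes are enriched for duplicated genes, these
false negatives land disproportionately on genes people care about.

MMGcount implements a two-stage remedy.

* **Stage 1** counts uniquely mapped fragments against genes under the
  three htseq-style overlap-resolution modes (`union`,
  `intersection_strict`, `intersection_nonempty`) and records the fate of
  every fragment: `assigned`, `no_feature`, `ambiguous`,
  `alignment_not_unique`, or `not_aligned`.
* **Stage 2** takes every fragment stage 1 could not assign and places it
  — uniquely — into a *multi-map group* (MMG): the set of genes
  overlapped by any of its reported loci.  Groups are discovered from the
  data alone; no family or paralogue annotation is consulted.  Group
  count matrices are exported for count-based differential-expression
  tools, so the signal from a gene family is analysed at family
  resolution instead of being thrown away.

The package also ships a perfect-read simulator with controlled gene
duplication and an exhaustive truth aligner, so the complete method is
testable end to end without any external aligner.

## Stage-1 semantics

Overlap is always evaluated against a gene's *exon union* (the reduced
union of exons over all its transcripts); intronic bases belong to no
feature.  For a uniquely mapped pair the decision set is computed over
the pooled aligned bases of both mates:

* `union` — every gene overlapping any aligned base qualifies;
* `intersection_strict` — a gene must cover *every* aligned base of both
  mates, so any overhang into an intron or intergenic sequence empties
  the set;
* `intersection_nonempty` — a gene must cover every aligned base that
  lies under at least one feature, which forgives overhangs but still
  demands consistency where features exist.

One gene in the set means `assigned`; none, `no_feature`; several,
`ambiguous`.  A fragment whose aligner reported several loci (NH tag
above 1, or more than one record per mate when NH is absent) is
`alignment_not_unique` before any overlap logic runs.  This pooled-pair
formulation guarantees that a fragment assigned under
`intersection_strict` is assigned to the same gene under
`intersection_nonempty` — strictness can only lose assignments.

CIGAR handling follows the usual reference-space rules: `M`, `=`, `X`
and `D` consume reference and take part in the per-base sets, `N` skips
reference, `I` and `S` consume none.  Counting is unstranded by default;
`stranded = "yes"`/`"reverse"` restrict features to the
fragment's (or its opposite) strand, for protocols where that is known.

## Stage-2 rules

Each unassigned fragment contributes one count to exactly one group per
sample: the lexicographically sorted union of gene ids overlapped by any
of its loci (serialised `"G1|G2"`).  Fragments whose loci overlap no
gene at all stay discarded.  Groups of size 1 arise when all loci of a
multi-mapped fragment hit the same gene, or only one locus hits any
gene; they are kept and can be folded back into the single-gene analysis
(`singletonMmgs()`).

Two explicit post-processing steps follow, with the reference
configuration used on the 27-sample dataset the method was developed on:

* **Support filter** — keep a group only if it has at least `minReads`
  (100) fragments in at least `minSamples` (13) samples.  Both
  thresholds are inclusive.  `minSamples` must be chosen by the analyst;
  the package never scales it silently to the sample count.
* **Containment collapse** — large groups (size ≥ 5) wholly contained in
  a larger surviving group are merged into it, counts summed per sample.
  The merge order is not specified by the rule itself, so the package
  fixes a deterministic one: candidates are visited smallest first (ties
  by group id) and merge into their smallest strict superset (ties by
  group id), repeating to a fixed point.  Collapse conserves per-sample
  totals and is idempotent; groups smaller than 5 are never merged away.
  Merged groups keep the superset's id only.

## Expression measures

Counts and FPKM interconvert by the exact formulas

$$\mathrm{FPKM} = \frac{R_c / T}{R_m}, \qquad R_c = \mathrm{FPKM} \cdot R_m \cdot T,$$

with $R_c$ the fragment count, $T$ the transcript length in kilobases
and $R_m$ the library size in millions of fragments; a read pair counts
once everywhere.  No effective-length or bias correction is applied —
deliberately, since length-model corrections are themselves a bias
source on these data.  For MMGs, which have no single defensible
transcript length, the package reports length-free FPM
($R_c / R_m$), with `logFpm()` applying a configurable pseudocount
(default 1) before the log.  $R_m$ is the total number of fragments in
the sample; for simulated perfect reads this equals the mapped total,
and for real data the choice between mapped and total is exposed through
the `librarySize` argument.

## What the simulator emulates — and what it does not

The generator reproduces the benchmark geometry: perfect 100-bp
paired-end reads with a 250-bp insert and zero errors, simulated from
the single longest transcript per gene, with fragment starts uniform on
the feasible range.  Transcripts shorter than the insert cannot be
simulated — the reason the 400-bp minimum transcript length exists.  Two
depth designs are built in: the *global* design (a fixed 1000 pairs per
gene) and the *targeted* design (per-gene depth uniform on
[100, 100000]).

Gene families are modelled as one ancestral sequence copied $k$ times
with independent per-base substitution at a divergence rate; divergence
0 gives identical copies, which force every read from any member to
exactly $k$ equally good loci.  Transcripts are embedded in a synthetic
genome separated by random intergenic spacers, contiguously by default
or split into exons by fixed-length introns; the truth aligner reports
every exact-match locus (both orientations), pairs mates by orientation
and insert, sets NH accordingly, and emits spliced (`M/N`) CIGARs for
intron-aware layouts.

Defaults chosen where the benchmark design is silent: transcript lengths
are drawn uniformly between 400 and 2500 bp (bracketing typical mRNA
lengths while keeping desk-scale runs fast), intergenic spacers are
300 bp, and synthetic ids are `GENE0001…`/`FAM1_1…`.  Three independent
RNG streams (seed, seed + 1, seed + 2) drive sequence generation, depth
draws and read placement, so count-only runs and full runs agree on the
same truth.

Passing tests on these simulations demonstrate the counting and
grouping logic, not real-data robustness: there is no sequencing error,
no quality or GC bias, no splice-junction reads beyond the known layout,
no incomplete annotation, and alignment is exact rather than heuristic.
Results on real aligner output will additionally reflect aligner
behaviour (e.g. how many loci it reports and caps) that the truth
aligner idealises away.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout, the Bioconductor
  convention; GTF needs no conversion at the boundary.
* Tie-breaks are lexicographic everywhere (reference transcript
  selection, collapse order), making every output reproducible
  byte-for-byte under a fixed seed.
* A zero-variance expression vector yields `NA` correlation, a sample
  with nothing unassigned yields `NA` rescue percentage — markers, not
  errors.  Division thresholds (`minReads`, `minSamples`,
  classification bounds) are validated and strict/inclusive exactly as
  documented.
* Gene classification against a uniform-depth truth uses strict
  inequalities: a count of exactly 100 is not underestimated and exactly
  1900 is not overestimated.  For variable-depth designs these absolute
  bounds are meaningless, so classification can be made relative to
  expected counts via `relativeTo`.

## A worked example

A 20-gene transcriptome with one identical two-member family, 100 pairs
per gene:

```{r example}
res <- runPipeline(list(
  nGenes = 20, pairsPerGene = 100,
  families = data.frame(size = 2, divergence = 0),
  seed = 1, minReads = 100, minSamples = 1))
fateTallies(res$stage1$sample1)
assay(res$mmg, "counts")
res$rescue[, .(unassigned, rescued, rescued_pct)]
```

Stage 1 assigns the 2000 fragments of the 20 unique genes and discards
all 200 family fragments as `alignment_not_unique`; stage 2 recovers
every one of them into the single group `FAM1_1|FAM1_2`.

## Problem sizes used in the checks

The shipped test-suite and acceptance script exercise the method at
desk scale: the full 19,654-gene global design is generated in
count-only mode (19,654,000 pairs), while sequence-level runs use a few
hundred genes at the global depth of 1000 pairs — enough for every read
to be represented and for the count histogram and FPKM correlation to
be measured exactly.  Filter/collapse rules are cross-checked against
brute-force re-implementations on a thousand random instances of up to
12 groups and 27 samples.

## Known limitations

* The truth aligner searches the embedded transcript space; a read that
  coincidentally matches intergenic spacer sequence would be missed.
  With uniform random spacers and 100-bp reads the probability is
  negligible, and the property tests compare against a naive full-genome
  scan.
* Stage-1 semantics aim at htseq-count's documented behaviour, not
  bug-for-bug parity with any specific release.
* Transcript-level (isoform) quantification, model-based estimators and
  differential expression are out of scope; the package exports
  edgeR/DESeq2-ready matrices instead.
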