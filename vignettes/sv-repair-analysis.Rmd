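---
title: "Identifying radiation-induced structural variants and their repair signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying radiation-induced structural variants and their repair signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svradiate)
```

## The problem

Long-read sequencing of irradiated plants yields, per sample, a set of
structural-variant (SV) calls against a reference genome: deletions,
insertions, duplications, inversions and inversion-duplications. Two
obstacles stand between those call sets and a statement like
"UV-B induced *n* SVs, *x*% of them repaired by microhomology-mediated
end joining":

* an untreated seed stock already differs from the reference by
  hundreds of SVs (its *pedigree*), only partly shared between
  biological replicates, so induced variation must be isolated by
  subtraction under a coordinate-tolerant notion of call identity;
* the repair pathway that produced a deletion is legible only in the
  fine structure of its junction — the short sequence identity between
  the two flanks that makes the breakpoint position ambiguous.

This vignette describes the models and conventions the package uses at
each stage, the parameters that matter, and what the synthetic
validation does and does not establish.

## Call identity, pooling and subtraction

Two calls are *identical* when they are the same SV type, on the same
chromosome, and both `start` and `end` agree within a tolerance
(`match_params()`, default 50 bp, applied to each breakpoint
independently; the inserted sequence is never compared). The tolerance
absorbs breakpoint wobble between samples from a long-read caller.

This relation is reflexive and symmetric but **not transitive**: call A
may match B, and B match C, with A and C 80 bp apart. The package
therefore never chains pairwise identity. Where a one-to-one
correspondence is needed (`match_sets()`), candidate pairs are taken
greedily by ascending total breakpoint distance with deterministic
lexicographic tie-breaks — a rule simple enough to verify against a
brute-force all-pairs oracle, which the test suite does on randomized
instances. Where a three-replicate concordance partition is needed
(`venn_partition()`), records become nodes of a match graph (edges only
between different samples) and each connected component is counted in
the Venn region given by the samples present in it; components holding
two records from one sample are flagged "inconsistent" rather than
silently resolved.

Pooling (`pool()`) is **concatenation, not union**: a pedigree
reference assembled from three untreated replicates of 248, 339 and
291 calls has size 878 even though the replicates share calls. This
mirrors how the subtraction baseline is assembled in practice — every
replicate observation is allowed to cancel a treated-sample call, and
deduplicating first would only change bookkeeping, not the subtraction
result. `subtract()` removes every target call matching any pooled
control record and keeps an audit of which control removed what.

The control structure is data, not code (`validate_config()`): treated
wild-type samples subtract the pedigree pool; treated mutants subtract
the untreated calls of their own genotype *and* the wild-type calls
under the same treatment, so that genotype-specific induced variation
is not confounded with treatment-generic variation.

## Filtering

`filter_calls()` retains records with SV length in
[`min_sv_length`, `max_sv_length`] (defaults 1 bp and 1,000,000 bp),
minimal supporting-read length ≥ 1000 bp and mapping quality ≥ 20. All
thresholds are inclusive — "minimal mapping quality 20" is read as "20
passes". Each rejected record is tallied once under the first criterion
it fails, so the tallies and the output partition the input exactly; the
tests lean on this conservation. The caller's own FILTER column is
honored by default (`PASS`/`.`), with a flag to ingest everything.

## Coordinates

Records store VCF conventions verbatim (`POS`, `END`, signed `SVLEN`)
so write-then-parse round-trips bit-exactly. For deletions, `POS`
anchors the base *before* the deleted run (the long-read caller
dialect), so the deleted bases form the 0-based half-open interval
`[start, end)` and `end − start` equals the length. Sequence access
(flanks, microhomology) converts to 0-based half-open at the module
boundary; annotation overlap queries use the printed
`[start, end]` span, with insertions as 1-bp anchors. BED inputs are
0-based half-open, GFF3 1-based inclusive; both are converted on
import by `load_annotation()`.

## Element assignment

Each record is assigned to exactly one of TE / PCG / IR by maximal
base-pair overlap over its query interval. Ties take the precedence
TE > PCG > IR — repetitive elements are the focus of SV analyses in
heterochromatin-rich genomes, so an SV half in a TE and half in a gene
is counted with the TE; the rule is a documented choice, exposed only
through its determinism. Centromeric membership uses the interval
midpoint (an SV straddling the pericentromere boundary belongs where
its center lies); HOT membership is any overlap of at least 1 bp,
because hotspot tracks are defined by overlap, not containment.
Chromatin states follow the nine-state segmentation convention, with
CS8/CS9 grouped as constitutive heterochromatin in summary output.

The genome background for enrichment tests is computed two ways — bp
fraction of each layer (default) and element-count fraction — because
published background panels are ambiguous between the two; the report
names the one used.

## Junction microhomology and repair labels

For a deletion `[s, e)` on reference `R`, define

* right extension: the largest `k ≤ w` with `R[s..s+k) = R[e..e+k)`,
* left extension: the largest `j ≤ w` with `R[s−j..s) = R[e−j..e)`,

with window `w = 50` bp, case-insensitive comparison, exact identity
only (no mismatch tolerance — the signature of interest is strict
micro-homology), and any N terminating the extension. The total
`j + k` is the junction microhomology; it is invariant under shifting
the reported breakpoints along the homology tract, which is exactly the
breakpoint ambiguity the homology creates. This invariance is what
makes an algorithmic replacement for manual junction curation testable:
a caller that places the breakpoint anywhere in the tract yields the
same measurement, and the suite asserts this over hundreds of
randomized cases, alongside a brute-force enumeration oracle.

Labels follow the total: ≤ 1 bp NHEJ (blunt or near-blunt end joining),
2–19 bp MMEJ, ≥ 20 bp an SSA candidate. The MMEJ band is bounded below
by the conventional 2 bp floor; the 20 bp boundary to canonical
single-strand annealing is where published ranges disagree (2–20,
2–25, 20–25 bp all appear in the repair literature), so all three
boundaries are configuration keys (`repair_params()`) and the defaults
keep the bands disjoint. "Low sequence quality in a flank" is
operationalized, in this reference-based reimplementation without
per-read data, as a flank truncated at a chromosome end or containing
any N (`max_n_fraction = 0`).

One-sided versus summed two-sided counting of the homology is not
settled by convention; the package reports both sides and sums them,
and records the per-side values in the output table.

## Insertion-origin tracing

Inserted sequences are located in the reference by seed-and-extend:
exact `k`-mer seeds (default `k = 15`, sampled every `k/2` positions on
both strands) nominate candidate windows, each window is locally
aligned with affine gaps (match +1, mismatch −2, gap open 4, gap
extend 1 — near standard nucleotide-BLAST weights), and hits within
100 bp of the insertion site are discarded so an insert never "finds"
its own flanking context. The best hit resolves the origin only if it
passes identity and query-coverage floors (both 0.8) *and* strictly
outscores the best hit at any other locus; an exact tie is reported as
ambiguous rather than broken arbitrarily, because on compact genomes
score ties are genuine duplications, not noise. Resolved donors are
classified by the same maximal-overlap rule as SVs; a donor overlapping
a TE without covering ≥ 95% of its span is flagged a truncated-TE copy
(the threshold is configurable; a full-span copy is the
transposition-like signature worth separating).

## The synthetic scenario

`scenario_spec()` defines the study conditions the generator emulates;
its defaults are fixed once and the tests are parameter-recovery
checks against them:

* genome: 3 chromosomes × 150 kb (a desk-scale stand-in for the
  5 × ~24 Mb plant genome), central centromeric zone of 20% per
  chromosome built from a 180-bp tandem repeat with 3% per-copy
  divergence — the repeat structure exercises the origin tracer's
  ambiguity handling; TE densities 0.5 (centromeric) / 0.15 (arms),
  PCG 0.05 / 0.30, states CS8/9 over the centromere and CS1–7 over
  arms, 4 HOT regions per chromosome;
* pedigree: 60 SVs, 50% in all three replicates (the core), the rest
  in one or two; induced: 40 SVs, all in the treated sample only;
  type mix DEL .45 / INS .35 / DUP .08 / INV .07 / INVDUP .05
  (INDEL-dominant, as observed in long-read plant call sets);
* deletion junctions are *engineered*: the reference is rewritten so
  that exactly the planned microhomology (default spectrum: mostly
  0–1 bp with a 2–6 bp MMEJ tail) extends across the junction, with
  mismatch guards one base beyond each side. Truth is exact by
  construction, so recovery tests assert equality, not approximation;
* insertion donors are copied from recorded loci (TE donors as 30–70%
  truncated sub-spans, 25% reverse-complemented, 70% intrachromosomal),
  placed on chromosome arms so random-sequence uniqueness holds;
* emission: pedigree records are independently jittered per sample,
  uniform on ±25 bp. Two jittered copies of one truth SV then differ
  by at most 50 bp — exactly the matching tolerance — so replicate
  identity and subtraction are guaranteed recoverable; the generator
  refuses larger jitter unless forced, making the stress mode explicit.
  Induced records exist in a single sample and are emitted at their
  precise breakpoints, so junction measurements on recovered induced
  calls stay exact. Distinct truth loci are kept ≥ 300 bp apart so
  jitter can never alias two SVs.

What passing these tests shows: the algebra, the junction measure, the
tracer and the bookkeeping are correct on inputs whose truth is known.
What it does not show: performance on real long-read call sets, where
breakpoint error is not uniform-bounded, deletions co-occur with
insertions of filler DNA, repeats are longer and older than the toy
centromere, and the SV caller itself has biased sensitivity. The
generator makes no claim to emulate those failure modes; it makes the
pipeline's *contracts* falsifiable.

## Numerical and design notes

* Quartiles of SV-size tables use linear interpolation
  (`quantile(type = 7)`); the INDEL aggregate pools DEL and INS.
* The homogeneity chi-squared applies no continuity correction, so the
  2×2 statistic equals the closed form `N(ad−bc)²/(r₁r₂c₁c₂)`.
* The rank-sum test reports the first sample's Mann-Whitney U with a
  normal approximation, tie-corrected variance and 0.5 continuity
  correction; identical samples short-circuit to p = 1 with a warning.
  No multiple-testing correction is applied by default, matching
  per-panel exact-p reporting; users can adjust downstream.
* Everything is deterministic: sorted record order
  (chrom, start, end, type, id), lexicographic tie-breaks in pairing,
  canonicalized JSON. Two runs of `run_all()` on the same inputs write
  byte-identical reports, and the test suite asserts it.
* Test problem sizes (scenarios of 2–3 chromosomes × 80–200 kb, 200
  engineered deletions, 50 traced insertions, 50 random pairing
  instances) were chosen as the smallest sets that exercise every code
  path with comfortable statistical margins.

## Limitations

* Breakend (BND) and translocation records are out of scope; only the
  five interval-shaped SV classes are handled.
* The repair classifier is reference-based: it cannot see filler-DNA
  insertions at NHEJ junctions or synthesis-dependent MMEJ tracts, and
  "undetermined" covers only truncation/N, not unresolvable repeat
  alignments.
* Origin tracing searches the supplied reference only — no external
  databases, no extrachromosomal DNA inference.
* Pooling-by-concatenation means subtraction stringency grows with the
  number of control replicates; that is intended (a pedigree call seen
  in any replicate is pedigree), but users comparing across designs
  with different replicate counts should note it.
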