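---
title: "Locus-resolved TE expression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-resolved TE expression: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telocus)
```

## Why locus resolution is hard, and what makes it possible

Transposable-element families exist as many near-identical genomic copies.
A read or an assembled transcript from one copy will usually align
acceptably to dozens of siblings, so family-level quantification is easy
but locus-level quantification is ambiguous by default. The signal that
breaks the ambiguity is post-insertion divergence: each copy carries
private substitutions and indels accumulated since it inserted. At a few
percent pairwise divergence, a transcript of a few hundred bases differs
from every sibling of its source copy at several positions, and an exact
(100% identity) alignment criterion can separate them.

`telocus` operationalises this with a four-stage cascade applied to each
assembled transcript against every reference locus that shares canonical
k-mers with it:

1. **Coverage**: at least 90% of the transcript length must align
   (`min_query_coverage = 0.90`). This removes chimeric or partially
   TE-derived contigs.
2. **Identity**: column identity over the aligned region must be at least
   0.95. Identity counts gap columns in its denominator — the strictest
   common reading of "percent identity" — so identity 1 is equivalent to
   zero mismatches *and* zero gaps.
3. **Perfect identity**: only alignments at identity 1 survive. Coverage
   may still be below 1, which is deliberate: truncated and spliced
   transcripts cover less than their locus but match it perfectly where
   they align.
4. **Tie curation**: transcripts whose best perfect alignment is tied
   across more than one locus — equal identity, coverage (rounded to four
   decimals) and score — cannot be placed and are removed. Ties are judged
   *globally*, against every k-mer-sharing locus, not just the partition
   that produced the transcript; uniqueness against a subset would be
   meaningless.

The cascade is monotone (raising any threshold never grows the assigned
set), its stage counts partition the input, and it is order-independent
(transcripts are processed in sorted order internally).

## Alignment model

The pairwise aligner is an affine-gap local (Smith–Waterman/Gotoh)
alignment with match +1, mismatch −2, gap open −4, gap extend −1 (a gap of
length L costs 4 + L). The scoring is exposed in `align_pair()` and fixed
as package defaults; the reference aligner for this step in the field is a
BLAST-family tool whose exact parameters are a configuration choice, so we
keep ours explicit and configurable. Identity and coverage are computed
from the traceback, not from the score. Tie-breaking is deterministic
(first-reached optimum in row-major order; diagonal preferred in
traceback). The implementation is ~100 lines of C++; the test suite checks
its scores against an independent full-matrix dynamic-programming oracle
written in R, on random and related pairs.

Reads are routed to loci before assembly by shared canonical 21-mers
(`min_hits = 2`), then `resolve_partition()` re-places each read pair on
its best-aligning candidate. k = 21 with two required hits was chosen so
that copies at ~5% divergence are separable while 1–2 sequencing errors per
read do not orphan it; both are configurable.

## Assembly as reference-placed consensus

Per locus, reads are placed by alignment, per-base depth is accumulated,
and maximal runs with depth ≥ 2 become *segment fragments* (depth 2
rejects singleton sequencing errors). The consensus is a per-column
majority vote with ties resolved to the reference base. Fragments are
joined into one transcript model only when a read or read pair has aligned
bases in both; otherwise they stay separate models. This is intentionally
not a de Bruijn assembler: in the genome-guided design the reference is
used as a substrate for grouping and placement, and a placed consensus is
the smallest mechanism that is exactly testable (on error-free tiled reads
the consensus must equal the locus sequence verbatim, and the suite asserts
exactly that).

A model is classified *spliced* when it has ≥ 2 fragments, or when its
single fragment is shorter than 90% of the locus's genomic length —
evidence that part of the nascent RNA was removed.

## Quantification

Counting is assignment-based: each read unit (pair) increments the
transcript with its best alignment identity; exact ties count to nothing
and are tallied as ambiguous. TPM uses transcript length as effective
length — no fragment-length correction, because the simulator's fragment
model is not a claim about any particular library chemistry; the
`effective_length` slot is exposed so a correction can be substituted. Per
sample, TPM sums to 10^6 unless every count is zero (the one documented
exception).

## Lineage classification

`liftover_fraction()` follows the single best-scoring chain overlapping an
interval (the liftOver convention the definitions presuppose) and reports
the fraction of bases inside aligned blocks plus the query-side images;
`reciprocal_fraction()` composes a forward and a backward pass. Three
independent flags follow:

* **primate-specific**: direct remap fraction to the outgroup genome
  (mouse role) < 0.10;
* **highly conserved in primates**: min(direct, reciprocal) ≥ 0.95 for
  *both* sister genomes (chimpanzee and bonobo roles);
* **candidate human-specific**: direct fraction < 0.10 to both sisters.

The flags are deliberately not a partition — a family can have loci that
are simultaneously conserved and primate-specific — because the
per-family summaries count them in side-by-side columns. Loci mapping to
exactly one sister genome receive neither the conserved nor the
human-specific flag; the source definitions are silent on this case and we
chose the conservative reading. Thresholds (0.10, 0.95) are exposed but
default to the published values. The per-family signed ratio is
human-specific/conserved when human-specific copies predominate and
−(conserved/human-specific) otherwise, rounded to one decimal, with a
signed-infinity sentinel at zero denominators.

Chain parsing validates the format's block-sum invariants and refuses
inconsistent files outright. The liftover arithmetic is property-tested
against a naive per-base mapping oracle over randomized chains, including
minus-strand queries.

## Enrichment statistics

Margins `(N, K, n, x)` come from interval overlap (a locus counts once if
it overlaps any feature by ≥ 1 bp). `hypergeom_upper()` is the standard
upper tail P(X ≥ x) via `phyper`; `fisher_two_tailed()` is the standard
two-sided exact test. We additionally expose `hypergeom_point()`,
P(X = x), because published enrichment tables are sometimes computed as
the point probability of the observed table rather than its tail — the
revTAD-style worked examples in our acceptance suite reproduce the
published values only under the point convention (the upper tail gives
values ~1.6× larger for the headline margin). Both are reported by
`enrich_test()` so the convention is always explicit.

## Case/control signatures

Detection filtering is two sequential inclusive gates: CPM ≥ 1 in ≥ 2
samples, then detection (count > 0) in ≥ 50% of samples. The built-in
differential tests are transparent stand-ins acting on CPM: a seeded
label-permutation test of the group mean difference (default; p = (1 +
#{|null| ≥ |obs|})/(n_perm + 1)) or Welch on log2(CPM + 0.5). A
negative-binomial count model is *not* reimplemented; the `external`
method accepts a precomputed table from a dedicated package, which is the
faithful route for real studies. Fold changes use pseudocount 0.5 on mean
CPM. Stratification gates on p < 0.05, |log2FC| > a configurable threshold,
and detection in ≥ 50% of the favoured group. The fold-change threshold
defaults to 1 (2-fold) but carries no claim of being canonical: published
descriptions of this step mix "2-fold", "logFC > 2" and "±4", which are
mutually inconsistent, so the parameter is explicit.

## The simulator and what it does (not) show

`sim_config()` defaults encode the study design the package emulates: 19
samples (9 cases), 100 bp strand-specific paired reads, Poisson read
counts per transcript, i.i.d. base errors with the Phred score implied by
the error rate, a 2-log2FC differential effect on a 10% subset, and TE
families at 5–10% per-copy divergence with short geometric indels (p =
0.5, capped at 5 bp) and optional 5′ truncation. Copies are mutated
independently from their consensus (a star phylogeny): the operational
premise is that accumulated private variants distinguish copies, and a
star is the smallest model with that property. Three non-focal genomes
named `outgroup`, `sister1`, `sister2` play the mouse/chimp/bonobo roles
through generated chain files; conserved loci sit in aligned blocks,
species-specific loci in chain gaps.

The simulator is deterministic: a fixed seed yields byte-identical files,
and the pipeline manifest hashes are reproducible end to end. Truth tables
(copy mutations, read→locus map, per-transcript counts, lineage labels,
annotation categories) are sufficient to score every downstream metric.

What passing tests on simulated data do *not* show: real repeat landscapes
(nested/fragmented elements, satellite context), GC and hexamer coverage
bias, quality-score miscalibration, intron-containing TE transcripts
spanning non-TE sequence, or chain files with rearrangements. Results on
real data depend on those factors; the simulation establishes correctness
of the machinery, not field performance.

## Problem sizes and numerical choices

The test suite and the acceptance script run the assignment benchmark at
200 loci (~6% pairwise divergence, error-free transcripts), lineage
recovery at 40 loci, null calibration at 1,000 transcripts × 19 samples ×
999 permutations, and signature recovery at 200 transcripts at depth 30 —
sizes chosen so the whole suite completes in a few minutes on one core
while keeping every estimate's sampling error well inside its acceptance
band. Alignment tie-breaks, consensus tie-votes (reference base), the
pair-level QC drop rule, and the stage-4 exact-tie definition (identity,
coverage to 4 decimals, score) are all deterministic so that identical
inputs give identical outputs regardless of ordering.

## Known limitations

* Quantification has no multi-mapping rescue (no EM); ambiguous units are
  reported, not redistributed.
* Effective length ignores fragment-length distribution.
* The built-in differential tests do not model count dispersion; use the
  `external` route for study-grade inference.
* Lineage calls use one best chain per interval; paralogous chain unions
  are out of scope.
* The enrichment module implements the statistics, not permutation/rotation
  null models for genomic colocalisation.
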