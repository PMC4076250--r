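---
title: "Scaffolding draft assemblies with uncorrected long reads: methods"
author: "longscaff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding draft assemblies with uncorrected long reads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longscaff)
```

## The problem

Draft bacterial assemblies built from short accurate reads typically stop at
tens to hundreds of contigs: repeats and low-coverage regions break the
assembly graph even when the underlying genome is a single replicon.
Uncorrected single-molecule long reads (CLR-type, with a per-base error rate
around 15%, dominated by insertions and deletions, and a typical length of
2–3 kb) are individually too noisy to assemble on their own at modest
coverage, but each read that spans a contig boundary is direct physical
evidence of which contigs are adjacent, in which relative orientation, and
roughly how far apart. `longscaff` turns that evidence into scaffolds in
three stages, consuming a draft assembly (FASTA) and read-to-contig local
alignments (PAF or BLASR m4).

## Stage 1 — placement filtering

Each local alignment is first **extended to a projected full-contig span**:
with aligned read interval $[r_1, r_2)$, aligned contig interval
$[c_1, c_2)$ on a contig of length $L$, and local scale
$s = (r_2 - r_1)/(c_2 - c_1)$, the unaligned contig head and tail are
projected onto read coordinates ($r_1 - s\,c_1$ and $r_2 + s\,(L - c_2)$ on
the forward strand; the two tails swap sides on the reverse strand).
Extended spans may leave the read — they are deliberately kept unclamped,
because only their differences matter: the gap between two contigs on one
read is the distance between their extended spans, so a read that touches
two contigs only near its ends still estimates the full inter-contig
distance.

Because CLR alignments are noisy, one read region often aligns to several
contigs. A placement is removed when its *aligned* interval overlaps the
aligned interval of any higher-ranked placement by more than `g` bases
(default 200; ranking by score, then identity, then contig id and position
for determinism). Two readings of this rule are possible — compare against
every higher-scoring placement, or only against higher-scoring *survivors*.
We use the first: it is a pure pairwise predicate, which makes the survivor
set monotone in `g` (raising `g` can only admit more placements) and
exactly reproducible by an exhaustive oracle; the survivor-only variant
violates monotonicity because a placement eliminated at small `g` can
survive at larger `g` and then shadow a third one. Overlap is measured on
aligned intervals, not extended spans: extended spans legitimately overlap
across true gaps and would trigger false removals. Placements are
pre-filtered at identity ≥ 0.70 and aligned length ≥ 100 bp; 15%-error
reads align to their true contigs well above that identity, so these act
only as noise guards. For drafts that carry repeats on contig edges
(e.g. Ray-style assemblies), `g` should be raised to ~500.

## Stage 2 — the contig-linkage graph

Surviving placements are sorted by position along each read. Every
consecutive pair (A, B) records a **link** between the read-facing ends of
the two contigs — on the forward strand a contig exposes its tail
downstream and its head upstream; reverse-strand placements flip the ends —
with a signed gap estimate (negative = implied overlap). Links are keyed
canonically on unordered oriented end pairs, so the same physical junction
read on either strand accumulates in one record. The per-link gap estimate
is the **lower median** of the per-read estimates: always an observed
value, robust to a single chimeric or badly aligned read.

Reads spanning three or more contigs contribute their full oriented tuple
(and every contiguous sub-tuple of length ≥ 3) to a **multi-contig path
store**. The store drives three decisions:

1. **Transitive reduction.** A direct link X–Y is deleted when a stored
   path contains X and Y in the same relative orientation with at least one
   intervening contig (with paths A>B>C>D, the shortcut A–C is dropped).
   Such shortcuts arise when the aligner fails to place the middle contig
   on some reads. Deletions are computed simultaneously against the
   original graph, never cascaded.
2. **Ambiguity resolution.** Links with fewer than `k` supporting reads
   (default 3, suppressing single chimeric reads) are discarded. A contig
   end with several surviving candidates accepts the best one when the
   second-best/best support ratio is at most `r` (default 0.7); otherwise
   the path store is consulted, and a candidate confirmed as an adjacent
   pair by exactly one stored path wins. The ranking uses read support
   rather than summed alignment scores — the simplest defensible reading.
3. **Repeat flagging.** If neither rule resolves an end, the conflicting
   partners share exactly one neighbor — the contig owning the conflicted
   end — and that contig is flagged as a repeated element. This is the
   classic repeat signature: a two-copy repeat contig R between (U1, U2)
   and (U3, U4) shows U1 and U3 competing for R's head with balanced
   support.

A link must be accepted from **both** of its ends. Once repeats are
flagged, their placements are removed from the read paths and links are
re-derived, so the unique contigs flanking a repeat become directly
adjacent; their gap estimates, being differences of extended spans, then
automatically include the repeat's length. This iterates to a fixed point
of the flag set (in practice one extra pass). The re-derivation is this
package's mechanism for letting multi-contig linkage "solve" ambiguous
pairings; the first-pass path store is retained because it still holds the
repeat tuples needed for placement.

## Stage 3 — scaffolding

Accepted links give every contig end at most one partner, so scaffolds are
the connected components of the end-link graph, linearized by walking from
a free end (orientation propagates from the walk's seed). Components that
close on themselves are circular candidates: the cycle is opened at the
weakest-support junction (ties broken lexicographically) and the scaffold
is flagged circular. Then:

* **Repeat placement.** For each junction (X, Y), a stored path X>R>Y in
  the junction's orientation frame with ≥ `k` supporting reads and R
  flagged inserts a copy of R, with both gaps taken from the path's
  per-read estimates. A repeat may be placed at many junctions; two
  distinct repeats with tied support at one junction place neither (with a
  warning).
* **Edge trimming and rejoining.** Repeat contigs still sitting on
  scaffold edges are stripped (iteratively) and link acceptance is re-run
  restricted to terminal non-repeat contigs of distinct scaffolds,
  iterated to a fixed point — a superset of a single post-processing pass
  that cannot lose joins. Trimmed and never-placed repeats are emitted as
  singleton scaffolds, so every input contig appears in the output exactly
  once unless placed as a repeat copy.
* **Junction resolution.** A positive gap estimate becomes a run of that
  many `N`s. A non-positive estimate triggers an overlap search between
  the left contig's suffix and the right contig's prefix: candidate
  lengths within `merge_band` (default 100 bp) of the estimated overlap
  are scored by per-base identity, and the qualifying length (identity
  ≥ 0.85) closest to the estimate wins. Per-base (substitution-only)
  comparison is sufficient because draft contigs are short-read-accurate;
  the band, not indel alignment, absorbs long-read gap-estimate noise.
  Choosing the length closest to the estimate, rather than the
  highest-identity one, avoids spurious 1–3 bp exact matches. If nothing
  qualifies, a minimal gap of `min_gap_n` (default 1) N is emitted so the
  AGP always records the junction as unresolved rather than silently
  abutting sequence.
* **Circularization.** A scaffold whose two terminal ends carry a
  surviving link with support ≥ `k` is flagged circular; the closing
  junction is resolved like any other, and a closing merge trims the
  terminal overlap. Output FASTA stays linear — circularity is reported in
  the data model and summary, never enforced on sequence.

Outputs are a FASTA (reverse-oriented contigs as reverse complements, gaps
as `N` runs, merges spliced), an AGP v2.1 whose object lengths equal the
FASTA lengths exactly (gap rows: type `scaffold`, linkage `yes`, evidence
`align_genus`), a plain-text summary, and a TSV dump of the accepted
linkage graph. Scaffolds are named `scaffold_1..n` by decreasing length
(ties by first contig id), and the whole pipeline is deterministic:
identical inputs give byte-identical outputs.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `g` | 200 bp | aligned-interval overlap above which the lower-scoring placement is removed; ~500 for repeat-edged drafts |
| `min_identity` | 0.70 | placement pre-filter |
| `min_aln_len` | 100 bp | placement pre-filter |
| `k` | 3 reads | minimum link support |
| `r` | 0.7 | second-best/best support ratio accepted without path evidence |
| `merge_min_identity` | 0.85 | per-base identity for a verified overlap merge |
| `merge_band` | 100 bp | search slack around the estimated overlap |
| `min_gap_n` | 1 | N-gap emitted for unverifiable negative estimates |

`k` and `r` are exposed on the command line; the source method computes a
best-alternative ratio but publishes no threshold, so 0.7 with `k = 3`
follows common scaffolder practice.

## The simulator and what it does (not) show

The package ships a generator so the full pipeline is exercisable without
external data. It emulates a bacterial-scale experiment: a uniform-random
genome (optionally circular), planted repeat families (copies ≥ 97%
identical, 1% substitution divergence), fragmentation into contigs either
at repeat boundaries (each family emitted once as a shared contig, the
behaviour of drafts built by assemblers that split at repeats) or at
near-even random breakpoints, true inter-contig gaps drawn uniformly from
0–500 bp (sized so 2–3 kb reads span junctions), and CLR-style reads:
count fixed as `round(coverage * G / mean_length)` before length sampling,
lognormal lengths (arithmetic mean 2500 bp, shape 0.4, truncated to
[300 bp, G]), and per-base errors at 15% split 50/35/15 between
insertions, deletions and substitutions — an indel-dominant mix
approximating published CLR profiles.

`simulate_placements()` bypasses sequence alignment: read intervals are
intersected with the truth layout and each ≥ 100 bp overlap becomes an
ideal alignment record whose read coordinates are distorted by binomial
insertion/deletion counts per span. Gap estimates therefore carry
realistic indel noise while remaining exactly reproducible; with error
rate 0 the records are exact. Repeat copies map to the single shared
repeat contig, reproducing repeat ambiguity faithfully. What this does
*not* model: chimeric and adapter artifacts, quality-value structure,
coverage bias, diploidy, and aligner-specific failure modes — so green
simulations demonstrate the algorithm, not robustness to every real
library. The test suite therefore also includes an integration path that
aligns simulated error-carrying reads with minimap2 (`-x map-pb -c`;
`-c` is required, since without base-level alignment PAF column 10 is not
a usable match count) and runs the pipeline on the resulting PAF.

The truth-based evaluator compares junctions as canonical oriented
adjacencies (multiset semantics, so each copy of a repeat junction must be
recovered separately) and reports correct/missed joins, misjoins, N50 and
per-junction gap error. Gap exactness is measured on the *estimated* gap:
a 0 bp true gap is estimated exactly on clean data but cannot be emitted
structurally, because an AGP gap row needs ≥ 1 N and a merge needs ≥ 1 bp
overlap.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open on the forward strand of both
  read and contig (PAF-native); AGP output converts to 1-based inclusive
  at a single point. m4 records are normalized on input (reverse-strand
  coordinates flipped; negative scores stored as positive magnitudes so
  "higher is better" holds across formats).
* Extension uses `round()` on the projected tails; a zero-length aligned
  contig interval rejects the record.
* Lower medians are used for all gap aggregation (even support: the lower
  central value).
* Empty inputs degrade gracefully: an empty alignment file is a warning
  and an empty result, a read with one placement contributes no links but
  counts toward coverage, and an all-repeat scaffold dissolves into
  singletons.
* Without contig sequences (alignment-only mode) every junction falls back
  to an N-gap and FASTA output is skipped; contig lengths are taken from
  the alignment records.

## Problem sizes used by the checks

The shipped tests run entirely on simulated data at desk scale, chosen to
finish in minutes while keeping ≥ 10 reads of support per junction:
200 kb/20 contigs for noise-free exactness (20 seeds), 500 kb/40 contigs
at 50× for the noisy regime (20 seeds) and for the 5×–50× coverage sweep
(10 seeds), 150 kb with a 2-copy 2 kb repeat for repeat placement, and
exhaustive enumerations up to 5 contigs / 8 placements for the
transitive-reduction and filter oracles.

## Known limitations

* Only single repeats are placed between unique flanks; tandem or nested
  repeat runs (X>R1>R2>Y) are trimmed and emitted as singletons rather
  than placed.
* Gap *filling* with read consensus, contig polishing and error
  correction are out of scope — junction sequence is either verified
  contig overlap or `N`s.
* Repeat detection relies solely on conflicting adjacencies; a repeat
  whose copies are never spanned together with distinct flanks simply
  stays unlinked (no coverage-based detection).
* The scaffolding core is single-threaded by design; at bacterial scale
  runtime is dominated by the external aligner.
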