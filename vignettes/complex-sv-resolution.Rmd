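---
title: "Resolving complex structural variants from assembly alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving complex structural variants from assembly alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexsv)
```

## The problem

When a phased haplotype assembly is aligned to a reference genome, most of
the contig aligns as long colinear blocks, and simple structural variants
(SVs) appear as gaps: a reference gap with no query gap is a deletion, a
query gap with no reference gap an insertion, a strand flip an inversion, a
reference back-step a tandem duplication. Complex structural variants
(CSVs) — here defined as SVs with more than two breakpoints — break this
one-gap-one-variant picture. They combine deletions, inversions,
duplications and *template switches* (segments copied from a distal donor
locus), and their breakpoints typically fall inside segmental duplications
(SDs): repeats longer than 1 kbp with more than 90% identity between
copies. Because a recombined SD copy aligns equally well to either
reference copy, the raw alignment of a CSV often *mimics* a simple deletion
or duplication, misleading downstream callers.

`complexsv` resolves this by treating variant calling as a path problem.
Alignment records become nodes of a directed acyclic graph (DAG); candidate
variants connecting record pairs become weighted edges; the accepted
callset is the minimum-penalty path from a source (before the first record)
to a sink (after the last). Because every edge runs from a smaller query
start to a larger one the graph is acyclic, and the shortest path is found
by single-pass relaxation in topological order — the $O(N+E)$
specialization of Bellman–Ford on DAGs (literal Bellman–Ford would be
$O(N\cdot E)$; on a DAG one pass in topological order reaches the same
fixed point).

## Pipeline stages

1. **Anchoring** (`index_and_anchor`): exact k-mer matches (default
   $k = 31$, odd so no k-mer is its own reverse complement) restricted to
   k-mers unique in the reference under canonical (strand-collapsed)
   counting. High-identity repeat stretches therefore never anchor, which
   is what lets SD-mediated events surface as unaligned gaps.
2. **Chaining** (`chain_anchors`): maximal colinear runs; a chain breaks on
   strand change, loss of reference monotonicity, or a diagonal shift
   beyond `max_gap` (10 kbp).
3. **Record extraction** (`extract_records`): same-diagonal runs become
   `=`/`X` blocks by direct base comparison; inter-run gaps up to `band`
   (2 kbp) are closed by global edit alignment; larger gaps terminate the
   record. Records are then split at internal indel runs of at least
   `split_indel` (50 bp, the minimum SV size) so that every SV-scale event
   is represented *between* records and flows through the graph uniformly —
   without this, a sub-2-kbp deletion would hide inside one CIGAR.
4. **Trimming** (`trim_overlaps`): where two records overlap on the query,
   the lower-scoring record is cut at the overlap (ties: the record with
   the larger query start loses), and remnants under `min_keep` (200 bp)
   are dropped. Output query intervals are pairwise disjoint and trimming
   is idempotent.
5. **Candidate enumeration** (`enumerate_candidates`): for each ordered
   record pair within `max_join` (1 Mbp) of query distance, gap imbalance
   yields DEL/INS candidates, strand change INV (or INVDUP when the
   inverted record overlaps the entering record's reference span),
   reference back-steps DUP, and unaligned query gaps are probe-scanned
   against the whole reference (repeats included, both strands): a distal
   hit cluster — farther than `switch_dist` (50 kbp by default) or on
   another sequence, explaining at least `ts_min_support` (80%) of the
   probes — proposes a TEMPLATE_SWITCH as a parallel edge.
6. **Solving and classification** (`solve_optimal_path`,
   `accept_and_classify`): variants on the optimal path are accepted.
   Accepted variants whose reference footprints lie within
   `merge_adjacent` (1 kbp) collapse into one composite call whose
   *signature* is the hyphen-joined token string in reference order
   (e.g. `DEL-INV-DEL`); tokens range over DEL, INS, DUP, DUPn (n ≥ 3
   tandem copies), INV, INVDUP. Each call carries a segment tiling of its
   query span (flank copies, inverted segments, donor copies, novel
   insertions) from which `reconstruct_haplotype` rebuilds the allele —
   byte-identically on noise-free fixtures, which is the pipeline's
   internal correctness oracle.

## The penalty model

The scoring function of the original implementation is not published, so
the model here is the package's own design, exposed through `sv_params()`:

* base penalty `open(class) + size_coef * log2(1 + span)` with open costs
  INS/DEL 2, INV/DUP 3, TEMPLATE_SWITCH 4 and `size_coef = 0.5`; null
  transitions cost 0. This prefers the fewest, smallest events — a
  parsimony criterion.
* an *alignability surcharge*: insertion content whose sampled k-mers match
  the reference pays `unaligned_rate` (0.02) per alignable base. Without
  it, the log-compressed size term makes "delete the segment and reinsert
  it" cheaper than using the segment's own alignment, and inversions or
  extra tandem copies would be misexplained as insertions. Template
  switches name their donor and pay no surcharge.
* a *jump surcharge*: DEL/DUP candidates spanning more than `switch_dist`
  pay `jump_open` (8) extra; a reference jump that far is better modelled
  as a template switch.
* query bases forfeited at SOURCE/SINK are penalised like alignable
  insertions, so the path cannot cheaply skip aligned records wholesale.

Ties are broken deterministically: fewer edges, then the lexicographically
smallest node sequence. A property suite checks the solver against
exhaustive path enumeration on randomized DAGs.

## Breakpoint conventions

A call is complex iff it has more than two breakpoints. Per-event
breakpoint multiplicities are DEL/INV/tandem-DUP 2, INS 1, INVDUP 3
(the duplicated-inverted junction is structurally distinct), DUPn n, and
template switch 4 (two target edges plus two donor edges); positions shared
between adjacent events in a cluster count once. This keeps lone
DEL/INS/INV/DUP simple while inverted duplications, higher-copy elements,
distal switches and all multi-event clusters are complex — matching the
taxonomy in which inverted duplications and higher-copy elements are
counted among composite signatures.

Breakpoints of deletions, insertions and inversions are ambiguous under
junction homology: if the first bases of a deleted interval equal the bases
after it, several placements produce the same haplotype, and with ~1/4
probability per junction a random fixture has at least one such base. The
package therefore ships canonical normalizations (`normalize_del`,
`normalize_ins`, `normalize_inv` — left-alignment for deletions, left
rotation for insertions, maximal symmetric expansion for inversions), and
exact-breakpoint comparisons are made between canonical placements on both
sides.

## Mimic flagging

The paper-level observation is that a recombined SD copy aligns to both
reference copies, so a CSV's outer alignment footprint looks like a simple
deletion (or duplication). A length-based test is tautological — any net
loss "is consistent with" a deletion of itself — so `flag_mimics` tests the
junctions instead: a complex call with nonzero net length change is a mimic
when a window (1 kbp) at the end of one of its interior inverted/donor
segments matches the reference in *forward* orientation (k-mer coverage at
least `mimic_cov = 0.3`). That is exactly the paralogous-junction situation
in which a naive aligner absorbs the segment into the flanks. A plain
inversion's junctions match only in reverse orientation and balanced events
are excluded outright, so simple and balanced calls are never mimics.

## The simulator as study condition

`make_reference` draws i.i.d. uniform bases (optional GC knob) and implants
SD pairs by copying one interval onto the other (reverse-complemented for
inverted pairs) with point substitutions at rate $100 - \mathrm{identity}$
percent. `random_plan` places DEL, INS, INV, TANDEM_DUP, INV_DUP and
DISTAL_SWITCH events uniformly with a minimum spacing of 500 bp between
footprints (donors included) so anchors exist between events; sizes default
to 200–5,000 bp (insertions 100–1,000 bp), tandem copy numbers 2–4, and
switch donors at least 60 kbp from their target. Operations are applied
right-to-left so truth coordinates stay reference-native, and truth records
are emitted per event cluster using the same 1-kbp adjacency rule as the
classifier, so truth and caller speak the same signature grammar by
construction. `simulate_cohort` implants shared variants in
`round(AF * 2n)` haplotypes at identical coordinates.

What the simulator does *not* emulate: sequencing or assembly error (the
haplotypes are exact), N runs, nested/overlapping events, mobile-element
homology, and the megabase scale of real SD-mediated CSVs. Passing tests
therefore demonstrate the correctness of the decomposition, scoring, path
selection, classification and merging machinery on faithful miniatures —
not robustness to assembly noise.

## Problem sizes and test design

The bundled benchmarks use 150-kbp references with five events per plan;
200 seeded plans form the main recovery suite (signature recovery,
exact simple breakpoints after normalization, byte-identical
reconstruction), 1,000 randomized DAGs of up to 12 nodes the solver oracle
suite, and 100 seeded clustered callsets of up to 50 calls the merge
oracle suite. These sizes keep the full suite comfortably within a few
minutes on one CPU while covering every event class; the scaled-down
SD worked example (80 kbp, 3-kbp inverted SD pair at 98% identity, a
deletion–inversion–deletion across it) reproduces the DEL-INV-DEL
signature with its mimic flag.

## Merging and population statistics

`merge_nonredundant` implements a greedy lead-first merge: candidates
sorted by descending current support, then position, then sample; a call
joins a merged variant iff reciprocal overlap ≥ 0.5 and, when both calls
carry sequence, global identity ≥ 0.8 (unit match, −1 mismatch/gap;
`sequence_identity`). Insertions, whose reference footprint is empty, are
gated by breakpoint proximity (≤ 500 bp) and length ratio (≥ 0.5) before
identity. Variant classes never merge across types, and the identity gate
is applied only to sequence-bearing calls (deletions are sequence-free in
the merge). Because the exact ordering rules of the original merging tool
are not published, a transitive-closure clustering oracle guards the greedy
result on well-separated random callsets. `allele_frequency` removes
excluded samples (e.g. trio children) from numerator and denominator
alike; `filter_mask` applies BED masks with the any-overlap rule used for
complex calls over centromeric satellite annotation, or a stricter
containment mode; `link_across_references` pairs calls made against two
references through their shared assembly (query) coordinates.

## Known limitations

* Inversions split into several minus-strand records (possible under heavy
  internal divergence) are tokenized per record; the simulator never
  produces this, real data could.
* The template-switch donor search reports one donor per gap; co-equal
  SD copies are disambiguated by support then coordinate, so the reported
  donor of a perfect-identity pair is a canonical, not unique, choice.
* Minus-strand *flank* records (a whole contig aligned inverted) are not
  given flank-copy segments during reconstruction; calls inside such
  contigs round-trip only when their outer anchors are plus-strand.
* `sequence_identity` clips sequences beyond 6 kbp to their ends before
  the quadratic alignment; merge decisions on longer insertions are
  end-anchored approximations.
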