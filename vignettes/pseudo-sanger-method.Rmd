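---
title: "Pseudo-Sanger assembly: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-Sanger assembly: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Illumina-class sequencers produce accurate but short reads. Many questions —
de novo assembly across repeats, base-pair-resolution structural variation,
marker genes in metagenomes — want reads that are long *and* nearly
error-free, like classical Sanger capillary reads. Pseudo-Sanger (PS)
sequencing reconstructs such reads computationally: a *nested* set of
paired-end libraries with stepwise decreasing insert sizes (for example
600, 400, 300, 200 bp) is sequenced from the same DNA, and the unsequenced
gap inside each large-insert pair is filled by a local assembly of the
smaller-insert pairs. The filled-in fragment — anchor read 1, the gap, and
anchor read 2 — becomes one PS read of roughly the large library's insert
length, with the consensus depth of all reads that map inside it.

Terminology used throughout: an **anchor read (AR)** is a pair from the
largest-insert library whose internal gap is being filled; **supporting
reads (SRs)** are pairs from the smaller libraries; the first consensus over
the anchored layout is the **primitive** PS sequence; SR pairs mapping
entirely inside it are **inner** pairs.

## The procedure

For each anchor pair, three steps:

1. **Candidate search.** All SR reads are indexed with blocked spaced seeds
   (contiguous care-blocks separated by don't-care columns). Both anchor
   reads are scanned base by base against this index, *as sequenced*: a
   read matching anchor read 1 forward is the left end of a pair whose
   partner points into the gap, and a read matching anchor read 2 forward
   is the right end of such a pair. Reads that only match an anchor in
   reverse belong to outward-pointing pairs — their partners lie outside
   the fragment — and are discarded; this is the forward-overlap rule.
   Every seed candidate is verified by gapless extension across the full
   implied overlap; if the mismatch fraction exceeds a threshold, a
   Smith-Waterman alignment is tried instead. Admitted pairs are
   re-oriented onto the anchor fragment's forward strand.

2. **Repeat gate and anchored layout.** Under uniform coverage at summed SR
   depth $D$, read length $L$ and minimum overlap $O$, the expected number
   of SR reads overlapping one anchor read is
   $E = D\,(2(L-O)+1)/L$.
   An anchor read attracting more than $1.5\,E$ verified hits is treated as
   repetitive and no PS read is built from that pair (the factor is
   configurable). Otherwise an overlap graph is built over the cluster —
   nodes are reads, directed edges are suffix–prefix overlaps of at least
   $O$ bp passing the identity threshold, contained reads are recorded
   separately — and a heap-driven search finds the layout from the left
   anchor to the right anchor that maximises the total number of overlapped
   bases, subject to the layout span falling inside the anchor library's
   insert range. The per-column plurality over the layout reads is the
   primitive PS sequence.

3. **Inner-pair refinement.** The primitive is queried against the SR index
   without gap alignment, in both orientations, keeping reads that lie
   entirely inside it; for each pair with one placed end the partner is
   placed inside the window implied by its library's insert distribution
   (gapless first, Smith-Waterman as fallback), and pairs whose partner
   cannot be placed fully inside are dropped. The final consensus re-votes
   every column over the layout reads, the recruited inner pairs, and the
   anchor-verified overlap hits from step 1; the winning vote fraction
   gives a per-column Phred-scaled quality capped at Q40.

Anchors gated as repetitive or failing assembly leave coverage holes, so
the pipeline iterates: the next-largest library's pairs are promoted to
anchors over the remaining smaller libraries, excluding pairs that were
already consumed as both-ends-inside contributors to an emitted PS read.
Reads never used in any local assembly are written aside for downstream gap
closing.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `seed_pattern` | `1111111001111111` | blocked spaced seed, span 16 bp, weight 14 |
| `sr_stride` | 2 | indexing stride over SR reads (anchors scanned at stride 1) |
| `min_overlap` | 30 bp | minimum verified read overlap $O$ |
| `max_mismatch_rate` | 0.08 | gapless-extension failure threshold |
| `sw_scores` | 1, −2, −3, −1 | match, mismatch, gap open, gap extend (gap of length $k$ scores $-3 - k$) |
| `sw_min_identity` | 0.92 | acceptance identity for gapped alignments |
| `repeat_factor` | 1.5 | repeat gate multiplier on $E$ |
| `insert_range_mult` | 3 | layout span constraint: mean ± 3 sd of the anchor library |

The seed pattern deserves a note. Candidate discovery is the only
non-verified step, so the pattern controls sensitivity alone, and we size
it against the worst case the overlap rule permits: a 30 bp minimum overlap
carrying independent sequencing errors on both reads. A long seed (span
near the minimum overlap) leaves so few windows inside a 30 bp overlap that
one mid-overlap error removes them all; with span 16 several windows fit
and the measured admission rate of truly-overlapping pairs exceeds 99% at
0.5% per-read error. Chance 14-mer collisions between unrelated reads are
eliminated by the gapless verification that follows every candidate.

## The layout search

The overlap graph can contain cycles in principle, but every suffix–prefix
edge advances the layout offset by at least one base. The search therefore
runs over *states* (node, offset), expanded from a heap in increasing
offset order; the state space is a DAG bounded by the insert-range maximum,
so the maximum-overlap layout is found exactly rather than greedily, and
arrival states at the right anchor are feasible exactly when their span
lies inside the insert range. Direction of search does not affect this
optimum, so a single left-to-right sweep is used instead of a bidirectional
meet-in-the-middle; exactness and reproducible tie-breaking are easier to
guarantee this way. Ties resolve by larger overlap total, then smaller
span, then the lexicographically smallest node sequence, the last
reconstructed against a backward score table so the choice is
deterministic under any input permutation.

Consensus tie rules: plurality per column; at a tie the covering read with
the smaller offset wins, anchors outranking supporting reads at equal
offsets. Gapped placements vote through their alignment operations —
deletions vote for a gap symbol (a winning gap removes the column),
insertions relative to the consensus coordinate do not create columns.

## What the final consensus votes

Besides the layout reads and the recruited inner pairs, the final consensus
votes the anchor-verified overlap hits from the candidate-search step at
their verified diagonals, including reads that cross the primitive's ends.
Without them the terminal handful of columns of every PS read is covered by
the anchor read alone (a fully-inside rule cannot recruit a read crossing
the boundary), anchor sequencing errors survive there, and the residual
error concentrates entirely in the first and last position bins instead of
being uniform along the read. These hits carry exactly the same alignment
evidence as everything else voted, so including them is the natural reading
of consensus-over-everything-placed; the measured effect is a flat residual
profile and edge columns at full depth.

## The simulator

The generator mirrors a modified-wgsim design: a random i.i.d. reference,
a second haplotype derived by independent per-site mutation at the chosen
heterozygosity, uniform fragment starts, Normal insert lengths (rounded,
truncated to at least read length + 1 and at most the genome length),
uniform haplotype and strand choice, FR read pairs, and independent
per-base substitution errors that never reproduce the original base. No
coverage bias, chimeric fragments, indel errors, quality models or PCR
duplicates are simulated; quality strings are a constant Q30 symbol since
the method never consumes them. Per-pair truth records (haplotype,
fragment interval, strand, injected error offsets) are emitted so
evaluation needs no mapper. One master seed drives everything; per-library
streams are derived deterministically from it, and identical seeds yield
byte-identical FASTQ output. The insert-size spread defaults to 10% of the
mean — a value typical of tight gel-based size selection — because the
study conditions specify only the means; it is exposed as a parameter.

Interspersed repeats can be seeded by copying one subsequence to
non-overlapping random positions, identically on both haplotypes, to
exercise the repeat gate and the iterative anchor demotion.

Because the simulation is diploid and supporting reads come from both
haplotypes, the consensus keeps the majority allele at heterozygous sites —
a coin flip at 50/50 depth. Evaluation therefore scores a mismatch column
as an error only when the PS base matches *neither* haplotype allele at
that position; indel columns always count. Counting the discarded
heterozygous allele as an error would put an artificial floor of roughly
half the heterozygosity (0.05% at het 0.001) under any consensus method.

What passing on this simulator does and does not show: the generator has
no coverage bias, no chimeras and no indels, so the results certify the
algorithm — orientation handling, layout optimality, repeat gating,
consensus correctness — under the stated error model, not robustness to
library artefacts of real data. Real-genome repeat structure is only
caricatured by identical seeded copies.

## Problem sizes and numerical choices

The packaged experiments use a 100 kb repeat-free genome and a 200 kb
genome with 50 copies of a 400 bp repeat (shorter than the 600 bp anchor
insert, hence resolvable), both at 60× total coverage across four
libraries; these sizes keep a full run in the low minutes on one core while
leaving thousands of anchors per pass. Truth evaluation uses banded global
alignment with unit costs and a band of the length difference plus 30.
Degenerate inputs are handled conservatively: `N` never matches a seed key
and never matches in alignment; reads shorter than the seed span are
skipped and counted; empty clusters and infeasible insert ranges fail the
anchor, never the run.

The implementation is single-threaded; anchors are independent work units
merged in input order, so the output is identical regardless of scheduling
and a thread-count setting is accepted only for interface compatibility.

## Known limitations

- Only the majority allele survives at heterozygous sites; no dual-haplotype
  output.
- Layout placements are substitution-only (matching the error model);
  indels enter only through the Smith-Waterman fallback during recruitment.
- The expected-count formula for the repeat gate is a reconstruction from
  its stated variables, validated by Monte-Carlo simulation within the
  package's own tests.
- Downstream contig assembly of PS reads is out of scope; PS FASTQ output
  is meant to feed an external overlap assembler.
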