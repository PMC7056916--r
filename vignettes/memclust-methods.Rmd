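---
title: "Methods: MEM-based greedy incremental clustering of long sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEM-based greedy incremental clustering of long sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memclust)
```

## The problem

Public collections of microbial genomes are heavily redundant: the same
species, often the same strain, is deposited many times as complete genomes,
chromosomes, or draft contigs. Dereplication reduces such a collection to a
set of non-redundant representatives. Classical sequence clusterers built for
reads or genes struggle at megabase scale, because their word-filter
heuristics and all-vs-all alignments do not carry over to sequences millions
of base pairs long.

`memclust` clusters long nucleotide sequences with the greedy incremental
scheme familiar from the CD-HIT family: sequences are sorted long to short,
the longest becomes the first representative, and every subsequent sequence
either joins the first earlier representative it is sufficiently similar to
or founds a new cluster. What makes megabase inputs tractable is the
similarity measure: instead of aligning whole genomes, the query is compared
to representatives through its **maximal exact matches** (MEMs), enumerated
from a **sparse suffix array** over the representative text.

## The identity model

A MEM between a representative $S$ and a query $P$ is an exact match that
cannot be extended on either side without a mismatch or a sequence boundary.
All MEMs of length at least `minlen` are collected, then refined to a
consistent segment set in four steps, applied to the projections on *both*
sequences:

1. MEMs whose span is completely contained in a single larger MEM are
   removed.
2. MEMs whose span is covered by the union of their two flanking neighbours
   (in begin-position order) are removed.
3. Remaining partial overlaps are trimmed: sweeping from the last MEM to the
   first, an overlap with the leftward neighbour (on either sequence) shifts
   the current MEM's start rightward on both sequences by the overlap
   amount; MEMs trimmed to nothing are dropped.
4. The surviving MEMs are extended outward under an x-drop rule with a score
   scheme (match reward, mismatch penalty, optional affine gaps): extension
   stops once the running score falls more than `xdrop` below the best score
   seen, and the best-scoring endpoint is kept.

The identity between query and representative is the extended-MEM identity

$$\mathrm{eMEMi} \;=\; \frac{N_{\mathrm{match}}}{L_{\mathrm{query}}},$$

where $N_{\mathrm{match}}$ is the number of identical aligned bases inside
the extended MEMs (matches only, also in gapped mode — aligned columns with
mismatches or gaps do not count) and $L_{\mathrm{query}}$ is the query
length. Because processing is long-to-short, the query is never longer than
the representative, so the statistic is a coverage-weighted identity of the
shorter sequence, capped at 1. A query joins the first representative whose
best-strand eMEMi reaches the `memiden` threshold.

## Sparse suffix arrays and MEM enumeration

Representatives are concatenated, each followed by a terminator that sorts
below every nucleotide; terminators are pairwise distinct in effect (ties
break by position), so no suffix comparison crosses a member boundary. The
full suffix array is built by prefix doubling with counting sort
($O(n\log n)$), the LCP array by Kasai's algorithm, and the sparse array
keeps every $K$-th text position (terminator positions excluded, since no
match can start there).

With sampling on the reference only, a MEM of length $\ell \ge L$ whose
start lies up to $K-1$ positions left of the nearest sampled suffix still
leaves a sampled match of at least $L-K+1$ characters. The finder therefore
searches **every** query position for sampled matches of length at least
$L-K+1$ (a top-down narrowing binary search yields the longest-match
interval; walking outward along the LCP array yields the exact match length
of every other candidate in the threshold interval). Each candidate is then
verified leftward over at most $K$ characters: if the scan finds the
left-maximal start within $K-1$ steps, the candidate is the canonical
(leftmost in-MEM) sample and the full MEM is reported; if $K$ characters all
match, the same MEM will be reported from the sample to its left, and the
candidate is skipped. Every MEM of length $\ge L$ is found exactly once, so
no deduplication pass is needed; the testsuite pins this against a
quadratic diagonal-scan oracle for all $K \in \{1,2,3,4\}$ and both strands.
This requires `minlen >= sparse_k`; shorter seeds would need a scanning
recovery path between sampled positions, which this package deliberately
omits (seeds below ~21 bp are dominated by chance matches anyway).

An `N` never matches anything, including another `N`: unknown sequence must
not contribute exact-match evidence. Structurally, however, `N` is an
ordinary letter of the index (the LCP array describes the plain
lexicographic order), and the mismatch rule is applied at search time.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `minlen` | 21 | bp | minimum MEM length. Under a uniform Bernoulli null no chance match materially longer than 21 bp is expected between ~1.7-Mbp random genomes, so 21 suppresses spurious seeds while keeping sensitivity; raise it (e.g. 41) to speed up clustering of close duplicates. |
| `memiden` | 90 | % | eMEMi threshold for redundancy. |
| `sparse_k` | 1 | — | sparse step $K$. $K=1$ is exact for any `minlen`; $K=2$–4 shrinks the index and speeds construction with no effect on results when matches are long (e.g. 100% identity clustering). |
| `chunk_mb` | 400 | Mbp | representative text per suffix-array block; bounds index memory. |
| `both_strands` | off | — | also compare the reverse complement; forward and reverse identities are computed independently and the larger wins (they are never pooled, which could double-count palindromic loci). |
| `gapped` | off | — | affine-gap x-drop extension; bridges indels, so it never finds fewer redundant sequences than ungapped extension on indel-divergent data. |
| `rebuild` / `rebuild_interval` | on / 64 | promotions | how often the block index is rebuilt over accumulated representatives; promotions since the last rebuild are searched through a buffer index. Pure performance knob — results are identical either way. |
| `threads` | 1 | — | workers for the inter-block screening pass (independent query-vs-index searches). Results are identical for every value. |
| score scheme | +1/−1, gaps −2/−1, xdrop 5 | — | extension scores. These follow common seed-extension practice and are configuration, not derived quantities. |

## Clustering algorithm

Input sequences are sanitized (uppercase; IUPAC ambiguity codes other than
`N` collapse to `N`), filtered (`min_keep`, default 21 bp), and sorted long
to short with input order breaking ties — the tie-break makes the whole
procedure deterministic. Records are partitioned greedily into blocks of at
most `chunk_mb` Mbp. For each block in turn:

a. the intra-block pass processes the block's sequences sequentially; each
   is screened against the representatives accumulated so far in the block
   (first satisfying representative wins, in discovery order) and is
   otherwise promoted;
b. after the block, an index over the block's representatives screens every
   still-unassigned sequence of later blocks, in global rank order.

Because each sequence is screened against earlier-block representatives
(step b of earlier blocks) before its own intra-block pass, and candidate
order is always discovery order, the final clustering is independent of the
block partition — a property the suite asserts — and equals the single-index
greedy result. Queries are only compared against representatives at least as
long as themselves; MEMs on shorter members are discarded during collection
(never emitted). Representatives of *equal* length are valid targets:
otherwise equal-length exact duplicates could never cluster.

## Numerical and tie-break choices

* **Ungapped x-drop endpoint:** among equal best prefix scores the shortest
  extension is kept (first maximum). The choice is pinned by an exhaustive
  best-prefix oracle in the tests.
* **Gapped extension:** banded affine DP (band width derived from
  `xdrop`, `gap_open`, `gap_extend`); rows terminate when every cell has
  dropped more than `xdrop` below the global best. Endpoint ties prefer
  higher score, then more matches, then fewer consumed positions.
* **Extension clipping:** neighbouring eMEMs could overlap after extension,
  double-counting matched bases in $N_{\mathrm{match}}$. Extensions are
  therefore clipped at the midpoint of the gap to the neighbouring MEM on
  each sequence (the right half of a gap belongs to the left MEM); sequence
  ends bound the outermost extensions.
* **Trimming of crossing MEM sets:** the right-to-left trim in
  representative order guarantees disjointness on the representative only.
  Raw MEM sets can cross (the query-order of matches need not follow the
  representative order), so a symmetric sweep in query order follows, and the
  pair repeats to a fixpoint. Trimming only ever shrinks spans, so the extra
  sweep cannot reintroduce overlaps; on collinear inputs it is a no-op.
  10,000 random (including crossing) fixtures assert the postcondition.
* **Identity at the threshold:** `memiden` is compared as
  `ememi >= memiden/100` on correctly rounded doubles; a 90% threshold
  admits exactly the queries whose rational identity is at least 9/10.
* **Degenerate inputs:** empty FASTA files yield empty record sets; an empty
  cluster set writes empty output files; a record larger than `chunk_mb`
  gets its own block; queries without any qualifying MEM score identity 0.

## The synthetic benchmark generator

Real dereplication inputs (RefSeq-scale genome collections) are multi-GB
downloads, so correctness is established on generated data with known truth.
`make_benchmark()` plants `n_groups` independent uniform-random
representatives; each copy is a random window (70–95% of the representative,
so the representative is the unique longest member) mutated by i.i.d.
substitutions and, optionally, 1–3-bp indels to a target identity;
`n_singletons` unrelated sequences are added. Everything is deterministic
per seed, with the global RNG state preserved.

The generator emulates the features the identity statistic responds to —
MEM fragmentation by substitutions, indel bridging by gapped extension,
containment redundancy via windowing, uniform base composition for the
chance-MEM null. It does **not** emulate repeat families, rearrangements,
horizontal transfer, GC skew, or realistic mutation spectra; passing the
truth-recovery tests therefore demonstrates the algorithm's correctness on
its own model of redundancy, not field performance on real genome
collections.

## Problem sizes used by the test suite

The suite verifies the chance-MEM null at its stated scale (three replicate
pairs of 1.7-Mbp random genomes, minimum MEM 15 bp, $K=1$); oracle
equivalence on 1,000 random pairs up to 500 bp across all sparse steps and
both strands; refinement geometry on 10,000 random MEM-set fixtures; exact
truth recovery on the 110-sequence standard benchmark (20 groups × (1+3)
members at 95% identity plus 30 singletons, 3–6 kbp); and the structural
invariances (threads, chunking, sparse step, rebuild schedule) and ordered
properties (threshold monotonicity, gapped ≤ ungapped cluster counts) on
6-group benchmarks of 1.2–2.5 kbp sequences. These sizes keep the full suite
in the minutes range while exercising every code path at the scales where
the algorithms' asymptotics already apply.

## Known limitations

* The quadratic-time fallback inherent in per-position top-down search makes
  near-identical megabase pairs slower than tools with matching-statistics
  suffix links; at the package's desk scale (kbp benchmarks, Mbp null
  checks) this is immaterial.
* `minlen < sparse_k` is rejected rather than recovered by scanning.
* Gapped extension reports matches on one optimal path; co-optimal paths
  with different match counts are resolved by the documented tie-break, not
  enumerated.
* The `.clstr` output dialect is a convention chosen for interoperability
  with existing dereplication tooling, not a format mandated by the method.
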