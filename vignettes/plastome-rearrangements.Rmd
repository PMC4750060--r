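---
title: "Methods: gene-order rearrangement, repeat screens and gene transfer in plastomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-order rearrangement, repeat screens and gene transfer in plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastrearr)
```

## The problem

Conifer chloroplast genomes have lost one copy of the canonical large
inverted repeat, and without it their gene order is unusually mobile:
related species can differ by many segmental inversions. Two things
follow. First, gene order itself becomes a phylogenetic character, and
the natural algebra for it is the signed circular permutation of locally
collinear blocks (LCBs) under the inversion (reversal) operation.
Second, the short repeats that remain — for instance the duplicated
`trnQ-UUG` gene found across Cupressaceae, Taxaceae and Cephalotaxaceae
— interact with those inversions: an inversion whose endpoint falls
*between* two tandem copies carries one copy away and flips it, turning
a tandem repeat into a dispersed *inverted* repeat (sIR). This package
implements the full analysis chain needed to study that process at desk
scale: exact reversal distances and scenarios, parsimony trees with
ancestral gene orders, a repeat-copy tracing engine, sequence-level
repeat screens, and the gene-structure analysis used for a plastid gene
that has relocated to the nucleus.

## Signed circular permutations and reversal distance

A genome is a circular arrangement of signed blocks (`scperm`). Two
arrangements are equal when they coincide after rotation or
whole-circle reflection; `canonicalize()` fixes the smallest block id
first and positive, which gives each equivalence class a unique
representative. Block ids may be any distinct positive integers so that
published LCB numberings can be used verbatim; ids are rank-mapped
internally where contiguity is needed.

`reversal_distance()` computes the exact minimal number of inversions
between two permutations under the unichromosomal circular model. The
circle is linearized by fixing one block, which reduces the problem to
the linear signed case on `n - 1` elements; the distance is then read
off the breakpoint graph as

$$ d = (m + 1) - c + h + f $$

with `m` elements, `c` alternating cycles, `h` hurdles and `f` the
fortress indicator. Hurdles are the minimal unoriented components under
span containment plus the greatest one when it contains all the others;
a fortress has an odd number of hurdles, all of them superhurdles
(checked directly by deleting each hurdle and re-deriving the hurdle
set). Because hurdle/fortress logic is notoriously easy to get subtly
wrong, the package carries an independent arbiter:
`bfs_distance_oracle()` does breadth-first search over the entire
canonical state space (feasible to `n = 7`) and the test suite demands
bit-exact agreement — exhaustively for all permutations at `n <= 4` and
on 1000 seeded random pairs at each of `n = 5, 6`. Any discrepancy is
treated as a release blocker.

`sort_by_reversals()` returns an explicit optimal scenario. At each step
it applies the lexicographically smallest distance-reducing inversion
(smallest left cut junction, then smallest right cut), so scenarios are
deterministic and replayable; cut junctions are recorded on the evolving
linearization of the input so the same cut list can drive the traced
configurations described below.

## Parsimony trees and ancestral gene orders

`mgr_tree()` reconstructs ancestral arrangements. With no topology
supplied it runs the greedy heuristic used for multiple genome
rearrangement: repeatedly apply, to some genome, the inversion that
maximally decreases the sum of its distances to the others (ties broken
by genome input order, then by smallest cut pair), merging two genomes
into a named ancestor when they coincide; when no single inversion
helps, the closest pair is collapsed along an optimal scenario so the
procedure always terminates. With a fixed unrooted topology, internal
nodes are labelled by iterated local search (neighbor labels plus all
single-inversion variants of the current label, multi-started from each
leaf); for block counts up to 6 the exact median of three neighbors is
also available (`median_permutation()`), computed by scanning the full
canonical state space with the cached BFS tables. We chose 6 as the
exact-median limit because the state space grows as
`(n-1)!\,2^{n-1}` and local search already recovers planted ancestors
reliably at the sizes the tests exercise; the greedy path is the one
used for realistic (33-block) inputs. Ancestors are reported with
`A<k>` labels, numbered after the leaves, following the convention used
in published plastome rearrangement trees.

Edge counts are always recomputed as reversal distances between the
endpoint labels, so the invariant "edge count equals the distance of
its endpoints" holds by construction and the tree total is a valid
upper bound on the true inversion count of any labelling found.

## Tracing repeat copies through inversions

`repeat_config()` interleaves oriented, zero-length repeat markers with
the blocks of a circular arrangement: a copy either occupies a gap at a
block junction or rides inside a block (with an offset retained only to
express "inside LCB k"). This resolution matches how the underlying
comparative data are reported — repeat copies are placed relative to
LCBs, not at base-pair precision.

`apply_inversion_traced()` needs one extra decision beyond the plain
permutation case: if a cut junction hosts `m` copies there are `m + 1`
gaps to cut in. Explicit `cut_slots` select the gap; the default picks
the gap nearest the inverted segment, which leaves junction copies in
place and makes the default action an involution. The central
combinatorial fact — a tandem pair becomes a dispersed inverted pair
*iff* exactly one of the two cut points separates the copies, and stays
an adjacent pair otherwise — is asserted exhaustively over all endpoint
and slot placements on 6-8-block toys.

The two narrated evolutionary scenarios ship as fixtures
(`trnq_config_sciadopitys()` + `trnq_scenario_to_taxus()`, and
`trnq_config_a25()` + `trnq_scenario_to_cunninghamia()`). They encode
only the blocks the narration names (LCB 1, 2, 11, 12, 25, 29), with
single filler blocks standing for unnamed stretches; that is sufficient
for every narrated cut point and copy placement to be well defined, and
the traces reproduce the published outcome: the tandem pair splits into
two dispersed, oppositely oriented loci (one flanking LCB 1, one
flanking LCB 2), and the three-copy arrangement ends with copies
associated with LCB 2, 1 and 12, two forward and one inverted.

## Repeat screens

`find_ssrs()` is a MISA-dialect microsatellite screen: maximal perfect
runs of primitive 1-6 bp motifs, with default minimum copy numbers of
10 (mono), 5 (di) and 4 (tri- through hexa-nucleotide). Runs are
truncated to whole copies so `end - start + 1 = unit_len * copies`;
a run is reported once under its primitive motif ("AAAA" is mono,
never di), motifs are reported as found (strand complements are not
merged), and compound-SSR merging is deliberately absent because the
published per-class counts sum over individual loci.

`find_tandem_repeats()` is a deterministic seed-and-extend detector for
long-unit tandem arrays (defaults: unit >= 30 bp, adjacent-copy
identity >= 0.90, >= 2 copies). Candidate periods come from identical
13-mers recurring at an in-range spacing; for each period the
self-match indicator `s[i] == s[i+d]` is segmented into clusters,
merging mismatch runs up to `floor((1 - identity) * d)` columns, capped
at 8 — without the cap, chance matches (rate 1/4 per column) chain into
genome-spanning clusters at large periods. Clusters can still overrun
the true array: boundary match-runs shorter than 4 columns are
stripped outright, a cluster must then span at least one unit at >= 70%
match density before any alignment is attempted, remaining short (< 13)
boundary runs are resolved by enumerating trim states and keeping the
best minimal adjacent-copy identity (then the longest region), and a
fractional trailing copy must itself match the corresponding prefix of
the preceding copy or it is treated as flank. Adjacent copies are
verified by global alignment scored match = 1 / mismatch = 0 with gap
columns counting as mismatches; overlapping calls are deduplicated
keeping most copies, then smallest unit. This is a re-design, not a
port of the probabilistic tool traditionally used for such screens, so
agreement with counts produced by that tool is expected only
approximately; on clean backgrounds with planted arrays the detector is
exact, which is what the tests assert.

## Gene transfer analysis

`longest_orf()` scans the three forward frames for the longest
ATG-to-stop frame (standard code), warning below 50 codons.
`find_introns()` aligns the genomic copy against the spliced
transcript with free end gaps (overlap alignment: the transcribed
region is embedded in the genomic copy, so promoter and downstream
flanks must stay outside the alignment rather than surface as spurious
terminal "introns"; match 2, mismatch -3, gap opening 8, extension 0.2
— gaps long enough to be introns are cheap to extend but expensive to
open, so an intron emerges as one maximal gap). Every maximal
transcript-row gap interior to the alignment is an intron. Offsets use the
translation-start convention (+1 at the A of ATG, -1 immediately 5' of
it, no zero), so an intron between the bases at -65 and -64 is reported
exactly so. Splice sites are taken purely from the alignment; GT..AG
conformance is annotated, never enforced, because the analysis must
accommodate a 5'-UTR intron whose splice model is unknown. Exonic
mismatches are reported as candidate RNA-editing sites rather than
errors. `percent_identity()` uses BLOSUM62 with affine gaps and counts
gap columns as mismatches, so only identical sequences score 1; since
protein identity figures depend on aligner parameters, downstream
comparisons of that number to published values are treated as soft
checks only. `scan_promoter()` is an exact-match scan reported at
negative offsets.

## Synthetic data: what it emulates and what it does not

The generators provide exact ground truth. `random_permutation()` is
uniform over raw signed arrangements (not canonicalized, so sign
balance is testable). `evolve()` applies `k` recorded random inversions;
the planted-history property — inferred distance never exceeds `k` and
equals it in >= 95% of seeded trials at 33 blocks, `k <= 8` — is the
package's calibration that distances at realistic plastome scale are
trustworthy.

`synth_genome()` builds a circular genome whose background has every
13-mer unique (so no tandem structure above the seed length can arise
by chance), lays out gene/intron/spacer features, plants SSR runs and
tandem arrays with flanking bases chosen so runs cannot extend, and
finally mutates away any chance microsatellite outside the planted
spans. On such backgrounds detector precision and recall are exactly
1.0 and coordinate recovery is exact, which is what the acceptance
checks measure. Real plastomes differ in ways the generator does not
emulate: compositional bias, nested and degenerate repeats, dispersed
duplications, and annotation error; passing these tests therefore
demonstrates algorithmic correctness on unambiguous signal, not
field-grade robustness to messy data. `synth_gene_pair()` plants
introns with boundary bases chosen to differ from the adjacent exon
bases, making the alignment gap placement unique, so intron recovery
can be asserted with zero tolerance.

Default scales are chosen to span toy-to-plastome conditions: test
genomes of 8-30 kb, the acceptance genome of 70 kb with the published
SSR class profile (53 loci: 36/11/5/1 by motif length, 34/6/13 by
region), permutations of 33 blocks matching the published LCB count,
and a 212-codon ORF with a 93 bp 5'-UTR intron at offsets -65/-64 and
a TATA box at -1599 as the gene-transfer geometry.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (GenBank dialect);
  circular features may wrap the origin (`end < start`).
* Ambiguity codes other than `N` are rejected at parse time: the
  genomes this analysis targets contain none, and failing fast beats
  silently miscounting composition.
* GC percentages are formatted by rounding half-up to two decimals, the
  presentation used in published composition tables.
* The BFS oracle caches one full distance table per block count and
  answers pairwise queries by relabelling, which keeps thousands of
  oracle comparisons cheap.
* Greedy MGR ties are broken lexicographically and by input order;
  every randomized generator takes an explicit seed; pipeline reruns
  with the same configuration and seed are byte-identical.
* The command surface is the exported functions themselves (plus
  `run_pipeline()` for orchestration); a shell wrapper would add
  nothing for an R-native audience.

## Known limitations

* Only the inversion (reversal) model is implemented — no
  transpositions, translocations or DCJ; that is the model under which
  the comparative analysis is defined.
* The greedy tree heuristic does not guarantee a minimum-total tree;
  its totals are validated against planted histories and path bounds,
  not against an exact Steiner solver, and the exact median is limited
  to 6 blocks.
* The tandem detector's coordinates are guaranteed exact only for
  perfect arrays on repeat-free backgrounds; degenerate arrays may be
  reported with trimmed boundaries.
* LCB computation itself (whole-genome alignment) is out of scope:
  permutations arrive as GRIMM files or via the shared-gene-order
  fallback `gene_order()`.
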