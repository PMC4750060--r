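# plastrearr

Comparative chloroplast-genome analysis at gene-order resolution, for
researchers studying plastome structural evolution in conifers and
other lineages that have lost the canonical large inverted repeat.
Without that repeat, plastomes rearrange freely, and two questions
dominate the analysis: *how many inversions separate two genomes* and
*what do those inversions do to the short repeats the genome carries* —
in particular, how a tandem repeat (such as the duplicated `trnQ-UUG`
gene of cupressophytes) is split by an inversion into a dispersed
**inverted** repeat (sIR).

## What the package computes

Genomes are modelled as signed circular permutations
$\pi = (\pi_1, \ldots, \pi_n)$ of locally collinear blocks, equal up to
rotation and reflection. The core quantity is the exact
Hannenhalli–Pevzner reversal distance under the unichromosomal circular
model, obtained from the breakpoint graph of the linearization as

$$ d(\pi, \sigma) \;=\; (m + 1) - c + h + f, $$

where $m = n - 1$, $c$ counts alternating cycles, $h$ counts hurdles
and $f$ flags a fortress. Around this sit:

* **Scenarios and trees** — `sort_by_reversals()` (deterministic
  optimal inversion scenarios), `distance_matrix()`, `mgr_tree()`
  (greedy multiple-genome-rearrangement tree with reconstructed
  ancestral gene orders `A<k>`, or internal labelling of a fixed
  topology), with an exhaustive BFS oracle (`bfs_distance_oracle()`)
  cross-checking every distance at small n.
* **Repeat tracing** — `repeat_config()` places oriented repeat copies
  at block junctions or inside blocks; `apply_inversion_traced()` /
  `trace_scenario()` propagate them through inversions;
  `classify_arrangement()` names the outcome (tandem_forward,
  adjacent_inverted, dispersed_forward, dispersed_inverted, ...). The
  narrated `trnQ-UUG` scenarios ship as fixtures.
* **Repeat screens** — `find_ssrs()` (MISA-style microsatellites:
  >= 10 copies mono, >= 5 di, >= 4 tri–hexa) and
  `find_tandem_repeats()` (>= 30 bp units at >= 90% adjacent-copy
  identity, seed-and-extend, alignment-verified).
* **Gene transfer** — `longest_orf()`, `find_introns()` (genomic vs
  transcript global alignment; interior gaps are introns, reported at
  translation-start offsets), `scan_promoter()`, `percent_identity()`.
* **I/O and orchestration** — GenBank flat files (`parse_genbank()` /
  `write_genbank()`), FASTA + TSV feature tables, GRIMM permutation
  files, newick trees, and `run_pipeline()` for config-driven runs.
* **Synthetic data** — seeded generators with exact truth tables
  (`random_permutation()`, `evolve()`, `synth_genome()`,
  `synth_gene_pair()`) so every stage is testable without downloads.

## Worked example: splitting a tandem repeat into an sIR

```r
library(plastrearr)

cfg <- trnq_config_sciadopitys()      # tandem trnQ pair between LCB 25 and 1
tr  <- trace_scenario(cfg, trnq_scenario_to_taxus())
for (x in tr) print(x)
```

```
<repeat_config> (+25 [trnQ-UUG#1+] [trnQ-UUG#2+] +1 +31 +29 +2 +11 +32)
<repeat_config> (+25 -29 -31 -1 [trnQ-UUG#2-] [trnQ-UUG#1-] +2 +11 +32)
<repeat_config> (+25 -29 -31 -1 [trnQ-UUG#2-] -11 -2 [trnQ-UUG#1+] +32)
```

The first inversion (cut between LCB 29 and the tandem pair's junction)
carries the pair along with LCB 1, placing it next to LCB 2. The second
inversion cuts *between* the two copies: one copy stays with LCB 1, the
other rides with LCB 2 and flips. The final state has two dispersed,
oppositely oriented copies — an inverted repeat born from a tandem
repeat:

```r
classify_arrangement(tr[[3]], "trnQ")   # "dispersed_inverted"
count_repeat_loci(tr[[3]], "trnQ")      # 2
```

Distances work the same way on any permutations:

```r
p <- scperm(c(25, 1, 31, 29, 2, 11, 32))
q <- apply_inversion(p, 1, 4)
reversal_distance(p, q)        # 1
sort_by_reversals(p, q)
#> <inversion_scenario> 1 inversion(s)
#>   step 1: cut junctions (1, 4)
```

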