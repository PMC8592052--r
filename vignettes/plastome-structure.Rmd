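---
title: "Plastome structural analysis with plastopart: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome structural analysis with plastopart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Flowering-plant plastomes are circular molecules of roughly 120–160 kb with
a conserved quadripartite layout: a large and a small single-copy region
(LSC, SSC) separated by two identical inverted-repeat copies (IRb, IRa).
Two classes of structural change dominate comparative work at the family
level: expansion or contraction of the inverted repeat at its junctions
with the single-copy regions, and the degradation (pseudogenisation or
outright loss) of dispensable genes, most prominently the eleven *ndh*
genes encoding the plastid NDH-1 complex. `plastopart` implements the
analysis chain for such a survey — quadripartite partitioning, junction
profiling and typing, expansion-event reconstruction, gene-status
classification, and repeat scanning — together with a synthetic-plastome
generator that plants every one of those structures with a machine-readable
truth table, so that each stage is verifiable end to end without any
external data.

## Quadripartite detection

`detect_quadripartite()` finds the longest pair of disjoint **exact**
inverted repeats. Candidate anti-diagonals are seeded by shared 21-mers
between the sequence and its reverse complement; each candidate diagonal is
then evaluated over the full circle and maximal match runs are read off
directly, so the reported pair is maximal by construction. Exactness is the
right model for finished assemblies, whose two IR copies are identical by
construction; if a record ever carries slightly divergent copies the
detector reports the largest identical core rather than silently extending
across mismatches.

Numerical choices:

* `min_ir_len = 1000` bp — far below the 26–33 kb IRs of photosynthetic
  angiosperms and far above incidental repeats, so the default is
  insensitive over a wide range.
* `k = 21` — seed length; chance 21-mer collisions in a 160 kb genome are
  vanishingly rare, and any true IR of at least `min_ir_len` contributes
  hundreds of seeds.
* Ties between equal-length maximal pairs are broken toward the smallest
  start coordinate, with a warning; sub-threshold runs never participate.
* A palindromic run (the two copies abutting head-to-head) is split into
  disjoint halves.

The resulting map fixes a **canonical frame**: the genome is rotated (and
if necessary flipped) so traversal reads LSC → IRb → SSC → IRa, with the 5′
end of *ycf1* in IRa when that gene is annotated (non-pseudo annotations
take precedence, since expanded genomes also carry ψ fragments). All
junction arithmetic, and every sequence-level summary in
`summarize_plastome()`, happens in this frame, which is why summaries are
bit-identical across arbitrary rotations and reverse-complementations of
the input — a property the test suite checks directly. Junctions are
reported as the IR-side base adjacent to each single-copy region (`J_LB`,
`J_SB`, `J_SA`, `J_LA`).

## Junction typing and expansion reconstruction

The `J_SA` profile decomposes the junction-spanning gene into its IR-side
and SC-side parts; `classify_jsa()` then types the junction:

* **Type C** — *ycf1* held entirely within the IR;
* **Type B** — at least `ab_threshold` bp of *ycf1* in IRa;
* **Type A** — otherwise.

The observed clusters sit near 925–1,066 bp (A) and 2,649–2,737 bp (B), so
the default `ab_threshold = 2000` bisects the gap between them; since the
raw bp value is always reported alongside the label, relabelling under a
different threshold is trivial.

`diff_junctions()` reconstructs expansion events against an
ancestral-like reference. Because the IR grows at its `J_SA` end while the
`J_LA` end is stable, the incorporated sequence is the prefix of the
target IRa beyond the longest common suffix with the reference IRa. That
prefix is segmented into maximal collinear blocks by exact anchored
matching (20-mer anchors, greedy rightward extension) against the
reference; each block is one event, ordered 5′→3′ along IRa, i.e. most
recent first. A block whose anchor finds no home is reported unmapped with
its genes flagged unknown. Where the reference sequence beyond one block's
donor happens to continue identically into the next block's content, the
boundary between the two events is collinearly ambiguous; the generator's
truth tables record that realised boundary, because no reconstruction can
resolve within a shared prefix.

Mechanism labelling is a hypothesis, not a proof: an event is
`repeat_mediated` only when the 16 bp / 10% screen finds at least one
short repeat with one copy within 500 bp of the event's outer junction and
one within 500 bp of its inner junction; everything else is
`dsb_or_other`, covering both double-strand-break copy-repair and
gene-conversion events that left no detectable repeat.

`map_segment_origin()` places an incorporated segment on a reference by
local Smith–Waterman alignment (match +1, mismatch −1, gap open −2, gap
extend −1, both strands). A placement must reach `min_identity = 0.8` over
at least 60% of the segment — the coverage floor exists because a random
segment otherwise "places" through a perfect 10-column micro-alignment.
Intergenic placements are named `geneLeft-geneRight spacer` in reference
gene order.

## Gene status

Genes are classified against a reference panel
(`build_reference_panel()`: per gene, the modal intact CDS length across
records, ties to the longest):

* **lost** — strictly less than 30% of the reference detectable
  (`coverage < 0.30`);
* **putative pseudogene** — an internal stop codon, a missing terminal
  stop, or a length differing from the reference by a non-multiple of 3
  (frameshift);
* **uncertain** — `N`s prevent a confident call (e.g. an assembly gap
  where a stop codon would be); this fourth state exists precisely so that
  missing data is not mistaken for degradation;
* **intact** otherwise. Accepted start codons are ATG and GTG, the latter
  recorded as a non-canonical-start note since translation table 11
  permits alternative initiators.

RNA editing is deliberately not modelled: a missing stop is called a
pseudogene even where C-to-U editing might restore it, and the
documentation of such calls is the place to flag candidates.

Presence is measured by sequence, not annotation, because annotations of
degraded genes are unreliable. The default route cuts the reference into
100 bp tiles, searches both strands with a 10% per-tile mismatch
allowance, and refines the edges of located tile runs by ungapped
base-level extension, which recovers truncation breakpoints exactly
(a 1,080 bp gene truncated at 30% measures coverage 0.3000). A second
route (`method = "align"`) implements recursive best-local-alignment
(Smith–Waterman, accepting blocks of ≥ 30 columns at ≥ 70% identity) and
is used as a cross-check in the tests; the tile route is the default
because it is orders of magnitude faster at equal answers on clean
assemblies, which is what the multi-seed recovery suites require. The tile
route can overcount coverage by at most ~10 bp at a truncation edge (a
tile straddling the cut may still pass its mismatch budget), which is why
planted "lost" fractions in the tests sit at 0.25 or below rather than
immediately under the threshold.

## Repeat scanning

Dispersed repeats use an ungapped Hamming model: the published pairs are
equal-length, and the mismatch budget `floor(0.10 · length)` reproduces
the published acceptance of 1 mismatch at 17–18 bp and rejection of 2 at
17 bp. A reported pair is **maximal**: extending it by one base on either
side would exceed the budget at the grown length or leave the search
windows. Since extension over a matching base never violates the budget,
every maximal window abuts a mismatch or an edge on both sides, and the
scanner enumerates windows over mismatch boundaries only — the test-suite
oracle instead checks every window of every diagonal directly, so the two
agree only if both the semantics and the implementation are right.
Self-pairs and fully-overlapping placements are excluded; each unordered
pair is reported once with `start1 < start2`; `N` never matches anything.

Tandem repeats are perfect arrays of primitive units (2–1,000 bp, at least
2 full copies), found per period as maximal runs of `s[i] == s[i+u]`. A
trailing partial copy extends the reported span but not the full-copy
count. Hidden-repeat removal discards any array whose span lies inside
another reported span, preferring the smaller unit at equal span — a
documented stand-in for the counting tool's undocumented setting of the
same name, which is also why absolute tandem *counts* are validated by
planted-array recovery and internal-consistency properties rather than
against published per-genome totals (the published tool's scoring floor is
not public). Mononucleotide runs are excluded by `unit_min = 2` together
with the primitivity requirement.

## The synthetic generator

`build_plastome()` emulates, at reduced scale, exactly the structures the
pipeline measures: 12 kb LSC / 7 kb IR / 9 kb SSC (≈ 35 kb total), i.i.d.
background at GC 0.378, codon usage weighted to the same composition, a
3.6 kb *ycf1* across `J_SA` with 1,000 bp (Type A) or 2,600 bp (Type B) in
IRa, the *ndh* suite and *rps15* in the SSC, rRNAs and *trnN* in the IR.
*ndhH* keeps its real 1,182 bp length so that the 592 bp / 50% duplicated
pseudogene scenario is reproduced literally. The scale was chosen once:
the SSC must hold a > 2.6 kb *ycf1* portion (so that the fixed 2,000 bp
A/B threshold separates the planted types) plus the *ndh* suite with
realistic spacers, and 9 kb is the smallest round size that does; at this
scale a full construct-and-recover cycle runs in well under a second, and
the multi-seed suites state their sizes as these defaults.

Design details worth knowing:

* **Shared gene complement.** Gene sequences are drawn from gene-specific
  RNG streams keyed by a `family_seed`, so records with different seeds
  are homologous (identical genes, divergent spacers) — the precondition
  for cross-sample reference panels.
* **Junction guards.** With random flanks, each IR junction has a 25%
  chance of extending one base by chance complementarity; the generator
  (and `apply_ir_expansion()`) therefore force the single-copy base
  abutting each junction to break complementarity, so the realised maximal
  IR is exactly the planted one. The conservation property for expansions
  accordingly exempts that one guard base.
* **Planted dispersed repeats** carry a 9-base anti-match zone on each
  flank: any window larger than the planted one then needs a budget of
  `m + k` mismatches at length `len + 2k`, which the 10% budget cannot
  reach, so the planted hit is the unique maximal one. Host spacers are
  re-randomised (bounded retries) if the surrounding background still
  produces a chance hit in the validation scan.
* **Lesions** are deterministic sequence edits: a mid-gene codon set to
  TAA (internal stop), the terminal stop overwritten (missing stop), a
  single-base deletion with the annotation shortened by one (frameshift),
  truncation to a coverage fraction with the remainder replaced by fresh
  background, whole-gene replacement (loss), or an in-frame 9-base N run
  (uncertain). Truncation truths use the realised `floor(n·frac)/n`
  coverage, which matters exactly at the strict 0.30 boundary.
* `apply_ir_expansion()` moves `J_SA` into the SSC by `extent`,
  duplicating the incorporated segment reverse-complemented at the IRb
  side; genes wholly carried along (or already continuing into IRa, like
  *ycf1*) gain full mirrored copies, a bisected gene gains a truncated ψ
  copy, and with `erode_remnant = TRUE` its stranded single-copy remainder
  decays into background — the composed two-event history
  (`simulate_type_c_two_events()`) reproduces the inferred Type C
  chronology: long DSB-style incorporation of *ycf1*, *rps15* and 592 bp
  of *ndhH*; loss of the stranded *ndh* material; then a 45 bp
  gene-conversion-style incorporation of intergenic spacer.

What the generator does **not** emulate: substitution-model divergence
along a phylogeny, sequencing error, IR copies that differ from each
other, SSC orientation isomers, or realistic codon usage beyond base
composition. Passing the recovery suites therefore demonstrates
correctness of the structural logic on clean, exactly-mirrored genomes —
the situation of finished assemblies — not robustness to divergent or
noisy input.

## Degenerate inputs and edge rules

* No IR above `min_ir_len` → an explicit no-IR result, not an exception;
  summaries still report length and GC.
* GC% is computed over non-N bases only; codons containing N translate to
  X; N never matches in any repeat scan.
* The lost threshold is strict (`< 0.30`): a gene at exactly 30% coverage
  is not lost.
* `diff_junctions()` of a genome against itself is empty; an expansion of
  extent 0 is the identity with an empty log; an extent consuming the
  whole SSC is an error.
* Exact self-centred palindromes are excluded from dispersed-repeat
  output as fully-overlapping placements.

## Problem sizes used by the checked suites

The multi-seed suites run 50 seeds per scenario at the default reduced
scale (35 kb genomes; tandem fixtures of 6–8 kb with planted units up to
30 bp scanned at `unit_max = 40–50`, matching the planted range), and the
scanner-versus-oracle comparisons use 100 seeded sequences of 60–170 bp —
the oracle checks every window of every diagonal, so its cost grows
cubically and short sequences exercise the semantics completely. The
acceptance script reruns the same computations at 12 seeds per scenario
and writes machine-readable rates.

## Known limitations

* Exact-IR detection reports the identical core of slightly divergent IR
  copies; a mismatch-tolerant refinement is future work.
* Event segmentation is exact-match greedy; deeply diverged incorporated
  segments would fragment into unmapped blocks rather than align loosely.
* The tile presence route quantises coverage at truncation edges by up to
  ~10 bp, as discussed above.
* Tandem totals are convention-dependent (scoring floor, span-vs-copies
  accounting) and should be compared only within runs of this package.
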