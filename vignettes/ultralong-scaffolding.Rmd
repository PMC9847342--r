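---
title: "Ultra-long-read contig scaffolding and repeat diagnostics: methods"
author: "ulscaf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultra-long-read contig scaffolding and repeat diagnostics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulscaf)
```

# The scaffolding model

`ulscaf` scaffolds assembly contigs with ultra-long nanopore reads. The
method works on *contig ends* rather than contigs: every contig has a `head`
(its coordinate-0 side) and a `tail` (its coordinate-length side), and a
linkage between two ends simultaneously encodes which contigs are adjacent
and in which relative orientation. The procedure is:

1. **Contact extraction.** Read-to-contig alignments (PAF) are grouped by
   read. Alignments below a mapping-quality or block-length threshold, and
   minimap2 secondary alignments (`tp:A:S`), are dropped. Reads mapping to a
   single contig carry no linkage information and are discarded. Surviving
   alignments are sorted along the read; consecutive alignments to the same
   contig and strand are collapsed to their outermost coordinates (split
   alignments across a small indel are one logical hit). For each adjacent
   pair the *exit* end of the first contig (tail on `+`, head on `-`) and
   the *entry* end of the second (head on `+`, tail on `-`) must both lie
   within `max_end_distance` of their contig end — alignments confined to
   contig interiors are evidence of a repeat, not of adjacency. Each
   surviving pair yields one contact with a per-read gap estimate: the
   unaligned read length between the two alignments minus the unaligned
   contig overhang on each side. The overhang of an alignment toward an end
   depends only on the end (`head`: `target_start`; `tail`:
   `target_len - target_end`); the strand enters through which end is the
   exit or entry. Negative estimates (probable overlap) are kept raw so the
   median sees all evidence.

2. **Graph filtering.** Contacts aggregate into edges weighted by
   supporting-read count. Edges with fewer than `min_contacts` (default 2)
   reads are dropped. The *reciprocal-max* filter then keeps an edge only if
   its count is the strict unique maximum among surviving edges at **both**
   of its ends; a tie disqualifies every tied edge. We chose the
   strict-unique interpretation because it is the only one that guarantees
   degree ≤ 1 per end deterministically — an ambiguous end is better left
   unscaffolded than joined arbitrarily.

3. **Simplification.** For runs without the reciprocal filter, branches are
   resolved by keeping the strongest edge at any end of degree > 1 (a tied
   maximum removes all edges at that end). Remaining cycles — which cannot
   occur in a correct linear chromosome — are broken at their weakest edge;
   a tie is broken at the lexicographically smallest edge key so the result
   is reproducible. After simplification each component is a simple path.

4. **Path extraction and gaps.** Each component with at least two contigs is
   walked from a degree-1 contig. The first contig is `+` if the walk exits
   via its tail, and every later contig is `+` if entered via its head.
   The canonical direction of a path is the one whose first contig id sorts
   before its last, making outputs diff-stable. The gap for each junction is
   the **median** of the per-read estimates (even cardinality: mean of the
   two central values, rounded half away from zero), clamped up to `min_gap`
   (default 10 bp) — contigs are never merged even when the median is
   negative. Candidate scaffolds whose *summed contig length* is below
   `min_scaffold_len` (default 2 Mb) are dissolved back to contigs; we
   measure the filter on contig span only, excluding gaps, so that the
   decision does not depend on the gap estimates themselves.

5. **Emission.** Scaffold FASTA (minus-oriented contigs
   reverse-complemented, gaps as `N` runs), GFA 1.0 (ends encoded in link
   orientations, counts in `ct:i`, gaps in `gp:i` since GFA 1.0 cannot carry
   a positive gap in its CIGAR), AGP 2.1 (`W`/`N` rows, linkage evidence
   `map`), and a contacts TSV.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_contacts` | 2 | reads | minimum read support for a linkage |
| `reciprocal_max` | on | — | require mutual best linkage |
| `max_end_distance` | 20,000 | bp | how far from a contig end an alignment may stop; well above local-alignment end slack at ultra-long scale, small against contig N50 |
| `min_mapq` | 10 | — | drops ambiguous placements |
| `min_block` | 1,000 | bp | drops spurious short hits |
| `min_scaffold_len` | 2,000,000 | bp | confident-scaffold filter (contig span only) |
| `min_gap` | 10 | bp (N) | smallest emitted gap |

# Repeat diagnostics

Repeat units are compared through `canonical_unit()`: the lexicographically
smallest string over all rotations of the unit and of its reverse
complement. This makes matching invariant to how a repeat finder phases or
strands an array — `TA` and `AT` are the same dinucleotide repeat, and the
plant telomere motifs `CCCTAAA`/`TTTAGGG` are one motif.

* **Telomeres** are called when a motif array of at least `min_array_len`
  (default 500 bp) intersects a terminal window (default 10 kb) of a
  sequence; at most one call per end, longest array wins. Completeness is
  the percentage of sequence ends carrying a call.
* **Centromeres** are clusters of arrays whose period is within ±5 bp of
  126 bp, merged when closer than 10 kb, and reported when the summed array
  length strictly exceeds 0.7 Mb. The cutoff is strict because the rule is
  phrased as "longer than"; the tolerance and merge distance are our own
  choices, since satellite arrays are fragmented by repeat finders.
* **AT contig ends** use a 1 kb terminal window: an end with an AT
  dinucleotide array in that window counts, giving per-contig classes 0/1/2
  and the two headline percentages (classes 1+2 vs class 0), plus per-class
  Nx curves. Any pure AT array qualifies via the canonical unit, which also
  covers reported units like `ATAT`.
* **Nx statistics** use the textbook definition: `Nx(x)` is the length `L`
  such that sequences ≥ `L` cover at least `x`% of the total. Tandem-repeat
  content is the per-sequence union of array spans so overlapping TRF calls
  are not double-counted; the tandem N50 is the N50 of individual array
  lengths.

The built-in `scan_tandem_arrays()` is an *exact* scanner (`seq[i] ==
seq[i+p]` runs, partial trailing copies included, each array reported at its
smallest period). It exists so the whole package is testable without an
external repeat finder; real analyses of approximate repeats should feed
`parse_trf_dat()` output instead. TRF rows occasionally print a period that
differs from the consensus-unit length; both are kept as printed, and
downstream calls use the field appropriate to them (period for centromere
selection, unit for motif matching).

# Ks peaks, WGD dating and TPM

`ks_modes()` fits a Gaussian kernel density (Silverman's rule-of-thumb
bandwidth unless given) on a 512-point grid over `[0, max(Ks)]` and reports
the highest local maxima. Grid endpoints count as candidate maxima so a
degenerate distribution still yields its peak. `wgd_age()` implements the
clock-like ratio argument: if speciation happened `T` Mya at Ks peak `k_s`,
a WGD at Ks peak `k_w` dates to `T * k_w / k_s`. The clock assumption is
documented, not validated, and the peaks are explicit inputs so the dating
is independent of how the peaks were measured. `tpm()` is the standard
length-normalised count transform; all-zero counts give all-zero TPM rather
than dividing by zero.

# What the synthetic generator emulates

`simulate_genome()` builds uniform-random chromosomes (an AT-rich
composition is an optional knob) carrying telomere arrays at both ends
(tail reverse-complemented), one random-unit 126 bp satellite array near the
middle, and interior AT arrays. `fragment_genome()` breaks chromosomes into
contigs — at random positions or centred on AT arrays, emulating assemblies
whose contigs terminate in AT tandem repeats — removing `gap_margin` bases
on each side of a breakpoint so every junction has a known true gap of
`2 * gap_margin`, and flipping contig orientations at random.
`simulate_ultralong_paf()` samples reads uniformly with log-normal lengths
and emits each read-contig overlap as an *exact* PAF record derived from the
placements, so tests are hermetic; users wanting realism can map the
simulated reads themselves with a real aligner. Noise knobs: independent
per-record dropout, and spurious two-alignment reads joining random
contig-end pairs. Spurious pairs are drawn *without replacement* over
distinct end pairs: they model mis-mappings scattered across the genome, and
they keep the zero-false-join property a statement about the
`min_contacts`/reciprocal filters rather than about collision statistics in
the noise generator.

The generator does **not** emulate base-calling errors, chimeric reads,
collapsed segmental duplications or misassembled contigs, so passing tests
demonstrate the graph algebra and filters, not robustness to alignment
artefacts on real data.

## Study problem sizes

The package's own validation study uses 5 chromosomes × 2 Mb with 8 contigs
each (true gaps 400 bp, orientations random, 30× coverage of ~50 kb reads),
noise-free and with 10% record dropout + 5% spurious contacts, over ten
seeds. At this scale a full-chromosome scaffold has a contig span of
1,997,200 bp — just under the 2 Mb production default — so the study passes
`min_scaffold_len = 1e6`, scaled to the synthetic chromosome size; the
production default stays at 2 Mb. On this design the pipeline recovers 100%
of junctions with the exact 400 bp gap in the noise-free case, and ≥95%
with zero false joins under noise.

# Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; TRF and AGP are converted
  at the boundary (1-based inclusive).
* Percentages and the WGD age are rounded half away from zero to two
  decimals; base R's banker's rounding would give different second decimals
  on exact halves.
* Medians of even-cardinality gap lists use the mean of the central pair,
  rounded half away from zero.
* Ties: a tied maximum at an end disqualifies all tied edges (filtering and
  branch removal); tied weakest cycle edges break at the smallest canonical
  key.
* Degenerate Ks samples (zero variance) fall back to a small positive
  bandwidth instead of failing.
* Empty inputs raise classed errors (`ulscaf_input_error` etc.) rather than
  returning empty results silently, except where an empty result is
  meaningful (no edges → header-only GFA; zero coverage → empty PAF).

# Known limitations

* The scaffolder never edits contigs: mis-joins in the input assembly
  propagate into scaffolds.
* Gap estimates come from alignment coordinates only; systematic aligner
  end-trimming biases the medians slightly upward.
* The exact tandem scanner misses diverged repeat copies by construction.
* `ks_modes` reports grid-resolution peak locations; closely spaced mixture
  components shift detected modes toward each other, as with any KDE.
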