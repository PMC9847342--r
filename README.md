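# ulscaf — ultra-long-read contig scaffolding and assembly repeat diagnostics

`ulscaf` is an R toolkit for genome assemblers working with highly
repetitive plant genomes. It addresses two linked problems:

1. **Scaffolding contigs with ultra-long nanopore reads.** HiFi assemblies
   of AT-repeat-rich genomes fragment at long tandem repeats; ultra-long
   reads (>50 kb) span the breaks. `ulscaf` turns read-to-contig alignments
   (PAF) into a *contig-end contact graph*: each read aligning near the ends
   of two different contigs contributes one contact between a specific end
   pair (`head` = coordinate-0 side, `tail` = opposite side), so an edge
   encodes adjacency *and* relative orientation. The graph is filtered by
   supporting-read count and a reciprocal-best rule (an edge survives only
   if it is the strict strongest linkage at **both** of its ends), branches
   are removed, cycles are broken at their weakest edge, and the remaining
   simple paths become ordered, oriented scaffolds. The gap at each junction
   is the median over reads of
   `(read gap between the two alignments) − (unaligned contig overhangs)`,
   clamped to a minimum. Outputs: FASTA, GFA 1.0, AGP 2.1, a contact table
   and an edge-drop log.

2. **Diagnosing why contigs break.** Tandem-array based analyses: telomere
   calls from terminal motif arrays (`CCCTAAA`/`TTTAGGG`, matched
   rotation- and strand-invariantly), centromere calls from 126 bp satellite
   clusters exceeding 0.7 Mb, classification of contigs by AT dinucleotide
   arrays at 0/1/2 ends with per-class Nx curves, and assembly/tandem-repeat
   Nx statistics. Arrays come from Tandem Repeats Finder `.dat` output or a
   built-in exact scanner.

It also includes Ks-distribution peak detection (kernel density) with the
clock-like ratio dating of a whole-genome duplication,
`T_WGD = T_speciation × Ks_WGD / Ks_speciation`, and TPM expression
normalisation — plus a fully seeded synthetic-data generator (genome with
planted telomere/centromere/AT arrays → contig fragmentation with known
gaps and orientations → exact ultra-long-read PAF with dropout/spurious
noise) so the whole pipeline is testable with no external data.

## Worked example

```r
library(ulscaf)

# simulate: 2 chromosomes x 500 kb, 4 contigs each, 400 bp true gaps,
# random orientations, 25x coverage of ~30 kb reads
truth <- simulate_genome(n_chrom = 2, chrom_len = 5e5, telomere_copies = 50,
                         centromere_len = 2e4, n_at_arrays = 3,
                         at_array_len = 2000, seed = 1)
truth <- fragment_genome(truth, n_contigs_per_chrom = 4, gap_margin = 200,
                         flip_prob = 0.5, seed = 2)
sim <- simulate_ultralong_paf(truth, coverage = 25, read_len_mean = 3e4, seed = 3)

res <- scaffold_pipeline(sim$paf, truth$contigs, min_scaffold_len = 2e5)
for (p in res$paths)
  cat(p$scaffold_id, ":", paste0(p$contigs, p$orientations, collapse = " "),
      "| gaps:", paste(p$gaps, collapse = ","), "| span:", p$contig_span, "\n")

jr <- junction_recovery(res$paths, truth)
cat(sprintf("junctions recovered: %d/%d (%.0f%%), false joins: %d\n",
            jr$n_recovered, jr$n_true, jr$recovery_pct, jr$n_false))
cat(sprintf("WGD age from Ks peaks: %.2f Mya\n", wgd_age(32.81, 0.51, 0.63)))
```

prints

```
scaffold_0001 : ctg0001- ctg0002+ ctg0003+ ctg0004- | gaps: 400,400,400 | span: 498800
scaffold_0002 : ctg0005+ ctg0006+ ctg0007+ ctg0008- | gaps: 400,400,400 | span: 498800
junctions recovered: 6/6 (100%), false joins: 0
WGD age from Ks peaks: 26.56 Mya
```

Each scaffold line lists the ordered contigs with their orientations; every
emitted gap equals the planted 400 bp truth, all six true junctions are
recovered with the right orientation algebra, and the Ks-ratio arithmetic
dates a duplication whose Ks peak is 0.51 against a 32.81 Mya speciation
whose peak is 0.63 to 26.56 Mya.

A command-line interface wraps the same functions
(`exec/ulscaf <subcommand>`): `simulate`, `scaffold`, `telomeres`,
`centromeres`, `at-ends`, `stats`, `wgd-age`, `ks-modes`, `tpm`; see
`--help` on each.

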