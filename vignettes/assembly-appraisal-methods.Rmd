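---
title: "Methods: appraising de novo assemblies against trusted references"
author: "asmappraise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: appraising de novo assemblies against trusted references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A de novo whole-genome assembly is a hierarchy of contigs (gap-free
units built from overlapping reads) linked into scaffolds
(supercontigs) whose internal gaps are written as runs of `N`. Judging
whether such an assembly is *good* requires several independent views:

* **contiguity** — how long are the pieces (N50 and friends);
* **base-level accuracy** — substitution, insertion and deletion rates
  measured against finished, trusted reference sequences (the role
  finished BAC clones play in well-studied genomes);
* **structural integrity** — contigs whose parts belong to different
  chromosomes (split-contig mis-assemblies), and whether independent
  read pairs map back concordantly;
* **representation** — how much of the trusted sequence, the gene
  complement, and previously missing ("novel") sequence the assembly
  captures.

`asmappraise` implements this whole battery as composable R functions
plus an orchestrated pipeline, and ships a synthetic-data generator
that plants every defect class with a machine-readable truth ledger, so
each metric is validated by *parameter recovery*: simulate defects at
known rates, run the pipeline, and check the estimates against the
ledger.

# Scaffold decomposition

Scaffolds are split into contigs at `N`-runs of at least
`gap_threshold` bp (default 10 bp; shorter runs stay inside contigs).
The genome-assembly literature does not agree on a single value, and
the split threshold matters for contig statistics, so it is exposed
everywhere. All internal coordinates are 0-based half-open; PSL and BED
already use this convention, GFF3 (1-based closed) is converted on
read. IUPAC ambiguity codes are converted to `N` on read (with a
logged count) rather than rejected, so real assemblies parse.

# Contiguity

`n_statistic(lengths, f)` returns the largest length `L` such that
pieces of length at least `L` contain at least a fraction `f` of all
bases (N50 at `f = 0.5`); ties at the crossing keep the larger `L`,
matching the "largest length such that" definition. Contig statistics
use contigs *strictly longer* than `min_length` (default 100 bp, the
conventional reporting cutoff); scaffold statistics are unfiltered and
scaffold lengths include internal gaps, since the gap is part of the
scaffold's span. Whether published N50s apply the 100 bp filter is
usually unstated; the package applies it to contigs only and records
the cutoff in its output.

# The aligner

The pipeline needs three alignment tasks — trusted-sequence accuracy
alignment, chunked novelty mapping, and transcript/cDNA matching — all
on nucleotide sequence of roughly 90% identity or better. Rather than
shelling out to external aligner binaries, the package includes a
seed-and-extend aligner (in C++ via Rcpp) with the classical
architecture:

1. **k-mer index** of the targets (default `k = 12`); k-mers containing
   `N` are skipped, and query k-mers occurring more than `max_hits`
   times in the index are ignored (repeat masking). Both strands are
   searched by reverse-complementing the query.
2. **chaining**: seed hits are clustered by (target, diagonal window)
   and chained monotonically; chains are evaluated largest-first so a
   cap on evaluated chains never drops the dominant alignment.
3. **banded affine-gap DP** over each chained window (Gotoh recursion;
   a gap of length L costs `gap_open + L * gap_extend`, defaults
   +1/−3/−5/−2 with band 64 bp), followed by ungapped X-drop extension
   of the window ends.
4. **score-valley splitting**: the window DP is global within its
   window, so a chain that accidentally bridges non-homologous sequence
   (e.g. across a mis-join junction to a coincidental repeat seed)
   would otherwise report the bridge as aligned. Any internal stretch
   whose running score drops more than `split_drop` (default 100)
   below the preceding maximum ends the alignment piece, restoring
   local-alignment behaviour.
5. **gap normalisation**: indels are left-shifted through homopolymers
   so equivalent optimal alignments yield byte-identical discrepancy
   coordinates.

When `band_width` is at least the query length, the exact unbanded
"fit" DP (query global, target ends free) is run against each seeded
target small enough for a full matrix; on such instances the reported
score equals the unrestricted affine-gap optimum, which the test suite
verifies against `Biostrings::pairwiseAlignment` as an independent
oracle. The aligner is a desk-scale stand-in, not a genome-scale
mapper: for very large jobs, external alignments can be substituted
wholesale through `read_psl()` at every stage.

`best_alignment()` breaks score ties by more matches, then
lexicographically smallest target id, then smallest target start, so
"single best alignment per query" is deterministic.

# Base-level accuracy

`tally_discrepancies()` compares assembly contigs to trusted sequences.
Where several alignments cover the same trusted base, the best-scoring
alignment owns the base (*per-base attribution*), so repeat-induced
multi-alignments never double-count events. Three conventions are
deliberate and configurable:

* the denominator of all three rates is **aligned trusted bases**
  (keeping substitution, insertion and deletion rates commensurable);
* indels are counted in **bases** (a 2 bp gap contributes 2), with
  per-event counting available via `discrepancy_rates(per_event =
  TRUE)`;
* coverage is the union of attributed target spans over the total
  trusted bases.

# Mis-assembly detection and normalisation

A contig is a split-contig mis-assembly when uniquely aligned segments
of at least the size cutoff (10/25/50 kbp by convention) land on two
or more chromosomes. "Unique" is operationalised as: the segment's
score is at least 1.1 times that of any overlapping competitor for the
same contig region (no published uniqueness criterion exists for this
procedure; the ratio is configurable). Same-chromosome placements more
than 1 Mbp apart or out of order are reported as intrachromosomal
events but excluded from the headline count by default.

Event counts are normalised to the average scaffold length `L` as
`N * C / L`. Only the proportionality to `N` and the inverse
proportionality to `L` are fixed by the definition of the procedure;
the constant `C` is a package choice, defaulting to the smallest mean
scaffold length among the compared assemblies so that the assembly
with that mean keeps its raw count. This choice is flagged here
because different constants rescale (but never reorder) the
comparison.

# Paired-end concordance

`classify_pair()` labels a pair *proper* when both ends map to one
scaffold, on opposite strands with the leftmost end on `+`, and the
outer distance is within `insert_mean * (1 ± tolerance)` (default
tolerance 0.3, a common proper-pair convention). Failing pairs take
the first applicable label in the order `both_unmapped`,
`one_end_unmapped`, `cross_scaffold`, `discordant_orientation`,
`discordant_distance`, so each pair gets exactly one label.

# Novel sequence

Contigs are cut into 1 kbp chunks; a sub-chunk tail is absorbed into
the final chunk (searched as a piece of the penultimate chunk), so
chunk lengths lie in `[1000, 2000)`. After aligning chunks to the
comparison reference at 90% identity, the aligned sub-intervals are
subtracted per chunk and remaining runs *strictly longer* than 50 bp
become putative novel segments. Any alignment at or above the identity
threshold masks its interval (not only best hits), which is the
conservative choice for declaring novelty. Screening against a
user-supplied contaminant or known-sequence database uses 98% identity
over 200 bp. Shared novel sequence between two assemblies is counted
from both directions (the totals differ in general); the single shared
figure reported is the smaller of the two (intersection convention).

# Gene representation

Transcript base coverage follows the chunk-vs-transcript design: only
the single best alignment per chunk is kept, alignments must exceed
95% identity over at least 100 bp, and covered bases are the union of
aligned transcript intervals, pooled as `100 * sum(covered) /
sum(length)`. cDNA completeness aligns full cDNAs to the scaffolds at
90% identity and counts a cDNA as covered at cutoff `c` when its best
alignment's aligned *query* bases reach `c` times the cDNA length
(aligned query bases, not target bases, because the cutoff is a
fraction of the cDNA). Gene fragmentation counts the distinct
scaffolds whose aligned reference span intersects a gene locus.

Note that even a perfect assembly does not reach exactly 100%
transcript base coverage under this method: a chunk overlapping a
transcript end by fewer than 100 bp is filtered, and an overlap shorter
than the seed cannot be found at all. This is a property of the
chunked best-hit method itself and is why finished reference
assemblies report gene coverage a little below 100%. The null-control
tests therefore relax the length filter to the seed length, isolating
the corruption machinery from this sampling artefact.

# The synthetic study

`generate_genome()` builds a truth genome emulating a compact
vertebrate genome: GC 41.6%, ~10% repeats, one gene per 50 kbp with
transcripts of 1–8 kbp taken from the genomic sequence (unspliced, so
chunk-vs-transcript alignment needs no spliced aligner). Repeats are
organised as families — a 500 bp consensus copied ~10 times with 2%
per-copy divergence — rather than identical tandem copies, which keeps
seed hit counts realistic and exercises the uniqueness logic.

`corrupt_assembly()` then plants defects:

* per-base substitution/insertion/deletion events at the specified
  rates, drawn independently with at most one event per base; the
  deletion rate is multiplied by `homopolymer_del_bias` (default 3)
  inside homopolymer runs of ≥ 4 bp, reproducing in synthetic form the
  deletion-heavy error signature of flowgram-based sequencing;
* fragmentation to target contig and scaffold N50s via an adaptive
  exponential breakpoint process (iteratively rescaled until the
  realised N50 is within 10% of target);
* interchromosomal misjoins spliced from pairs of ≥ 20 kbp,
  mostly non-repetitive contigs on different chromosomes (the donors
  are removed from the normal tiling, so every planted misjoin is
  detectable and no extra ones exist);
* contaminant contigs (1–5 kbp) drawn verbatim from a synthetic
  foreign genome at GC 30%, standing in for bacterial contamination;
  the foreign genome is returned as the screening database;
* novel inserts (default 1 kbp at GC 54.2%) placed into assembly
  contigs only — the emitted reference is the unmodified truth genome,
  so the inserts are genuinely absent from it.

Every event is recorded in the `truth_ledger` with truth-genome
coordinates, and the realised rates are stored alongside the specified
ones. All randomness flows through one seeded generator per operation;
identical spec + seed gives byte-identical output, and the global RNG
state of the session is restored afterwards.

`simulate_pairs()` draws read pairs uniformly from the truth genome
(insert size Normal(mean, sd), read 1 forward, read 2 reverse
complement) and, given a corrupted assembly, computes each pair's truth
class from the ledger's contig-to-scaffold mapping. Scaffold gaps in
the generator insert `N`s without consuming genome sequence, so a pair
spanning a within-scaffold junction is still proper at the default
insert tolerance; this idealisation (real gaps hide sequence) is a
known simplification of the generator.

## What the generator does not emulate

Read-level error simulation (flowgrams, quality strings), diploid
heterozygosity, segmental duplication structure, and GC-coverage bias
are out of scope. Passing parameter-recovery tests therefore shows the
*measurement machinery* is unbiased under the planted defect model; it
does not certify behaviour on defect classes the generator cannot
produce (e.g. collapsed duplications).

# Validation strategy and problem sizes

The test suite validates each operation three ways: worked examples
with hand-computed expectations; independent oracles
(`Biostrings::pairwiseAlignment` for alignment scores, cumulative-sum
enumeration for N50, brute-force base sets for interval unions); and
closed-loop parameter recovery against the truth ledger. The recovery
study uses ten seeded replicates of a 5 Mbp, four-chromosome genome
with substitutions at 2×10⁻⁴, insertions at 5×10⁻⁵, deletions at 10⁻⁴
with 3× homopolymer bias, five misjoins, 2% contaminant contigs and
fifty 1 kbp novel inserts — sizes chosen so that each replicate
carries several hundred of every event class (keeping binomial
error small) while a replicate completes in about a minute on one
CPU. Recovered rates are required to sit within three binomial
standard errors of the planted rates; misjoin counts must be exact;
contaminant recall must be complete; novel-sequence recovery must
reach 90% of planted bases (the shortfall is boundary wobble at insert
edges, bounded by the seed and X-drop parameters).

# Numerical and degenerate-input choices

* Alignment identity is `matches / (matches + mismatches + gap bases)`,
  in `[0, 1]`; `N` never counts as a match.
* An all-`N` scaffold decomposes to zero contigs; an empty length list
  is an error for `n_statistic`; a tally with zero aligned bases
  refuses to emit rates.
* `read_psl` recomputes scores from counts under the current scoring
  scheme, since PSL carries none; round-trips preserve block lists
  exactly.
* Score ties anywhere resolve by fixed deterministic chains, so
  repeated runs are bit-identical.

# Known limitations

The aligner is not a genome-scale read mapper; inversions within one
chromosome are not called; breakpoints are not refined to base
resolution; novel segments are not assembled into longer units or
classified taxonomically. The normalisation constant for mis-assembly
counts, the uniqueness ratio, and the gap threshold are all declared
conventions — they are exposed as parameters precisely because the
procedures they parameterise do not pin them down.
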