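---
title: "Methods: quadruplex/i-motif scanning, read filtering and synthetic ground truth"
author: "quadscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quadruplex/i-motif scanning, read filtering and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadscan)
```

## The problem

G-quadruplexes (G4) are four-stranded nucleic-acid structures formed by
stacked guanine tetrads; in transcripts they concentrate in untranslated
regions, where they can modulate translation and transcript stability. On
the strand complementary to a G4-forming stretch, the C-rich sequence can
fold into an i-motif. Because de novo transcriptome assemblies contain both
sense and antisense representations of the underlying genes, a sequence-level
survey of putative quadruplex-forming sequences (PQS) in a unigene set must
scan for both the G-rich and the C-rich form.

`quadscan` implements the full desk-side portion of such a survey as a
reusable pipeline: raw-read quality filtering, assembly summary statistics,
PQS/i-motif scanning, and localization of hits to 5'UTR, CDS or 3'UTR — plus
a synthetic-data generator that plants motifs and read defects with exact
ground truth, so every stage can be validated without external data.

## The PQS model

The scanner uses the classical tract/loop definition

$$d(G_{3+}L_{1-7})_{3+}G_{3+}$$

i.e. at least four tracts of three or more consecutive guanines, separated by
loops of one to seven bases, equivalently the regular expression
`G{3,}.{1,7}G{3,}.{1,7}G{3,}.{1,7}G{3,}`. All four geometry parameters
(`g_run_min`, `loop_min`, `loop_max`, `min_repeat_units`) are exposed through
`pqs_pattern()`; the defaults above are the standard plant-EST setting.

Two deliberate consequences of taking the regex literally:

* **Loops are unrestricted.** The `.` matches any base, including G and N, so
  a loop may itself contain guanines. No "loop must not extend a tract"
  correction is applied; this is flagged here because thermodynamic scanners
  (G4Hunter, cGcC) make different choices. Scoring of folding propensity is
  out of scope.
* **Tracts absorb whole runs.** In the default scan a run of $k \ge 3$
  guanines is consumed by the tract that starts it, so tie-breaking between
  overlapping tract placements never arises in default mode.

### Scan modes

`find_g4()` provides two semantics:

* `default` — standard regex scanning: left-to-right, non-overlapping,
  greedy. A long G-rich region yields one maximal hit. This mirrors what any
  script built on a regex engine reports.
* `exhaustive` — every `(start, end)` substring that parses as
  tracts-and-loops, including nested and overlapping intervals. This is the
  verifiable superset used for planted-truth recall and for downstream
  analyses that must not depend on scan order.

Internally the exhaustive mode is a memoized reachability recursion over
G-run start positions, not a regex. Its results are checked (in the test
suite and the acceptance script) against `pqs_brute_force()`, an independent
quadratic enumerator that validates every candidate substring with the
recursive-descent parser `parse_quadruplex()`. The two routes share no
matching code. Every reported hit also carries its tract/loop decomposition,
re-derived by the parser from the matched substring, so a hit can be audited
without re-running the scan.

### i-motif

`find_imotif()` applies the identical geometry with cytosine tracts. It is
implemented as a G4 scan of the reverse complement with coordinates mapped
back (`[s, e)` on length $L$ maps to `[L-e, L-s)`), which is mathematically
identical to scanning the C-based pattern on the given strand; the test
suite verifies this equivalence against a direct C-tract enumeration. The
hit's `matched_seq` and decomposition refer to the given strand. Unigene
counting (`count_pqs_unigenes()`) collapses multiplicity: a transcript with
many hits counts once per motif class.

## Read filtering

`filter_fastq()` applies three removal rules to raw reads, in the fixed
attribution order adapter, N, quality:

1. adapter: longest exact common substring with the adapter strictly greater
   than 9 bp;
2. ambiguous bases: fraction of `N` strictly greater than 3%;
3. quality: fraction of bases with Phred Q strictly below 3 greater than 50%.

All thresholds are configurable (`filter_thresholds()`); the defaults encode
a stringent HiSeq-era pre-assembly cleanup. Three readings deserve
justification because they are easy to get subtly wrong:

* **Strict inequalities.** "More than" is taken literally: a read with
  exactly 3% N, exactly 50% low-quality bases, or exactly a 9-bp adapter
  match is kept. The boundary tests pin this down.
* **Removal, not trimming.** A failing read (or either mate of a pair) is
  discarded whole; adapter or quality trimming is a different operation and
  out of scope.
* **Adapter matching is exact.** With no published adapter sequence or
  aligner to reconstruct, the longest exact common substring is the
  deterministic, oracle-checkable choice; the adapter sequence itself is a
  required input. The evaluation order affects only which rule a removal is
  attributed to — the keep/remove decision is order-independent, and the
  kept set is invariant under input permutation.

Qualities default to Phred+33 (`phred_offset = 64` selectable for legacy
encodings).

## Assembly statistics

`n50()` is the standard contig N50: with lengths sorted descending, the
length at which the cumulative sum first reaches half the total. It is
always a member of the input multiset; no interpolation. `summarize_assembly()`
adds count, total/mean length, longest sequence, the fraction of sequences
*strictly* longer than a cutoff (default 500 bp), and a binned length
distribution with bins $[kw+1, (k+1)w]$ (default width 100 bp, open-ended
above 3000 bp; both configurable — the bin layout is a presentation choice,
not a statistic).

## ORF-based localization

Public assemblies rarely come with curated UTR annotations, so localization
is operationalized through the longest open reading frame:
`find_longest_orf()` scans the three forward frames for ATG-to-stop ORFs of
at least `min_codons` codons (default 50, a conventional short-ORF floor,
surfaced as an argument) and keeps the longest, ties broken toward the
smaller start then the smaller frame. ORFs lacking an in-frame stop inside
the transcript are rejected so that `[0, orf_start)`, `[orf_start, orf_end)`
and `[orf_end, L)` always tile the transcript exactly. Forward frames only:
unigenes are treated as sense-strand transcripts, antisense structure being
already captured by the i-motif pattern.

`classify_region()` assigns each hit to the region containing the majority
of its bases, ties breaking toward the 5'-most region — a deterministic rule
chosen because per-gene region labels must be single-valued. This heuristic
is a declared substitute for homology-based UTR annotation, not a
reconstruction of it; on real data a BLAST-anchored CDS would be more
trustworthy, and hits on transcripts without an accepted ORF are reported as
`NO_ORF` rather than guessed.

## The synthetic-data generator

The generator exists so that each pipeline stage can be scored against
*constructed* truth:

* **Backgrounds** (`generate_background()`): i.i.d. bases at a requested GC
  content, rejection-resampled until the brute-force checker finds zero G4
  and zero i-motif intervals. The checker is `pqs_brute_force()`, not the
  scanner, so the unit under test never certifies its own fixtures. Default
  300 bp at GC 0.5 — a mid-range unigene fragment; at this length the
  rejection rate is well under 5%, and pathological GC near 1 fails with an
  instructive error.
* **Plants** (`plant_motifs()`, `motif_string()`): motif strings replace
  background bases (length-preserving, so pre-planned coordinates stay
  valid; overlapping plants are an error). Tracts are pure G (or C), loops
  are filled with `A`. A G/A (or C/A) string contains no `ATG`, no stop
  codon, and no tract of the opposite base — so a plant can never create a
  cross-class hit, never seed a spurious reading frame, and the planted
  interval itself always re-parses. Planting can still *delete* a background
  stop codon, which could promote a competing reading frame; see next point.
* **ORF-bearing transcripts** (`generate_orf_transcripts()`,
  `simulate_region_plants()`): an ATG and a terminal TAA are written at
  chosen coordinates (defaults 240 and 690 on a 900-bp transcript — a
  150-codon CDS with realistic UTR room), internal in-frame stops are
  rewritten, and the candidate is rejected unless the constructed ORF is the
  unique longest. Region-targeted plants are placed strictly inside the
  requested region and the dominance check is repeated *after* planting,
  with redraw on failure, so region truth labels are exact by construction.
* **Reads** (`generate_reads()`): read pairs sampled from transcripts at
  Q=40, with a chosen fraction of pairs carrying exactly one violation on
  mate 1: a 12-bp exact adapter insert, `floor(0.03·L)+1` N bases, or
  `floor(0.5·L)+1` bases at Q=2. Clean windows are rejection-checked against
  all three rules, so each truth label is breached by exactly its read and
  nothing else. Qualities are flat by design: the generator emulates rule
  boundaries, not a sequencer error model (no quality-by-cycle decay, no
  indels, no coverage structure). Consequently, passing these checks
  demonstrates the *rules* are implemented exactly; it says nothing about
  how a trimmed-vs-removed policy would perform on real instrument output.

All generators consume a single integer seed and are byte-reproducible;
derived sub-seeds stay below $2^{31}$.

## Numerical and engineering choices

* Coordinates are 0-based half-open everywhere internally and in BED output;
  TSV output adds 1-based inclusive columns for human reading.
* FASTA is written wrapped at 60 columns; ingest uppercases, maps RNA `U` to
  `T` (EST data are cDNA) and rejects IUPAC ambiguity codes other than `N`,
  whose scan semantics would be undefined.
* The exhaustive scanner and the parser both cap their memoization keys at
  the minimum tract count, keeping worst-case work polynomial even on
  adversarial G-dense input.
* `run_pipeline()` writes only to its output directory, logs stage progress
  to stderr, and is byte-deterministic for a fixed config — deleting outputs
  and re-running reproduces them exactly.

## Validation scale

The shipped checks run the scanner/oracle comparison on 1,000 random 300-bp
sequences, planted-recall on 200 motifs across 100 transcripts, filter
fidelity on 1,000 read pairs with 10% violations per rule, N50 against its
definition on 500 random multisets, and ORF search against exhaustive
enumeration on 1,000 random 600-bp sequences — sizes at which the quadratic
oracles are still exact, chosen so the whole suite completes in minutes on a
single core.

## Known limitations

* Pattern matching is purely sequence-based; no folding energetics, no
  G4Hunter-style scoring, no RNA-vs-DNA distinction beyond the U→T mapping.
* The longest-ORF heuristic mislocalizes hits on transcripts whose true CDS
  is not the longest ORF (chimeras, long 5'UTR uORFs, incomplete assemblies).
* The read filter neither trims nor error-corrects; it only removes.
* The generator's reads are unrealistic by intent (flat qualities, exact
  single violations); they are fixtures, not simulations of an instrument.
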