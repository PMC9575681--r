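---
title: "Gap filling with anchored Markov chains: methods and design notes"
author: "markovfill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap filling with anchored Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Scaffolding joins contigs with runs of `N` whose length estimates the
unknown sequence between them. Gaps cluster in and around genomic repeats,
exactly where short-read evidence is weakest; long reads often span a
gap's neighbourhood even when no single read assembly resolved it.
`markovfill` fills scaffold gaps by collecting, from long reads aligned to
a gap's flanks, the read intervals that should contain the missing
sequence, summarising them statistically, and generating a replacement
sequence of exactly the gap's length.

# The procedure

## Gap detection and flank extraction

Gaps are maximal case-insensitive N-runs. For each gap up to `flankLen`
bases of flanking sequence are taken per side, truncated at the scaffold
boundary and at the nearest ambiguous base, so a flank never spans a
neighbouring gap and is always plain A/C/G/T. Each gap is labelled
`both_full`, `left_short`/`right_short`, `single_left`/`single_right` or
`no_flank`; the last is unfillable and skips alignment entirely. When both
flanks are truncated to the same sub-threshold length the gap is labelled
`both_full` (the flanks are balanced, merely short); the label only feeds
reporting.

The alignment query is `leftFlank + N^gapLength + rightFlank`. Bounding
the flanks bounds the query, which keeps alignment specific: an unbounded
gap region in a repeat-dense genome would attract thousands of equivalent
matches.

## Alignment and filtering

The internal aligner seeds exact 15-mers from the query's non-N segments
against the read set and runs Smith-Waterman (Biostrings
`pairwiseAlignment`, match 1, mismatch −2, gap open 2, gap extend 1) on
each seeded read and its reverse complement. Aligning the two flank
segments separately — rather than the N-containing query — makes "N never
counts as a match" structural instead of a scoring convention. Percent
identity is matches over aligned columns including internal indel columns
(`pid` type `PID1`). Pre-computed 12-column tabular alignments can be
substituted (`aligner = "external-tabular"`); their 1-based inclusive,
possibly descending coordinates are normalised exactly once, at parse
time, to the package-wide 0-based half-open convention with the
orientation retained as a flag.

Hits are kept when identity ≥ 97 %, aligned length ≥ 40, and the query
interval lies within 10 bp of the N-run. The 97 % (and 98 % high-quality)
identity thresholds are the method's defining constants; the length and
distance cut-offs are intentionally explicit knobs (`minAlnLength`,
`maxGapDistance`) because only the *existence* of such restrictions, not
their values, is fixed by the method. Survivors are classified `left`,
`right` or `spanning` relative to the N-run.

## Read extension

A left-flank hit is extended rightwards: forward orientation puts the
candidate interval start at `send + (gapStart − qend)` and the end one gap
length later. A right-flank hit is extended leftwards from
`sstart − (gapLength + (qstart − gapEnd))`. Reverse-orientation hits
mirror the arithmetic from the opposite read end, with the strand recorded
as `−`; the reverse complement is applied later, at extraction time.
Indices falling outside the read are clamped to the read boundary and the
record flagged `clamped`; clamped intervals are shorter than the gap and
are the mechanism behind partial fills. Intervals that clamp to nothing
are dropped.

Two branches deserve a note because the natural-language description of
the method underdetermines them:

* **Reverse left-extension.** "The new start index becomes the difference
  between the new start index and the gap length" is circular as written;
  the only reading that yields a gap-sized interval is
  `new_start = new_end − gapLength`, which is what is implemented.
* **Reverse right-extension.** The formula
  `send − (gapLength + (qstart − qend))` ignores where the alignment ends
  relative to the gap. The implementation uses the geometric mapping
  `new_end = sstart − (gapStart − qend)`, `new_start = new_end − gapLength`,
  which coincides with that formula (up to indels) whenever the alignment
  touches the gap — i.e. in every case the formula was written for — and
  remains correct when it stops short.

Spanning hits map the gap offsets directly through the alignment onto the
read; they are the ideal case and need no extension.

## Transition table

Candidate intervals become sequences (minus-strand intervals
reverse-complemented, everything uppercased; candidates containing N are
dropped and counted). Each candidate's adjacent-pair frequencies are
counted into a 4×4 matrix over A=0, C=1, G=2, T=3, the per-candidate
counts are **summed**, and each row is normalised once by its total.
Summing counts before normalising weights candidates by the number of
pairs they contribute; averaging per-candidate probability tables was
rejected because it would give a 1-pair candidate the same influence as a
500-pair one. Rows with zero total stay zero — dividing would be
undefined, and a zero row correctly encodes "this predecessor was never
observed" (the only state a 1-nt candidate can produce).

## Anchored generation and selection

Generation starts from the last scaffold base before the gap (uppercased,
since the table is indexed on uppercase nucleotides). Anchoring guarantees
the chain continues the gap's left context instead of starting at an
arbitrary state; a gap at scaffold position 0 has no anchor and is
reported `unfillable:anchor_missing` rather than anchored on the right
flank with a reversed walk, which would be an invention beyond the method.
`gapLength` successive states are drawn from the current state's row. A
dead state (all-zero row) ends generation early with a partial fill.

Because generation is stochastic it is repeated `nSamples` times (default
8, allowed 5–10) and each sample is scored by its average transition cost:
the mean of the n−1 step probabilities along an n-base sequence. The
anchor step is excluded — n−1 terms for n generated bases is the only
count consistent with that definition; including the anchor step is the
plausible alternative and would shift every score by one term. The
highest-scoring sample wins; ties break to the lexicographically smallest
sequence, then the lowest sample index, so output is fully deterministic
under a fixed seed. Full-length samples always beat partial ones; a
partial fill is written only when no sample reached full length, and then
only its leading bases replace Ns. Gaps of 1 bp are unfillable by
definition: a single base admits no dinucleotide pattern.

Length-1 generated sequences score 0 by convention (no transitions);
this only matters for 2 bp gaps whose single step died.

## Splicing and reporting

Fills replace exactly `[gapStart, gapEnd)`; every other byte of every
scaffold, including soft-masking case, round-trips untouched. An optional
`lowercaseFills` marks inserted bases in lowercase but is off by default
so the default output is plain. A fill longer than its gap is a contract
violation and raises an error rather than being truncated. The per-gap
report (TSV + JSON summary + JSON-lines log) records status, filled
length, average cost and candidate count.

# Randomness and reproducibility

One master seed governs a run. Each gap draws from an RNG stream seeded
with `masterSeed + hash(gapId) mod (2^31 − 1)` (a 31-bit polynomial string
hash), so a gap's fill does not depend on how many gaps preceded it, and
the whole pipeline is a pure function of inputs and configuration — two
identical runs produce byte-identical FASTA, reports and logs. The
simulator derives its read-stage stream the same way, so genome and reads
are independent draws from one seed.

# The synthetic study

The generator emulates the data a gap filler actually faces, desk-scale:

* **Genome**: i.i.d. bases at configurable GC (default 0.5), with planted
  repeat units (each copy independently substituted at a divergence rate)
  because repeats are the canonical cause of gaps. The reference study
  plants one 100 bp unit ×5 at 2 % divergence in 50 kb.
* **Scaffold**: disjoint, non-touching gaps cut from the reference, truth
  recorded; half the gaps are biased into repeat copies when repeats
  exist (best-effort — placement falls back to uniform when the copies
  are saturated, as 20 gaps of 50–300 bp cannot all sit inside five
  100 bp units). Default: 20 gaps of 50–300 bp.
* **Reads**: uniform position and strand to a target coverage (default
  15×), normal lengths (mean 2 kb, sd mean/4, floor 200),
  substitution:insertion:deletion errors at 60:20:20 of the per-base
  error rate (default 0 for the reference study). The mix is a coarse
  long-read caricature — it exists to stress the identity filter, not to
  model a specific instrument.

What the fixtures do **not** emulate: chimeric reads, quality values,
diploid variation, assembly misjoins. Passing tests therefore demonstrate
the pipeline's internal correctness and its behaviour under clean and
mildly repetitive conditions, not instrument-grade realism.

Problem sizes in the shipped tests (50 kb genome for the reference study,
6–20 kb elsewhere) were chosen so the whole suite exercises every stage —
including alignment of hundreds of reads — while staying comfortably
desk-scale.

# What fidelity to expect

Filling has two separable goals: restoring the *length and local
composition* of the missing sequence, and restoring its *exact bases*.
The first is what a first-order chain is built for and what the pipeline
achieves on the reference study (every gap filled at exactly gap length;
run `scripts/acceptance.R` to reproduce the measurements). The second is
information-theoretically out of reach of the generator itself: a 4×4
table is a lossy summary, and resampling from it emits, at each step, the
true next base only with that base's conditional probability (≈ 0.25–0.5
on near-uniform sequence). Exact-base recovery therefore requires either
near-deterministic transition structure (low-complexity or strongly
patterned gaps — the deterministic-chain tests show exact recovery there)
or using a spanning candidate directly, which this method by design feeds
into the table rather than copying (consensus or candidate polishing is
an explicit non-goal). The edit-distance identity reported by
`evaluateFills()` on random-sequence gaps reflects this ceiling and
should be read accordingly.

Other known limitations: gaps longer than both flanks attract alignments
that cannot be extended into full candidates (clamped, partial fills);
single-flank gaps rest on one anchor and inherit its ambiguity; and
gap-length estimates in the scaffold are taken at face value — the filler
never re-estimates gap length.
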