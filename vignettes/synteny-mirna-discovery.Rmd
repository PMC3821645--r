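---
title: "Synteny-based discovery of orthologous pre-miRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-based discovery of orthologous pre-miRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmir)
```

## The problem

Most genome-wide microRNA annotation transfers rely on local sequence
similarity (BLAST-style searches), which truncates alignments at the
divergent 5' and 3' ends of pre-miRNA hairpins and floods the candidate list
with false positives. When two species are close enough that whole-genome
alignments exist, conservation of genomic neighbourhood — synteny — is a
stronger signal: a pre-miRNA annotated in a reference genome should sit at
the orthologous locus of the target genome, reachable by translating its
coordinates through the alignment. `synmir` implements that pipeline:

1. **Liftover.** Reference pre-miRNA coordinates are carried through UCSC
   chain alignments into target coordinates.
2. **Family collapsing.** When several members of one miRNA family land on
   overlapping target loci, a single representative is kept.
3. **Hairpin filtering.** Candidate sequences must fold into a plausible
   pre-miRNA hairpin that a dinucleotide-preserving randomization test
   cannot explain by composition alone.
4. **Re-identification.** Predictions are cross-referenced against known
   annotations with an overlap-ratio rule, and optionally compared with
   sequencing-derived calls.
5. **Regulatory context.** Accepted miRNA genes are classified intronic or
   intergenic, their upstream regulatory sequence is extracted, and
   JASPAR-style position frequency matrices are scanned over it.

Every stage is testable offline because the package ships a simulator that
builds paired genomes with a ground-truth chain file, planted hairpins,
host-gene models and planted motifs.

## Coordinates

Internally every interval is 0-based, half-open, on the forward strand of
its chromosome. GFF3 and browser-style tables (1-based inclusive) are
converted at the I/O boundary; BED and chain files already use the internal
convention. Chain query-side coordinates of minus-strand chains are stored
exactly as the chain format writes them (counted from the start of the
reverse-complemented chromosome) and converted to forward-strand
coordinates only inside the liftover engine, so chain files round-trip
bit-exactly.

One published host-gene table row (PTOV1 / ppy-mir-4706) places the miRNA
end one base past its host gene end; the source's coordinate convention for
that row cannot be recovered. Fixtures therefore assert strict intron
containment for the other eleven rows and treat that row under a documented
one-base extension of the gene.

## The liftover model

A chain is a scored, block-gapped alignment: an ordered ladder of aligned
blocks (`size`) separated by reference-only gaps (`dt`) and target-only
gaps (`dq`). `map_interval()` carries each base of a query interval through
the ladder; bases inside `dt` gaps are lost. The result is classified:

* `mapped` — the best chain aligns at least `min_match` of the bases and
  the mapped bases form one contiguous target interval (a closed `dt` gap
  does not break contiguity; a `dq` insertion does);
* `split` — enough bases align but a target insertion separates them;
* `partial` — the best chain aligns some but fewer than `min_match`;
* `deleted` — every overlapping chain aligns zero bases;
* `unmapped` — no chain overlaps the interval.

`min_match` defaults to 0.95 (dimensionless fraction; the choice brackets
what whole-genome liftover tools use by default and is exposed
everywhere). When several chains qualify, the highest-scoring one wins,
with ties broken by the lower chain id — determinism over guesswork. Split
results are excluded from candidacy by default (`allow_split = TRUE` keeps
the largest piece): pre-miRNAs are 40–180 bases long, and a broken mapping
at that scale signals disturbed synteny rather than a usable locus.
Multiply-mapping loci are reported at their best locus only; the liftover
table retains every status so alternative policies can be layered on.

The engine is verified two ways: against a naive per-base walk of the
block ladder on thousands of random intervals over simulated chains with
indels and inversions, and against `rtracklayer::liftOver` on plus-strand
chains.

## Candidate construction and family collapsing

Lifted loci are length-filtered to 40–180 bases. Animal pre-miRNA
precursors concentrate in roughly 60–120 nt; the wider default bracket
deliberately over-covers so the structure filter, not the length gate,
does the discriminating. Both bounds are arguments.

Within one family, candidates on the same chromosome and strand whose
intervals overlap by at least one base are clustered by single linkage and
each cluster keeps exactly one representative: the highest liftover match
fraction, ties resolved by the lexicographically smallest source name. The
published procedure states only that one member represents the family at a
locus; the specific representative rule here is the package's own
deterministic convention. Candidates without a family label are never
collapsed.

Names are assigned miRBase-style: the species prefix replaces the source
prefix (`hsa-mir-2115` transferred into chimpanzee becomes
`ptr-mir-2115`); distinct loci that collide on a name get `-1`, `-2`
suffixes in coordinate order; and a candidate overlapping a known
target-species record adopts the known name. Letter-variant naming
(`-a`/`-b`) is out of scope: the numeric-suffix rule is a documented
convention, not a reconstruction of the full community scheme.

## The hairpin filter

The published pipeline classified candidates with MiPred, a trained random
forest over folding features. Re-implementing a trained classifier would
import an opaque dependency into an otherwise transparent pipeline, so the
package substitutes a documented rule set with the same intent — separating
pre-miRNA-like hairpins from pseudo-hairpins — built on three primitives:

**Folding.** `fold_hairpin()` maximises a weighted pairing score over all
nested (pseudoknot-free) structures by dynamic programming:
`w(GC) = 3`, `w(AU) = 2`, `w(GU) = 1`, with hairpin loops forced to span
more than `min_loop = 3` unpaired bases. The weights are a pseudo-energy:
they order pairs by stability without claiming thermodynamic accuracy, and
they keep the optimum exactly verifiable — the test suite checks the DP
against exhaustive enumeration of every nested structure for 200 short
sequences. A thermodynamic folder can be swapped in behind the same
`fold_result` contract.

**Features.** From the optimal structure: paired fraction
(`2 · n_pairs / length`), normalised pairing score, the longest perfectly
stacked helix, the number of hairpin loops, and the terminal loop size.

**Randomization test.** The pairing score is compared against
`n_shuffles = 99` dinucleotide-preserving (Eulerian) shuffles with the
add-one estimator `p = (1 + k) / (1 + n)`, so `p` is never zero and the
resolution at the default is 0.01. Shuffles preserve mono- and
dinucleotide counts exactly; a sequence that is its own only dinucleotide
arrangement (e.g. `ACACACAC`) correctly yields `p = 1`. All shuffling is
seeded; identical seeds give identical p-values.

**Decision.** `classify_hairpin()` calls a candidate *real* iff all of:
length in `[40, 180]` bases, paired fraction ≥ 0.5, longest stem ≥ 14
pairs, at most 2 hairpin loops, and randomization `p ≤ 0.05`. The
published work modified only a length threshold and left its value
unstated; these defaults are this package's declared conventions,
calibrated so that planted hairpins (perfect inverted repeats, stems 20–35
bp) pass in ≥ 18/20 seeded replicates while their dinucleotide shuffles
fail in ≥ 18/20. Every threshold is a visible argument.

## Re-identification and the overlap ratio

A prediction recovers a known pre-miRNA when

    overlap ratio = overlapping bases / pre-miRNA length >= 0.5,

with the boundary inclusive. The published formula's denominator ("the
corresponding miRNAs") is ambiguous; the package resolves it to the
*known* record's length — re-identification is a claim about recovering
documented annotations — and exposes `denominator = "predicted"` and
`"shorter"` as alternatives. Matching is strand-strict by default
(pre-miRNAs are stranded); the original procedure is silent, so
`strand_strict = FALSE` is available. Percentages are reported to two
decimals: 601 of 655 known records gives 91.76.

`venn_compare()` applies the same rule with the sequencing-derived
record's length as denominator to partition predicted and sequenced sets
into both/only counts. Sequencing-derived calls enter as finished BED
records; read processing is out of scope.

## Regulatory regions and motif scanning

A miRNA locus is *intronic* when it lies wholly within an intron of a gene
model (host strand irrelevant for containment), *exonic* when it
intersects any exon, *intergenic* otherwise. Intron indices follow
transcription order, so on minus-strand genes they count from the 3'-most
exon. When introns of several genes contain a locus, the shortest
containing intron wins (ties to the smaller gene id) — a deterministic
stand-in for unknowable host-gene biology, and logged as such.

Regulatory sequence is extracted by context: for intronic miRNAs, from the
host intron's transcription-order start to the miRNA's transcription-order
start (empty when the miRNA begins the intron); for intergenic miRNAs,
2000 bases upstream of the precursor start on the miRNA's own strand
(`upstream_len` tunable), truncated at chromosome edges. "Upstream" is
strand-aware by the package's choice; the source does not say. The region
is split at every run of `N` into clean segments — scanning never sees an
ambiguous base — and minus-strand regions are reported
reverse-complemented, in transcription orientation.

Scanning converts a position frequency matrix to log2-odds with a
background-distributed pseudocount (total 0.8):
`p(b, i) = (count(b, i) + 0.8 · bg(b)) / (colsum(i) + 0.8)`. Both strands
are scanned; a window is a hit when its score, rescaled between the PWM's
attainable minimum and maximum, reaches `rel_threshold = 0.8`. A relative
(rather than p-value) threshold was chosen because it is
background-portable and exactly testable; both the threshold and the
pseudocount are arguments. Nucleosome occupancy enters as an optional
bedGraph track: each hit is annotated with the base-weighted mean
occupancy over its window, and `o_max` (off by default) drops hits in
high-occupancy sequence, operationalising the observation that binding
sites favour nucleosome-depleted regions. The interaction model that
produced such tracks in the literature is not re-implemented; any
per-base track fits the interface.

## The simulator

`simulate_synteny_pair()` derives a target genome from a random reference
by seeded substitutions (default 1%), short indels (default 0.002 per
base, lengths 1–8) and segmental inversions (default 1 per genome,
2–4 kb), writing the true alignment as one chain per colinear segment —
inverted segments become minus-strand chains with chain-convention
coordinates. Defaults (2 chromosomes × 50 kb) are chosen so a full
simulate–plant–recover cycle runs in seconds while still exercising every
liftover code path (gaps, inversions, multi-chain chromosomes).

`plant_features()` writes perfect inverted repeats (stem 20–35 bp, loop
4–10 nt) over matched positions of both genomes. Each hairpin sits wholly
inside one aligned block and is written identically on both sides (through
the reverse complement for inverted segments), so the manifest coordinates
are exact oracles rather than probabilistic targets — edits never touch
planted footprints because planting overwrites both genomes after the
edit step. A configurable fraction of hairpins (default 0.5) receives a
two-exon host gene placing it in intron 1; the remainder stay intergenic.
Motifs are PFM consensus strings written at recorded offsets.

What the simulator does **not** emulate: realistic primate divergence
(rearrangement spectra, repeat content, GC heterogeneity), imperfectly
conserved hairpins (planted orthologs are identical in both genomes), and
sequencing noise. Passing the planted-truth suite therefore demonstrates
correctness of the machinery — coordinates, alignment arithmetic, strand
handling, detection calibration on clean signal — not expected recovery
rates on real genomes, where conservation is partial and chains imperfect.

## Numerical and degenerate-input choices

* Liftover ties: highest chain score, then lowest chain id.
* Folding traceback prefers leaving the last base unpaired, then the
  smallest pairing partner; one optimal structure is reported
  deterministically.
* The randomization p-value uses the add-one estimator, so `p ∈ (0, 1]`.
* Zero-length regulatory regions (miRNA at the intron start) yield zero
  segments, not an error; exonic contexts raise an error because no
  extraction rule exists for them.
* Segments shorter than a motif width scan to zero hits silently.
* An empty known set reports `NA` re-identification percentage.
* Chromosome-edge upstream windows are truncated, never wrapped.

## Problem sizes in the test suite

The suite verifies the liftover engine on ~1,500 random intervals against
a per-base oracle, folding on 200 random sequences (length ≤ 14) against
exhaustive enumeration, the overlap ratio on 10,000 random interval pairs,
motif scanning on 50 random 500-bp segments × 5 PFMs against brute-force
window scoring, and end-to-end recovery of 100 planted orthologs across
five seeded simulations. These sizes make the whole suite run in a couple
of minutes on one core while leaving each property's search space
essentially exhausted at the scales where exhaustive checking is possible.

## Known limitations

* The hairpin filter is a transparent stand-in, not a trained classifier;
  its operating point on real genomes differs from MiPred's.
* Family labels are consumed from an input table; covariance-model family
  annotation (Rfam/Infernal) is out of scope.
* Mature-arm calling, target prediction and GO enrichment are consumed
  results in the source work, not methods of this package.
* The numeric-suffix naming convention under-determines community naming
  for paralog families with letter variants.
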