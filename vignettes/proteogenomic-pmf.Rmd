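---
title: "Proteogenomic PMF identification from genome traces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic PMF identification from genome traces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrace)
```

## The problem

When an organism has an unfinished genome and sparse protein annotation,
peptide-mass-fingerprint (PMF) spectra from 2D-gel spots cannot be searched
against a curated proteome. `protrace` implements the proteogenomic
alternative: translate raw whole-genome shotgun *traces* (single reads, no
assembly) in all six reading frames, keep every stop-free segment of at
least 50 amino acids as a candidate open reading frame (ORF), deduplicate
the candidates into checksum-keyed *URFs* (unique reading frames), and
search the PMF peak lists directly against that database. Because such a
database is enormous and mostly non-coding, significance is calibrated with
a reversed-sequence decoy copy of the database: the score above which a
chosen fraction of decoy peptides survives becomes the acceptance threshold
for the real (forward) search.

## The pipeline, stage by stage

### Six-frame ORF databases

Frames +1/+2/+3 translate the forward strand at offsets 0/1/2, frames
−1/−2/−3 the reverse complement, under the standard genetic code, with
trailing partial codons dropped. An ORF is a *maximal stop-free run* in one
frame translation — stop-to-stop, including runs that touch the read ends.
We deliberately impose no start-codon requirement: a single trace usually
covers a gene fragment, so demanding an ATG would discard most genuine
coding sequence. For the same reason alternative initiator codons are never
translated as methionine; a frame translation has no privileged start.
"Longer than at least 50 amino acids" is resolved inclusively (length ≥ 50,
tunable via `min_len`).

Ambiguity codes are kept, not masked: a codon that resolves to a unique
amino acid is translated to it, any other fuzzy codon becomes `X`. `X` is
not a stop, so it does not split an ORF, but peptides containing `X` are
excluded from mass computation downstream (their mass is undefined).

Coordinates are 0-based half-open on the *forward* strand for both strands,
with the frame sign carrying the strand. One convention for both strands
makes probe design against the original nucleotide read a trivial
substring operation, which the tests exercise by round-tripping every ORF
back through its recorded coordinates.

URF identifiers are lowercase hex MD5 digests of the upper-cased amino-acid
sequence: deterministic across runs, independent of provenance, and cheap
to verify. Digest collisions between unequal sequences are checked for and
fatal (for 32-hex-digit MD5 on short protein strings none is expected, but
the audit costs one pass). `split_database()` partitions a database into
consecutive blocks for engines with entry limits; because every entry is
scored and ranking happens after the partitions are merged, splitting is
lossless, which the tests verify against an unpartitioned search.

### Reversed decoys

The decoy database is the plain character-wise reversal of every URF, id
`DECOY_<urf_id>` (the prefix stays outside the digest, so pairing is
recoverable). Reversal conserves length, residue composition and therefore
total mass — invariants the acceptance tests assert entry by entry — while
displacing the tryptic cleavage pattern. No shuffled or Markov decoys are
provided; see *Known limitations* for what plain reversal does and does not
randomize.

### In-silico digestion and masses

Trypsin with the Keil rule (cleave C-terminal to K/R, suppressed before P),
0..`max_missed` missed cleavages (default 1). MH+ masses are monoisotopic
residue sums plus water plus one proton (average-mass mode available);
fixed modifications are per-residue deltas (carbamidomethyl-C is bundled as
a constant, but the default is none, since the original acquisition
settings are not public). Peptides shorter than 4 residues are excluded
from database searches by default: below that length, chance mass
coincidences within tolerance dominate.

### Scoring

The scorer is a fully documented probabilistic stand-in on the familiar
−10·log10(P) scale; it is **not** MASCOT, and its absolute score values
(e.g. the threshold around 55 reported for MOWSE-type scores on real data)
are not comparable. For one spectrum with *n* peaks against one entry:

1. Greedy one-to-one matching: candidate (peak, peptide) pairs within the
   tolerance (default 0.2 Da, ppm available) are ranked by absolute mass
   error, ties broken by lower peptide start offset, and accepted so that
   no peak and no peptide is used twice. One-to-one matching prevents a
   single peak from inflating the match count through mass-degenerate
   peptides.
2. Null model: each peak matches the entry by chance with probability
   *p* = min(1, *m·w/R*), where *m* counts the entry's peptides inside the
   query mass range (extended by the tolerance at both ends, so a peptide
   matchable to an extreme peak is always counted — otherwise *p* = 0
   could co-occur with *k* > 0), *w* is the full tolerance window width
   and *R* the query mass span.
3. Score: the upper-tail binomial probability P(X ≥ *k*), X ~ Bin(*n*, *p*),
   reported as p-value and −10·log10(p-value). p-values are floored at
   1e-300 to keep scores finite; *p* ≥ 1 is clamped (score 0) with a
   warning.

Every entry is scored; the top 50 per database label (forward and decoy
separately, matching the original search protocol of 50 hits per database,
100 per spot) are retained after partition merging, ordered by score, then
matched count, then entry id — a total order, so results are deterministic.
Forward and decoy searches share one code path and one parameter set.

### Unique peptides and the decoy threshold

A peptide's score is the score of the best retained hit that matched it,
and when the same peptide maps to several URFs (or several spots) only the
highest score is kept — counts are therefore counts of *unique peptides*
per database label. Threshold selection ranks the decoy unique-peptide
scores and takes the k-th highest with k = ⌊fn_rate · n⌋ (default
fn_rate = 0.05): for distinct scores exactly k decoy peptides sit at or
above it. Ties all pass, with a warning reporting the excess (ties are
common here, because peptides carried by the same hit share its score).
With k = 0 the threshold is +∞ and *nothing* passes, decoy or forward — a
finite "max + 1" rule would still let a strong forward hit through, which
contradicts what a zero false-negative budget means. Applying the
threshold to the forward assignments is idempotent and reports pass counts
and the pass percentage; a URF is flagged *reliable* if at least one
passing forward peptide maps onto it (set semantics).

### Compositional complexity

The "information content" annotation is the Kullback–Leibler divergence of
a peptide's residue composition from the uniform background over 20
letters: Σ f_a·log2(20·f_a), i.e. log2(20) minus the composition entropy.
It is 0 for a peptide using all residues equally and log2(20) ≈ 4.32 bits
for a homopolymer, so *high* values mean *low* complexity. The flag
threshold defaults to 2.5 bits and is strict (`>`); the flag is an
annotation only — no peptide is removed by it, since no removal rule was
ever validated.

### Reporting

All percentages are `100·num/den` rounded **half-up** to two decimals
(base R's `round()` rounds half to even, which changes boundary cases like
0.125). Overlap tables against external study sets consume homology pairs
as data (candidate id, study set); computing the alignments themselves is
out of scope.

## The synthetic-data generator

`make_traces()` emulates shotgun reads: i.i.d. background nucleotides at a
configurable GC fraction (default 0.32 — an AT-rich invertebrate genome),
lengths normal around 800 nt. Planted proteins are back-translated with
uniform codon usage and inserted at a codon-aligned position on a random
strand, flanked by in-frame stop codons, replacing background of the same
length; by construction the ORF extractor recovers exactly the planted
sequence at the recorded coordinates, which is what makes rank-1 recovery
a meaningful end-to-end oracle. `make_fingerprint()` emulates a PMF peak
list: each tryptic MH+ mass is observed with probability `detect_prob`
(default 0.7), perturbed by Gaussian error (default SD 0.05 Da), plus
uniform noise peaks over 700–3500 Da; spots simulated from a protein keep
at least one true peak.

What the generator does **not** emulate: sequencing error and quality
decay along reads, codon bias, intron-split genes, correlated peak
intensities, detector mass bias, and the compositional statistics of real
genomes. Passing benchmarks therefore demonstrate the pipeline's internal
correctness and calibration under its own assumptions, not performance on
real traces and spectra.

`run_benchmark()` executes the whole pipeline on the default conditions —
2,000 traces × ~800 nt, 20 planted proteins of 60–120 residues (one
spectrum each), 20 pure-noise spectra of 15 peaks, database partitions of
at most 5,000 entries (exercising the merge path) — in well under a minute
on one CPU, and evaluates: the rank of each planted URF for its own
spectrum, and the false-pass rate among forward unique peptides (a forward
peptide is false when it is not a tryptic peptide of any planted protein)
against the decoy estimate.

## Known limitations

**Reversed decoys leak true peptide masses.** Reversing a protein maps the
tryptic fragment between two cleavage sites to the reversed fragment with
the C-terminal K/R swapped for the *previous* fragment's K/R. Whenever the
two flanking residues agree (both K or both R, about half the time, plus
both termini), the decoy peptide has exactly the same residue multiset —
hence the same mass — as a forward peptide. For PMF, which matches masses
only, this means the decoy of a protein that is genuinely present in a
spectrum rescues a large share of its true peaks and scores highly. On the
default benchmark the reversed copies of the 20 planted proteins
contribute the majority of the top-5% decoy scores, which pushes the
threshold up and makes the decoy estimate *conservative*: the realized
false-pass rate among forward peptides falls significantly below the
nominal 5% (the acceptance suite contains exactly this check, and it fails
by design of the decoy construction, not by accident — excluding the
planted decoys restores agreement, ~5.5% vs 5%, and on pure-noise runs
forward and decoy are statistically indistinguishable). At full scale,
with tens of thousands of decoy unique peptides and few true proteins,
the contamination sits well below the 5% tail and the same procedure is
approximately calibrated — which is precisely why the fraction is framed
as a false-*negative* budget on the decoy side rather than a
false-discovery rate. Users who need a clean null for PMF should consider
shuffled decoys; this package intentionally ships only the reversal
construction it models.

**Score scale.** The binomial score is uniform-background; it ignores peak
intensities and the mass-dependent peptide frequency structure that MOWSE
matrices capture. Thresholds selected by the decoy procedure transfer;
absolute score values do not.

**Desk scale.** Test and benchmark problem sizes (hundreds to thousands of
traces, tens of spectra) are chosen so the full suite runs in minutes; the
genome-scale counts of a real trace archive (10^7 reads, 10^7 URFs) are
metadata-format examples only and are not reproduced.

## Session info

```{r}
sessionInfo()
```
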