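---
title: "Methods: motif-demarcated toxin/immunity module annotation and locus comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-demarcated toxin/immunity module annotation and locus comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orphanscan)
```

# Scope and model

`orphanscan` annotates bacterial loci that carry polymorphic toxin/immunity
modules of the CDI (CdiA-CT/CdiI) and Rhs (Rhs-CT/RhsI) families and compares
two such loci for rearrangement. The biological model the package encodes is:

- The toxic C-terminal region (CT) of the full-length gene begins immediately
  after a conserved demarcation peptide motif (VENN in CdiA; PxxxxDPxGL in
  Rhs) and is hypervariable beyond it.
- A small immunity gene sits immediately downstream of every CT, orphan or
  main.
- Orphan modules are detached CT remnants: they encode the motif and a CT but
  generally lack a translation initiation codon and Shine-Dalgarno (SD)
  sequence, while their immunity ORFs remain expressible.
- Loci rearrange by deletion between motif junctions (loading an orphan CT
  onto the full-length gene) and by module interchange between strains.

All internal coordinates are 0-based half-open; every emitted file (GFF3,
TSV) is 1-based inclusive. Input is treated as linear; circular replicons are
out of scope. Translation uses the bacterial/plant-plastid genetic code
(NCBI table 11) — every organism in this problem domain is eubacterial — with
codons containing N or IUPAC ambiguity codes rendered as `X`, which can never
match a motif residue. That choice is deliberately conservative: low-quality
sequence cannot create motif hits, only miss them.

# Stage by stage

## Six-frame motif scanning

A motif pattern uses uppercase residues for exact matches and `.` (or `x`)
for "any residue". The scanner translates all six frames and reports every
(including overlapping) occurrence via zero-width lookahead, then maps
residue index *i* in frame (*offset*, *strand*) back to the nucleotide span
of its codons. On the plus strand the CT start equals the motif span end; on
the minus strand it equals the span start, because the CT extends leftward in
genome coordinates. Frames containing an in-frame stop inside the motif span
cannot match, since `*` never equals a residue letter.

## ORF calling and initiation signals

ORFs are enumerated stop-to-stop on both strands so that start-less CT
fragments remain representable, and each segment is annotated with its most
upstream start codon from {ATG, GTG, TTG} (the standard bacterial initiator
set; the source material does not enumerate one). Segments at a sequence edge
without a terminal stop are reported with `stop_present = FALSE` (fragments
at contig edges); segments with neither a stop nor any start codon carry no
biological signal and are not reported.

"Properly spaced Shine-Dalgarno" is quantified as: the best match count of
the 6-mer anti-SD consensus `AGGAGG` placed with a spacing of 4-20 nt between
its 3' end and the start codon, ties broken toward the smaller spacing. An
ORF is *expressible* iff it has a start codon and SD score ≥ 4 of 6. The
window bounds and threshold are documented assumptions, not literature
constants, and are exposed in `orf_config()` (`sd_window_min`,
`sd_window_max`, `sd_min_score`).

## Module assembly

Each motif hit seeds a CT region (motif end to first in-frame stop, truncated
at the sequence edge otherwise) plus the length of uninterrupted in-frame
coding sequence upstream of the motif. Pairing then selects the nearest
same-strand ORF whose start lies within `max_gap_nt = 300` downstream of the
CT end and whose length falls in 150-900 nt ("small ORFs" at the scale of
known immunity genes); ties on gap go to the longer ORF. Two package-specific
rules matter here:

- ORFs that themselves contain a demarcation motif are CT fragments, i.e.
  modules in their own right, and are never offered as immunity candidates.
  Without this exclusion a module whose immunity gene has decayed would
  capture the next orphan's CT as its "immunity".
- A paired ORF that is itself a fragment (no start or weak SD) is kept, with
  `immunity_expressible = FALSE` — degenerate arrangements occur in real
  loci.

A module is *main* when `upstream_coding_nt >= 3000` (inclusive; full-length
CdiA/Rhs proteins exceed 1,400 residues, so 3,000 nt is a conservative floor
well above any orphan remnant) **and** the ORF hosting the motif is
expressible. At most one main module is allowed per locus; two is a
structural error instructing the caller to split the input. Orphans are
labelled `o1..oN` in 5'-to-3' positional order on the locus strand (majority
strand of the motif hits). Motif-less fragment ORFs — substantial (≥ 300 nt)
non-expressible ORFs overlapping neither a module nor the full-length gene —
are recorded as notes, never labelled.

An insertion element interrupting a CT cannot be *proven* from a single
locus, so the package reports what is observable: the CT ends at the first
in-frame stop inside the insertion, and because the element pushes the
immunity ORF beyond the pairing window the module is reported unpaired with
an `unpaired_or_interrupted` note. `truncated = TRUE` is reserved for CTs
running off the sequence edge. No minimum CT length is enforced beyond the
motif itself.

## Locus comparison

Block comparison is seeded by exact shared 21-mers (`k` configurable, odd,
11-31) on both strands of the subject. Seeds on a common diagonal are chained
when the bridged gap is itself near-identical (≥ 90%) or tiny (≤ 12 nt), so a
sustained divergent stretch always breaks the block; blocks are then extended
outward until three consecutive mismatches, trimmed to matching boundaries,
and reported when ≥ 100 nt at ≥ 90% identity. Extension is gap-free by
design: indels surface as block boundaries, which keeps event calling simple
and auditable. Block boundaries may creep a few chance-matching nucleotides
past a true junction; every downstream quantity is constructed to be immune
to that creep.

- *Divergence breakpoints*: a block boundary within 30 nt of a
  motif-encoding span of locus A is reported as a breakpoint anchored at that
  motif. Boundaries at the sequence edges are ignored.
- *Deletion-fusion* (A = reference): consecutive plus-strand blocks
  contiguous on B (gap ≤ 30 nt, overlap allowed) but separated on A. The
  deleted length is A-gap minus B-gap, i.e. the difference of the two block
  diagonals — exact regardless of boundary creep, which cancels. The event is
  annotated with the A modules inside the gap (removed) and the A module
  whose motif junction abuts the gap end (now fused onto B's main gene).
- *Interchange*: every module pair (CT-plus-immunity span, coding
  orientation) is aligned globally; pairs at ≥ 90% identity over ≥ 500 nt
  are reported. At the event level, pairs conserved *in place* (same label on
  both sides) are plain conservation and are filtered out; interchange means
  near-identity at a different position.

Global alignment is Needleman-Wunsch with match +1 / mismatch −1, gap open 5,
gap extension 1 for nucleotides and BLOSUM62 with gap open 11 / extension 1
for peptides; a gap of length L costs open + L·ext. The tools originally used
for such comparisons publish no parameters, so these standard values are
package defaults, stated rather than hidden. Identity is identical columns
over all alignment columns, end and internal gaps included in the
denominator.

## qPCR relative expression

The efficiency-corrected ratio e = E_target^(−Ct_target) / E_ref^(−Ct_ref),
with efficiencies (fold per cycle, valid range > 1) supplied by the user from
standard curves; standard-curve fitting itself is routine and out of scope.
Replicates summarize as mean ± SEM (sample SD / √n); the SEM is undefined and
refused for n < 2. The function is strictly decreasing in Ct_target,
increasing in Ct_ref, and exactly 1 when target and reference coincide.

# The synthetic locus generator

`generate_locus()` emits the canonical architecture: a 5' spacer; an
expressible full-length gene (in-frame stop, `AGGAGG`, a 6 nt A/C-only
spacer, `ATG`, ~9 kb of stop-free coding whose 3' region encodes
motif + CT + stop); an immunity ORF 15 nt downstream behind the same
SD-junction; then the requested orphan units, each an in-frame stop anchor,
motif, start-codon-free CT, stop, and its own SD + immunity ORF. Key
construction invariants:

- Orphan CT frames use only non-start, non-stop codons (the motif itself is
  encoded with start-free codons, e.g. GTT for Val), so orphan fragments can
  never carry initiation signals — they are fragments by construction, not
  by chance.
- The SD junction (`TAA AGGAGG [ACx6] ATG`) contains no start codon at any
  offset, so the planted immunity ORF at gap 15 nt is always the nearest
  candidate and pairing is unambiguous.
- Candidate loci containing chance motif occurrences anywhere in six frames
  beyond the planted ones are rejected and regenerated from a derived seed;
  generation stays deterministic for a fixed seed.

Noise features: a stop-dense cassette (30 nt units with stops in all six
frames) inserted mid-CT emulates an insertion element; the same cassette
placed after a CT whose immunity was dropped emulates a decayed remnant —
stop density guarantees no ORF of ≥ 150 nt can arise there, so "no immunity"
is a property of the sequence, not of luck; a start-free, motif-free coding
fragment emulates motif-less CT debris.

What the generator does *not* emulate: real toxin/immunity homology (planted
CTs are random and mutually non-homologous), GC skew and codon usage of real
genomes, IS-element terminal repeats, and multi-strand loci (all planted
features are co-oriented, as in the real loci this models). Passing the
recovery tests therefore demonstrates coordinate- and classification-level
correctness of the machinery, not performance on diverged real sequence,
where motif variants (e.g. VEKN) must be supplied as user patterns.

`apply_rearrangement()` plants a deletion from a position inside the main CT
to an orphan's motif junction (the deleted length is forced arithmetically,
so recovery checks are exact) or copies an orphan module over another locus's
main module. The 3,557 nt re-enactment uses a geometry with main CT 1,800 nt,
immunity 600 nt and spacers 1,200 nt, because a CT-to-junction deletion must
exceed the inter-module distance; the compact default geometry cannot host
it. Out-of-frame fusions are permitted — detection is nucleotide-level and
frame-agnostic.

# Validation design and problem sizes

The test suite checks every stage against an independent route: a
hand-written codon-table translator and naive translate-and-search scanner;
an exhaustive affine-gap DP aligner that enumerates co-optimal alignments (so
identity is compared against the attainable set, not an arbitrary
tie-break); brute-force SD window slides; and planted ground truth for
module recovery (exact equality of labels, classes and coordinates on
noise-free loci), deletion lengths (50-10,000 nt, exact), and interchange
identity (≥ 99%). The shipped validation runs 200 scan-oracle sequences of
5-10 kb, 100 synthetic loci with 0-6 orphans mixing both motifs, 100 planted
deletions and 15 module copies; `scripts/acceptance.R` recomputes the same
quantities from a caller-supplied seed. Real-accession spot checks (e.g. CT
identity percentages between named UniProt entries) require network access
and sit outside the shipped suite; when run, alignment-parameter uncertainty
warrants a ±2 percentage-point tolerance.

# Known limitations

- Homology-based naming of CT families and functional toxin-domain calls are
  out of scope; the scanner annotates structure, not activity.
- No profile/PSSM motif models: degenerate motifs are expressed as wildcard
  patterns only.
- Block comparison has no inversion handling within blocks (plus/plus and
  plus/minus orientations only) and no gapped extension.
- The SD model is a consensus match count, not a free-energy model; its
  threshold trades sensitivity against calling spurious initiation signals.
- The mechanism behind an observed rearrangement (independent acquisition vs
  recombination) is not inferred; the package reports events only.
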