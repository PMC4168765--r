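---
title: "Methods: modelling intron-retention variants and truncated receptor prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling intron-retention variants and truncated receptor prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronret)
```

# The problem

A "type II" transcript arises when one intron of a multi-exon gene is left
unspliced in the mature mRNA. Continuing the reading frame of the coding
sequence across the exon/intron boundary almost always reaches a stop
codon a short distance into the intron, so the variant encodes a protein
truncated at the boundary plus a short novel C-terminal peptide encoded by
intronic sequence. For the interleukin-18 receptor alpha gene this
mechanism is predicted to yield a receptor lacking its intracellular TIR
domain — functionally a candidate decoy. This package implements the
in-silico half of that analysis as reusable, deterministic components:
transcript modelling, truncation prediction, in-silico PCR,
polyadenylation/termination scanning, repeat-insert characterization, and
cross-species comparison, each testable end-to-end on synthetic loci.

# Coordinate model

All user-facing coordinates are 1-based and inclusive, matching how locus
coordinates and primer binding ranges are conventionally printed;
conversions to 0-based systems happen only at I/O boundaries (BED export
is 0-based half-open per that standard). A genome record may carry an
`offset` so that a several-kilobase slice of a chromosome can be addressed
with genuine chromosome coordinates — this is how the packaged human
surrogate locus uses hg19 numbers without shipping a chromosome.

Introns are indexed by the exon they follow: intron *k* lies between exons
*k* and *k* + 1, so "intron 8-9" is intron index 8. Minus-strand genes are
supported by reverse-complementing extracted segments; all
transcript-level coordinates are strand-relative 5′→3′, and strand
handling is verified by a symmetry property (a gene mirrored onto the
minus strand of the reverse-complemented genome must produce byte-identical
transcripts).

# Frame anchoring and the novel C-terminal

Reading frame is propagated from a **frame anchor**: a transcript position
known to be the first base of a codon. We anchor by transcript position
rather than GFF phase fields because published gene models are most
reliably anchored by a printed (transcript nucleotide, protein residue)
pair — for the packaged human fixture, transcript nt 1132 is the codon
start of residue 370.

The **novel C-terminal peptide** is defined operationally as the residues
encoded by codons containing at least one intronic nucleotide, up to but
excluding the first in-frame stop. This definition makes the published
residue counts reproducible: with the retained segment starting at
transcript position $s$ and anchor $a$, the novel region begins at the
first codon start $c \ge a$ with $c + 2 \ge s$. The boundary codon's
composition (exonic nt, intronic nt) is reported whenever the exon does
not end on a codon boundary. If no stop occurs before the transcript end,
the report carries a `no_stop` flag and the peptide runs to the last
complete codon. Codons containing ambiguity codes translate to `X` and are
never treated as stops — the conservative choice for draft-quality genome
bases. Only the standard nuclear genetic code is supported.

# Alignment engine

Pairwise alignment is a three-state affine-gap dynamic program implemented
in C++ with two modes:

* **global with free end gaps** — terminal overhangs are unpenalized
  (appropriate for aligning a sequencing read against a longer predicted
  transcript); the empty overlap (score 0) is admitted as a floor;
* **local** — best-scoring subalignment, empty alignment allowed.

A gap run of length $L$ costs $open + (L - 1) \cdot extend$. Defaults are
match +5 / mismatch −4 with gap open 12 / extend 3 in global mode (the gap
penalties documented for the read-vs-prediction comparisons this package
reproduces), and open 10 / extend 0.5 in local mode, following the common
Smith–Waterman tool convention. The published comparisons used a
proprietary "65% similarity" nucleotide matrix whose numeric values are
not public, so identity percentages from that tool are reproducible only
approximately; the match/mismatch scores here are config-overridable and
a full substitution matrix can be supplied. Traceback is deterministic:
on ties, diagonal beats up beats left, and among predecessor states the
match state wins. The tests check the engine against two independent
oracles (an exhaustive path enumeration on tiny pairs and a
direct-definition cubic DP on pairs up to length 8) and against the
reference Bioconductor aligner on longer pairs.

Alignment statistics follow the conventional triple: identities
(exact-match columns), positives (identities plus IUPAC-compatible
columns, e.g. `R` vs `A`), and gapped columns, all over the alignment
length. The substitution spectrum counts transitions (A↔G, C↔T),
transversions, and gap runs; gap runs are counted **per row**, so adjacent
indels in opposite rows are separate events.

The progressive multiple aligner builds a guide tree from k-mer distances
(k = 6, fractional shared-count distance) with UPGMA (average-linkage
`hclust`), then merges profiles along the tree with the same affine
engine, scoring profile columns by frequency-weighted match/mismatch sums
(ambiguous symbols score 0). There is no iterative refinement: outputs are
deterministic for fixed input order and parameters, and figure-level
percent identities from refinement-based tools are matched approximately,
not bit-exactly. Percent identity to a reference row is computed over the
reference's non-gap columns only.

# PolyA signals, termination, and EST evidence

The polyA scan reports exact `AATAAA` occurrences by default; variant
hexamers (`ATTAAA`, …) are opt-in because only the canonical signal is
asserted in the analyses this package reproduces. A termination site is
called from EST evidence: the EST's trailing oligo(dA) run (default: the
longest A-suffix with at most one interruption, minimum length 8) is
trimmed, the remainder is locally aligned to the intron, and the TTS is
the 3′-most covered intron position. Without EST evidence no cleavage
offset is invented: the call is an interval
(signal end, signal end + 40 nt by default) labelled `signal-only`; the
window width is an arbitrary, documented configuration value, since the
published 357-nt endpoint is EST-derived rather than formula-derived.

# Repeat-insert characterization

A candidate insertion is characterized by (i) the target-site duplication:
the longest direct repeat, within configurable bounds (5–25 nt, ≤1
mismatch — typical retrotransposition values; the source analyses print no
bounds), with one copy immediately 5′ and one immediately 3′ of the
insert; (ii) the oligo(dA) tail length under the same interruption rule as
EST trimming; (iii) the distance from the nearest upstream polyA signal's
hexamer end to the 5′ TSD start; and (iv) a substitution spectrum against
a user-supplied consensus after free-end-gaps alignment. Because whether
published divergence counts include the tail/TSD regions is ambiguous, the
spectrum is reported both over the full alignment and restricted to the
consensus-covered column span.

# The synthetic-data generator

`generate_locus()` emits a locus in which every feature the pipeline
detects is planted with known truth: exon/intron structure (defaults: 3
exons of 150/120/90 nt, retained intron of 600 nt — small enough for fast
recovery grids, large enough to hold all features), a designated boundary
phase (0/1/2 exonic nt in the boundary codon), a planted novel length
(codons to the stop), a single `AATAAA` at a chosen intron position
(default 290), a TTS (default 357, mirroring the EST-supported human
endpoint), optional TSD/element/tail insertions, and primer pairs in exons
and in the retained intron. Defaults mirror the human case (phase 1,
novel length 22); the rodent case is phase 1 with novel length 5.

Design points worth knowing:

* The spliced coding sequence is generated codon-wise from sense codons,
  so the spliced transcript never contains a premature stop — which the
  tests use as a frame-anchoring sanity check.
* Recovery tests are exact, not statistical, so planted features are made
  unambiguous by construction: accidental `AATAAA` occurrences upstream of
  the TTS are rejection-scrubbed (and the intron is rebuilt if an
  occurrence falls inside a protected feature core); the two intron bases
  at the TTS boundary and a two-base spacer before the oligo(dA) tail are
  forced non-A so greedy A-trimming cannot eat genuine sequence; and
  requesting novel length 0 with a split boundary codon rewrites the
  exon's final bases to be compatible with the stop triplet.
* All randomness is seeded and scoped (`withr::with_seed`), the seed is
  recorded in the manifest, and the global RNG state is untouched.
* Every generated locus is self-validated before being returned: the
  generator re-runs the pipeline's own detectors and errors out rather
  than emit a locus whose manifest does not recover.

`generate_species_panel()` derives diverged species by uniform (JC-style)
substitutions outside protected feature cores, with optional stop
knockouts and optional short indels confined to the intron tail (indels
shift downstream exon coordinates, which the per-species gene models
absorb). `generate_noisy_reads()` produces substitution/indel-bearing
full-length reads as stand-ins for Sanger consensus reads.

What the generator does **not** emulate: splice-site motifs (no GT/AG
enforcement), realistic substitution processes (no transition bias,
no rate heterogeneity), base-quality structure, heterozygosity, or
paralogy. Passing the recovery suite therefore demonstrates algorithmic
correctness on unambiguous inputs, not robustness to the full messiness
of real genomes.

# The packaged human fixtures and the surrogate locus

The package ships verbatim the published human materials that are plain
text: the 362-nt expected type II sequence (302 exonic nt + the first 60
intron nt), the primer table with binding coordinates and product sizes,
and the hg19 locus coordinates. The chromosome sequence itself cannot be
shipped, so `il18r1_surrogate()` builds a **synthetic** slice at run time:
random background with every published sequence planted at its published
coordinate. Intron nt 61–68 (beyond the published 60-nt prefix) are two
synthetic sense codons plus a stop, chosen so the continued frame yields
the reported 22-residue novel C-terminal; the `AATAAA` placement at intron
position 290 is likewise a synthetic choice (the published account places
it just upstream of the 357-nt termination point without an exact
coordinate). Everything derived from the surrogate is therefore exact in
its coordinate arithmetic (687 bp and 874 bp products, 4,251-nt retained
segment, position 1136 ↔ chr2:103,006,678) while its sequence background
is explicitly synthetic and documented as such.

```{r surrogate, eval = FALSE}
rep <- run_pipeline_surrogate()
rep$amplicons
rep$truncation$novel_peptide
```

# Problem sizes and determinism

The shipped tests run entirely offline on synthetic loci of a few hundred
to a few thousand nucleotides: the parameter-recovery grid covers boundary
phases × novel lengths {0, 1, 5, 22, 50} × TSD {7, 12, 20} × tails
{0, 8, 15} × polyA/TTS placements across more than one hundred seeded
fixtures; the alignment engine is checked against the independent oracles
on thousands of short pairs; coordinate round-trips are verified on ten
thousand random positions. These sizes were chosen so the full suite
completes in well under a minute on a laptop while still exercising every
code path. All pipeline outputs are byte-reproducible for fixed inputs
and configuration.

# Known limitations

* The truncation module assumes a single retained intron per transcript;
  multiple simultaneous retentions and trans-splicing are out of scope.
* The aligner is exact dynamic programming; there is no heuristic seeding,
  so it is not a database-search replacement.
* The progressive MSA has no refinement step and should not be expected to
  match refinement-based aligners column-for-column on divergent inputs.
* Conserved-column detection requires per-row frame offsets supplied by
  the caller for stop codons; it does not infer frames.
* TSD detection reports the longest qualifying repeat; for near-periodic
  duplications the boundary between repeat and flank is inherently
  ambiguous.
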