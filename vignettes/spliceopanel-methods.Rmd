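---
title: "Methods: identifying spliceosomal genes in a non-model transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying spliceosomal genes in a non-model transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceopanel)
```

# The problem

Organisms such as euglenids process nuclear pre-mRNA with a spliceosome
whose protein inventory has never been annotated, and they additionally
replace the 5' end of most messages with a short spliced-leader (SL) exon
by trans-splicing. Screening a de novo transcriptome assembly and a partial
genome draft for a curated reference panel of spliceosomal proteins
involves several steps that are usually run as one-off scripts around
BLAST: translated homology search, reciprocal best-hit (RBH) orthologue
calling, open-reading-frame (ORF) verification across sequencing platforms,
SL-prevalence estimation, genomic snRNA detection and drug-contact-residue
comparison. `spliceopanel` packages that workflow as tested, reusable
components, together with a seeded synthetic-data generator that stands in
for the sequencing data and makes every stage verifiable against ground
truth.

# The reference panel

The panel is a manifest (id, display name, category, optional
paralogue-group token) plus protein sequences. The packaged manifest
reproduces the published 257-protein inventory: 110 snRNP and non-snRNP
proteins (14 Sm/LSm, 9 U1, 21 U2-related, 19 U4/U5/U6, 19 NTC/NTR/IBC,
3 RES, 15 EJC/TREX, 7 ATPase, 2 CBC, 1 debranching enzyme), 79
stage-specific proteins, 43 SR/hnRNP/pre-mRNA-binding proteins and 25
miscellaneous ones. Because the source figure is not machine-readable, rows
whose names the accompanying text does not print carry systematic
"(placeholder)" names; the category structure and all counts are faithful.
Sequences are deliberately not bundled (the source provides names, not
sequences): `load_panel()` accepts a placeholder sequence for pure
accounting, or a user-supplied FASTA for real screening.

Twelve paralogue sets are screened as single units: `collapse_paralogues()`
replaces each set by its first-listed member while retaining every member
sequence as a valid homology target, shrinking 257 entries to 241. One set
(the hnRNP A group) has an ambiguous published membership; the default
grouping uses four members so the collapsed total matches the published
241, and the grouping lives in a manifest column so users can re-group
without touching code.

# Homology search and orthologue assignment

The search is a full affine-gap Smith–Waterman over all six reading frames
of each transcript against every panel member sequence plus a decoy
background — no seeding heuristics, because at desk scale correctness is
cheaper than speed. Scoring defaults are BLOSUM62 with gap open 11 / extend
1; a gap of length $L$ costs $11 + L$. Raw scores convert to bit scores via
the Karlin–Altschul parameters $\lambda = 0.267$, $K = 0.041$ (the standard
gapped BLOSUM62 11/1 values; the source names BLAST but no parameters), and

$$E = m \, n \, 2^{-S'} , \qquad S' = \frac{\lambda S - \ln K}{\ln 2},$$

with $m$ the frame-peptide length and $n$ the total residue count of the
searched protein set. Acceptance is strictly $E < 10^{-6}$, matching the
published rule. Nucleotide searches (snRNA scan, copy-number clustering)
use +2/−3 with gap 5/2 and $\lambda = 0.625$, $K = 0.41$.

A transcript is assigned to a panel entry only if (i) its best hit across
panel-plus-decoys is a member sequence of that entry and (ii) its best hit
within the panel alone is the same entry — strict RBH; the published
description of the reciprocal step is looser, and a
`no_forward_background` switch reproduces that panel-only screen. Copy
numbers come from single-linkage clustering of each entry's assigned
transcripts at ≥ 95% global nucleotide identity, so redundant assemblies of
one locus count once while diverged duplicates count separately.
Transcripts flagged as assembly chimeras are excluded from copy counting,
mirroring how the original study re-annotated a chimeric transcript after
discovering it.

## Over-extension and the X-drop discipline

An exact local aligner differs from a seeded-extension search in one
practically important way: it will happily bridge unrelated sequence —
an intron, or the other half of a chimeric fusion — whenever flanking
matches pay for the bridge, and it will extend into weakly positive chance
similarity because the optimum ends wherever the running score peaks.
Typical excursions of that random walk sit on the Karlin–Altschul scale
($\sim \ln n / \lambda \approx$ 20–30 raw score units). Two derived
operations therefore post-process alignments:

* **Splitting** (genomic projection): an HSP is cut wherever its running
  column score drops more than 12 below its maximum, recovering the
  per-exon HSPs a BLAST-style X-drop extension would have reported.
  Sub-segments inherit the parent's significance but must clear a raw-score
  floor of 25 to discard chance micro-matches.
* **Core trimming** (chimera flagging): an HSP is reduced to the shortest
  column span within 30 raw-score units of its optimum, removing chance
  tails that would otherwise hide the near-disjoint two-segment fusion
  signature.

# Cross-platform ORF verification

`find_orfs()` reports every maximal ATG-to-stop span in all six frames plus
stop-less 3'-open spans. An ORF is *intact* relative to a panel protein
when it has a start, a stop, and covers at least 80% of the reference
length (inclusive boundary; the source never defines "intact", so the
threshold is explicit and configurable). Genes are then reconciled between
the short-read assembly and the full-length reads into four classes
(both / NGS-only / FL-only / neither); the published class counts
(118, 40, 2, with 9 in neither) sum to 169 against a stated universe of
168 — the package's fixture uses the printed class counts and the tally
invariant checks against its own universe.

A transcript is flagged as a chimera when two trimmed HSPs to entries of
different paralogue groups occupy query ranges overlapping by less than 10%
of the shorter one, each covering ≥ 25% of its subject; the breakpoint is
the midpoint between the ranges.

# Genomic projection and exon chains

Each contig is translated in six frames and searched iteratively (masking
previous hits) against the protein, split per the X-drop discipline, and
the best collinear chain by summed raw score is selected. Chained
neighbours may overlap generously (up to 150 nt) but the overlap is charged
at a typical per-residue match score, which prices duplicate hits of the
same exon out of the chain. At each junction the unexplained length —
raw contig gap plus 3 nt per doubly-claimed subject residue — decides
intron-ness (≥ `min_intron`, default 30 nt); boundaries are then snapped to
the nearest canonical GT..AG pair within 90 nt, subject to a length
consistency cap so a sub-threshold junction can never acquire a fabricated
intron. GT..AG is annotation, never a filter, because the organism also
uses nonconventional introns. Splice-boundary refinement currently operates
on plus-strand chains only; minus-strand genes are detected and chained in
forward-contig coordinates with a strand field, but their intron boundaries
are not snapped — a known limitation.

`covered_fraction` is the union of matched protein ranges over the protein
length, per contig; "majority on a single contig" is strictly
`covered_fraction > 0.5`, reproducing the published more-than-half rule.

# Spliced-leader detection and prevalence

Trans-splicing adds the SL exon 5'-terminally, possibly truncated by
library preparation, so only suffixes of the SL are matched: a read is
flagged when an SL suffix of ≥ 12 nt occurs with ≤ 1 mismatch (no indels)
starting within the first 5 nt of the read; the longest qualifying suffix
wins. These defaults keep the analytic false-positive rate far below one
call per test-scale read set and are configurable; the source states no
matching rule. The organism's real SL sequence is not printed in the
source, so it is a required input; the generator ships a fixed synthetic
24-mer.

Prevalence is the flagged fraction — per gene when a read-to-gene map is
available (a gene counts once if any of its reads is flagged), matching the
published per-gene accounting — with a Wilson 95% interval. Reported
percentages are rounded half-up (one decimal, or integer display where the
published figure is an integer).

# Genomic snRNA scan

Queries (the same snRNA from increasingly distant species) are tried in
order; the first with any accepted hit is the reported "successful query",
emulating the published fallback from a close relative's U6 to the human
one. Hits are extracted iteratively per strand so tandem copies each yield
one hit; maximal runs of ≥ 2 same-element, same-strand hits with
start-to-start spacing ≤ 1 kb are reported as tandem arrays (the published
ten-copy array occupies an 8 kb contig, hence sub-kilobase spacing). Motif
annotation is pure configuration — IUPAC patterns with optional position
windows — because the source shows motifs only graphically; no default is
asserted as organism truth.

# Modulator contact mapping

Splicing-modulator insensitivity is examined at sequence level: a global
affine-gap alignment transfers structure-defined contact residues from the
human reference to the query protein. A contact is conserved iff the
aligned residue is identical; contacts landing in gaps are unmapped and
divergent. "Similarity" is defined here as the fraction of alignment
columns (gaps included) with a positive substitution score; the source
never defines its similarity figures, so they are reported but not asserted
against. The packaged contact set carries only the residues named in print
(SF3B1 V1078 and PHF5A C36 for pladienolide B; CDK11 H572 and G579 for
OTS964); the remaining SF3B1 contacts are shown only graphically in the
source and are user-extensible.

# The synthetic world

The generator emulates the statistical structure the analysis assumes, not
the sequencing process:

* Panel proteins are uniform random sequences (100–250 aa by default;
  shorter than many real spliceosomal proteins, a deliberate desk-scale
  choice) starting with M.
* Orthologues diverge by independent per-site substitution (default 0.15 in
  the easy scenario; 0.3 in the paper-like scenario) and are
  back-translated with a fixed most-frequent-codon table so translated
  search is exact at divergence 0.
* Presence is Bernoulli (0.9 easy; 166/241 paper-like); ~10% of present
  genes carry a second copy diverged 10% at the nucleotide level;
  ~5% of present genes spawn a head+tail fusion chimera; 10 random
  background transcripts emulate non-spliceosomal contamination.
* Full-length reads are the transcripts with the SL prepended per gene at
  the study-level prevalence 0.727.
* Genomic contigs carry the CDS split by GT..AG introns (40–120 nt) at
  near-equal codon-boundary cuts — equal-sized exons are the natural
  reading of "a gene split by k introns", and random cuts would create
  micro-exons no homology search could detect — plus one contig with a
  tandem small-RNA array.

One top-level seed derives an independent stream per record, so adding a
gene never shifts another gene's sequences, and all outputs are
byte-identical under a fixed (seed, scenario).

What a green test establishes is that the pipeline's decision rules recover
the truth of this stated world; it does not establish performance on real
reads (no sequencing error model, no coverage variation, no assembly
artefacts beyond the modelled chimeras, codon usage fixed rather than
organism-specific).

# Numerical choices

* Coordinates are 0-based half-open internally; BLAST-style outputs are
  1-based inclusive; minus-strand features are stored in forward-contig
  coordinates with a strand field.
* Alignment tie-breaks: among co-optimal local alignments, smallest query
  start then smallest subject start; within a traceback, match over
  insertion over deletion. Ties are resolved identically on every run.
* Percentages round half-up with a small relative epsilon so decimal
  halves stored just below .5 still round up.
* The empty alignment (all-negative scores) yields a zero-score HSP with an
  empty range rather than an error.

# Known limitations

* Minus-strand splice-boundary refinement is not implemented (annotation
  only).
* Karlin–Altschul parameters are fixed per scheme, not estimated from the
  matrix; E-values for custom matrices require user-supplied
  $\lambda$, $K$.
* The chimera rule assumes two-gene fusions; three-part chimeras would be
  flagged on one junction only.
* Cross-species comparison operates purely on homology calls; the published
  counts additionally folded in mass-spectrometric evidence and are
  therefore not reproduced number-for-number.
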