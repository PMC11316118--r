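---
title: "Proteogenomic smORF discovery and Ribo-Seq coverage classification with smorfkit"
author: "smorfkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic smORF discovery with smorfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smorfkit)
```

## The problem

Small open reading frames (smORFs, here at most 150 codons) encode
microproteins that standard genome annotation misses. Two lines of
evidence exist for them: ribosome profiling (Ribo-Seq), which sequences
25–34 nt ribosome-protected fragments (RPFs), and proteomics, which
matches fragmentation spectra against a protein database. Each has a
blind spot. RPFs are so short that reads from duplicated loci
(pseudogenes, retrotransposons, paralog families) map to multiple
genomic sites and are discarded as multi-mappers, while reads under
dense isoform nests overlap several features at once and are discarded
as ambiguous. Proteomics only finds what is in its database.
`smorfkit` implements the computational core of a
proteogenomics-first workflow: build a custom database containing the
whole coding potential of a transcriptome, let peptide evidence
identify microproteins, and then *diagnose* — rather than silently
lose — the Ribo-Seq mapping regime of each identified smORF.

## Database construction (`seqdb`)

Assembled transcripts (GTF exon models over a genome FASTA) are spliced
(`extract_transcript_sequence()`) and translated in the three forward
frames. Each frame is segmented at stop codons; within an inter-stop
segment containing at least one ATG exactly one ORF is emitted, starting
at the *most upstream* ATG — the longest candidate per segment. ORFs
truncated by the transcript end (no closing stop) are kept and flagged,
because 3'-incomplete assemblies are common. Codons containing N
translate to X and at most one X per protein is tolerated by default
(`x_policy = "drop"` discards such ORFs instead). Proteins longer than
`max_aa = 150` residues are discarded; that ceiling mirrors the
conventional smORF definition and is configurable.

The search database appends a tagged reference proteome and contaminant
entries to the predicted microproteins (predicted entries deduplicated
on sequence with provenance ids merged — a prerequisite for well-defined
unique-peptide logic later), then adds one decoy per forward entry. The
decoy is the full character reversal of the forward sequence, including
the initial methionine, and contaminants are decoyed too. Internally all
intervals are `GenomicRanges` objects (1-based closed); GTF input and
output therefore needs no coordinate shifting, and one convention is
used everywhere.

## Digestion and peptide physicochemistry (`digest`)

`digest_trypsin()` applies the classic Keil rule — cleave after K or R
except before P — with zero missed cleavages; peptide offsets always
reconstruct the parent. Monoisotopic masses are residue-table sums plus
one water (18.0105646863 Da), with fixed carbamidomethylation available
as a constant per-cysteine offset. Isoelectric points solve net charge
zero by bisection on (0, 14) to 1e-4 pH, with a strictly decreasing
Henderson–Hasselbalch charge model over the termini and D, E, C, Y, H,
K, R. The pKa table is EMBOSS by default, Bjellqvist selectable; the
choice is recorded on the output because absolute pI values shift
between tables even though distribution comparisons are stable.

A peptide is a **unique tryptic peptide (UTP)** when it occurs as a
substring of exactly one forward protein in the database. Substring
(not digest-based) matching is deliberate: a homolog that merely
contains the span disqualifies the peptide even if trypsin would never
release it from that homolog. I and L are distinct by default; since
mass spectrometry cannot tell them apart an `il_equivalent` switch
collapses them. UTP status is monotone: growing the database can only
revoke uniqueness, never grant it.

## PSM filtering (`psmfilter`)

Scored peptide-spectrum matches arrive in a pin-style table. Instead of
a semi-supervised re-scorer, q-values are computed directly from
target–decoy competition: rank by descending score, estimate FDR at
each threshold as (1 + decoys above) / (targets above) — the +1 makes
the estimator conservative — and take the running minimum from the
permissive end. Ties share the estimate of their block and mixed
target/decoy mappings resolve to target. Protein-level inference uses
picked-protein competition: a protein's score is its best PSM, each
target competes with its reversed decoy, and only the higher-scoring
pair member enters the ranked list (ties keep the target). A grouped
variant estimates q-values separately for microproteins and canonical
proteins; the global estimate remains the default because grouped
estimation is markedly more liberal for the novel group.

The surrounding filters are exact implementations of their rules:
peptides occurring in any annotated or contaminant sequence are removed
(multi-predicted peptides are kept); predicted proteins wholly contained
in an annotated protein (100% identity over 100% of the query) are
excluded by substring containment, which is equivalent to the stated
alignment criterion and needs no external aligner; the second-round
database appends only first-search survivors to the reference proteome
with fresh decoys, so re-scored FDR estimates are not diluted by a
bloated three-frame database. For immunopeptidomics the evidence unit is
the intact peptide, so q-values are computed at peptide level and
candidates pass an inclusive affinity ≤ 100 nM, percentile ≤ 0.02 and
7–12 residue window; the nonspecific search space enumerates all
substrings of 8–25 residues with monoisotopic mass in 500–1500 Da.

## Four-regime read counting (`ribocov`)

Alignments (SAM; secondary flag 0x100 honored, NH used when present)
are counted against the smORF coordinates appended to the reference
annotation under four regimes: default, ambiguity allowed (`-O`
analogue), multi-mapping allowed (`-M` analogue), and both. The
semantics are per alignment: a read reporting several alignments is
unassigned (multi-mapping) unless the regime allows it, in which case
every alignment that individually overlaps exactly one feature assigns
it — an alignment overlapping several features needs the ambiguity
switch. A read contributes at most one count per feature no matter how
many of its alignments hit it, overlap means at least one shared base
(`min_overlap` configurable), and counting is unstranded by default.
Every read lands in exactly one summary category (assigned /
multi-mapping / ambiguity / no features), so the four categories
partition the library — an invariant the tests enforce.

RPKM is count / (kb × million assigned reads), with the assigned total
taken per regime. A smORF joins a mapping group when a regime yields at
least 10 raw counts, and its label is the least permissive qualifying
regime: `Default`, else `Amb` or `MM`, else `MM_Amb`, else
`NoCoverage`. When both single relaxations qualify the tie goes to
`Amb` by default — ambiguity is the weaker relaxation, since the read is
still uniquely placed in the genome — with `mm` and `both` available.
The multimapper-exclusive set (`MM`/`MM_Amb` labels that do not qualify
under `Amb` alone) isolates the smORFs whose translational evidence
exists *only* if multi-mapped reads are admitted. The export matrix is
log10(RPKM + 1), rows ordered by group then descending `mm_amb` RPKM;
the log base is a documented choice.

## Annotation (`annotate`)

Each smORF gets exactly one class by precedence: overlap with a
pseudogene or retrotransposon biotype (`rtORF`), frame-compatible
same-strand CDS overlap (`aiORF`, an alternative initiation site of the
annotated ORF — frame compatibility is assessed on genomic coordinates,
a single-exon heuristic), full containment in the 5' UTR of a coding
transcript (`uORF`), retained-intron transcripts (`riORF`), lncRNAs
(`lncORF`), no transcript overlap (`noncoding`), else `other-overlap`.
rtORF ranks first because duplicated-locus residence is the property
that explains multi-mapping, the analysis this classification feeds;
the order is recorded on the output and configurable in spirit (the
rules are small, pure functions). Overlapping-feature counts use
transcript records, matching the isoform-density reading of the
coverage analysis; repeat residence is any one-base overlap with a
RepeatMasker-style interval. Conservation tables are filtered with
strict bounds, E-value < 0.001 **and** bit score > 50, before building
the per-species presence matrix.

## The simulator (`simulate`) — and what it does not show

All tests run against `make_genome()` fixtures with analytic ground
truth. One chromosome carries, separated by 250 nt random spacers:
single-copy intergenic smORF loci (expected group `Default`), paralog
families of byte-identical copies (`MM`) — divergence defaults to 0
because exact duplication is precisely the copy-paste regime of
retrotransposons and young pseudogenes that causes multi-mapping —
isoform nests of three overlapping reference transcripts above one
smORF (`Amb`), and one locus per annotation class with the reference
features that define it. Half the planted smORFs are spliced over one
42 nt intron; some loci sit on the minus strand. Each 60 nt UTR is
ATG-free with an in-frame stop just upstream of the planted start, so
the planted protein is exactly what the most-upstream-ATG rule must
recover.

Reads are drawn uniformly within ORF blocks (RPFs, 25–34 nt,
strand-matched) or along host-transcript exons (RNA-seq, 100 nt, both
strands), then placed by exact matching against the whole genome: every
exact hit becomes an alignment, the true origin is primary, and NH is
the hit count. Multi-mapping truth is therefore analytic, not
heuristic. Reads never span exon junctions (they are drawn within
blocks), which keeps CIGARs ungapped. PSM tables mix true matches
(peptides sampled from forward entries, scores from N(12, 2)) with
false matches and symmetric decoys (random peptides, N(4, 2)); the
configured false fraction (default 0.3) makes empirical FDP measurable.
Affinity and homology side tables straddle their filter boundaries with
truth recorded at generation time, and a 50-copy paralog family
differing at a single diagnostic residue reproduces the situation where
only peptides spanning that residue are UTPs.

What passing these tests does **not** show about real data: no
sequencing errors or soft-clipping (alignment is exact-match), no
junction-spanning reads, no 3-nt periodicity structure, no realistic
score distributions or retention-time features, genomes of tens of
kilobases rather than gigabases. The simulator validates the *logic* —
counting semantics, FDR calibration, coordinate arithmetic, boundary
behavior — not aligner or search-engine behavior.

## Numerical and design choices

* Coordinates: `GenomicRanges` 1-based closed throughout; GTF I/O is
  then the identity on coordinates.
* Translation uses the standard genetic code table; any codon
  containing N maps to X.
* q-value ties break by (score, then lexicographic id) for
  deterministic output; the +1 decoy correction keeps one-item lists at
  q = 1 rather than 0.
* pI bisection tolerance 1e-4 pH; tests require agreement with a
  0.001-step grid search within 0.01 pH.
* Problem sizes in the test suite (1,000 random transcripts up to
  10 kb, 1,000 spliced round-trip ORFs, 20 × 2,000 PSMs, 20 read-set
  seeds at 23–30 reads per ORF) were chosen as the smallest sizes at
  which the binomial noise of the measured proportions is well inside
  the asserted bounds.
* Known limitations: aiORF frame compatibility ignores splicing within
  the CDS; `gregexpr`-based read placement does not report
  self-overlapping periodic matches (irrelevant for random sequences);
  grouped FDR assigns a PSM to the group of its first mapped entry.
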