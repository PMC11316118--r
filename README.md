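# smorfkit

Proteogenomic discovery of small open reading frames (smORFs) and
classification of their ribosome-profiling coverage.

## The problem

smORFs (here ≤ 150 codons) encode microproteins that standard
annotation misses. Ribosome profiling should reveal their translation,
but its 25–34 nt ribosome-protected fragments (RPFs) multi-map across
duplicated loci — pseudogenes, retrotransposons, paralog families — and
land ambiguously under dense isoform nests, so read-counting tools
silently discard exactly the evidence those smORFs need. A
proteogenomics search against a three-frame-translated transcriptome
sidesteps this: a peptide-spectrum match to a unique tryptic peptide
(UTP) pins the microprotein to one database entry even when every
Ribo-Seq read at the locus is a multi-mapper. `smorfkit` implements
that workflow's computational stages for R:

* **seqdb** — splice transcripts from a genome FASTA + GTF, translate
  all three frames, and emit one ORF per inter-stop segment starting at
  the most upstream ATG; build the tagged search database
  (predicted + annotated + contaminants) with one reversed-sequence
  decoy per forward entry.
* **digest** — Keil-rule tryptic digestion, monoisotopic masses
  (residue sums + H₂O), isoelectric points by bisection on the
  Henderson–Hasselbalch net charge, amino-acid composition profiles,
  and UTP assignment by substring occurrence across the database.
* **psmfilter** — target–decoy q-values with the conservative
  FDR̂(s) = (1 + #decoys ≥ s)/(#targets ≥ s) estimator and
  running-minimum q-values; picked-protein competition (higher-scoring
  member of each target/decoy pair); grouped FDR; annotated-peptide
  removal; perfect-match exclusion; second-round re-scoring databases;
  HLA filters (affinity ≤ 100 nM, percentile ≤ 0.02, 7–12 aa) and the
  nonspecific 8–25 aa / 500–1500 Da peptide space.
* **ribocov** — read counting under four regimes (default, ambiguous
  `-O`, multi-mapping `-M`, both), RPKM, mapping-group assignment
  (≥ 10 raw counts to qualify; least-permissive qualifying regime
  wins), the multimapper-exclusive set, and the log₁₀(RPKM+1) heat-map
  matrix.
* **annotate** — precedence-ordered smORF classes
  (rtORF > aiORF > uORF > riORF > lncORF > noncoding > other-overlap),
  overlapping-feature counts, repeat residence, and conservation
  filtering (E-value < 0.001, bit score > 50).
* **simulate** — a seeded generator of genomes with paralog families
  and isoform nests, exact-match-placed RPF/RNA-seq alignments in SAM,
  PSM tables with a known false fraction, and boundary side tables —
  every fixture carries its ground truth.

See `vignettes/smorf-proteogenomics.Rmd` for the models, parameter
choices and limitations.

## Worked example

```r
library(smorfkit)

sim  <- make_genome(sim_config(seed = 7))        # 22 planted smORFs
pred <- predict_smorfs(sim$genome, sim$tx_models)
nrow(pred)
#> [1] 60                        # all 3-frame candidates, planted ones included
db <- build_custom_db(pred)
nrow(db); sum(db$category == "decoy")
#> [1] 92
#> [1] 46                        # one decoy per forward entry

psms <- make_psms(db, sim_config(seed = 7, n_psms = 2000,
                                 psm_false_fraction = 0.3))
q <- qvalues_target_decoy(psms$score, psms$is_decoy)
sum(!psms$is_decoy & q <= 0.01)
#> [1] 1382                      # identifications at 1% FDR ...
mean(!psms$is_true[!psms$is_decoy & q <= 0.01])
#> [1] 0.008                     # ... with empirical FDP 0.8%

reads <- make_reads(sim, "rpf")                  # 25-34 nt RPFs, exact placement
prof  <- coverage_profiles(reads, ribocov_features(sim))
grp   <- assign_mapping_group(prof)              # >= 10 raw counts per regime
table(grp$group[grp$smorf_id %in% sim$smorfs$orf_id])
#>     Amb Default      MM
#>       8       5       9
# 5 unique loci count under default settings; the 9 paralog copies are
# invisible without -M; 3 nest smORFs (plus class loci under reference
# transcripts) need -O.

cls <- classify_smorfs(sim$smorf_blocks,
                       as_reference_annotation(sim$annotation))
table(cls$label)
#>  aiORF lncORF noncoding other-overlap riORF rtORF uORF
#>      1      1        14             3     1     1    1
```

A command-line dispatcher wraps the same functions
(`exec/smorfkit database|digest|search-post|ribocov|annotate|simulate`),
e.g.

```sh
smorfkit simulate --seed 7 --out fixtures/
smorfkit database --genome fixtures/genome.fa --gtf fixtures/smorfs.gtf \
         --max-aa 150 --out db.fa
smorfkit ribocov  --sam fixtures/reads_rpf.sam --smorf-gtf fixtures/smorfs.gtf \
         --reference-gtf fixtures/reference.gtf --min-counts 10 --out-prefix cov
```

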