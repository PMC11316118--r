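Package: smorfkit
Title: Proteogenomic Discovery and Ribo-Seq Coverage Classification of
    Small Open Reading Frames
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for ribosome-profiling-assisted proteogenomics of
    small open reading frames (smORFs) and their microprotein products.
    Builds custom proteomics search databases by three-frame translation
    of assembled transcripts with ATG-priority ORF selection, appends
    tagged reference and contaminant entries and reversed-sequence
    decoys; performs in silico tryptic digestion with monoisotopic mass
    and isoelectric point calculation and unique-tryptic-peptide (UTP)
    assignment; filters peptide-spectrum matches with target-decoy,
    picked-protein and grouped q-values plus annotated-peptide removal,
    perfect-match exclusion, second-round re-scoring databases and HLA
    immunopeptidomics filters; classifies per-smORF Ribo-Seq coverage
    under four read-counting regimes (default, ambiguous, multi-mapping,
    both) with RPKM and mapping-group assignment; annotates smORFs by
    overlap with reference transcript models, repeats and homology hit
    tables; and ships a deterministic simulator that generates genomes
    with paralog families and isoform nests, ribosome-protected-fragment
    and RNA-seq alignments, and PSM tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
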