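#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-fixture generator. The
#' defaults define the study conditions the rest of the package is
#' exercised under: exact paralog copies (the retrotransposon /
#' pseudogene copy-paste regime that causes multi-mapping), isoform
#' nests of depth 3, ribosome-protected-fragment lengths of 25-34 nt
#' against 100 nt RNA-seq reads, 30 reads per planted ORF, and PSM
#' tables with a 30% false-match fraction.
#'
#' @param seed Integer seed; every derived fixture is a pure function of
#'   it.
#' @param n_paralog_families Number of duplicated-locus families.
#' @param copies_per_family Copies per family (>= 2 for multi-mapping).
#' @param divergence Per-site substitution probability between family
#'   copies (0 = exact duplicates).
#' @param n_unique_loci Number of single-copy intergenic smORF loci.
#' @param n_isoform_loci Number of isoform-nest loci.
#' @param isoform_depth Overlapping reference transcripts per nest.
#' @param rpf_len_range Ribosome-protected-fragment length range (nt).
#' @param rna_len RNA-seq read length (nt).
#' @param coverage Reads generated per planted ORF.
#' @param psm_false_fraction Fraction of target PSMs that are false.
#' @param n_psms Number of target PSMs in the simulated table.
#' @param orf_len_aa Range of planted ORF lengths (amino acids).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_paralog_families = 3L,
                       copies_per_family = 3L, divergence = 0,
                       n_unique_loci = 5L, n_isoform_loci = 3L,
                       isoform_depth = 3L, rpf_len_range = c(25L, 34L),
                       rna_len = 100L, coverage = 30L,
                       psm_false_fraction = 0.3, n_psms = 2000L,
                       orf_len_aa = c(30L, 45L)) {
  cfg <- list(seed = as.integer(seed),
              n_paralog_families = n_paralog_families,
              copies_per_family = copies_per_family,
              divergence = divergence, n_unique_loci = n_unique_loci,
              n_isoform_loci = n_isoform_loci,
              isoform_depth = isoform_depth,
              rpf_len_range = rpf_len_range, rna_len = rna_len,
              coverage = coverage, psm_false_fraction = psm_false_fraction,
              n_psms = n_psms, orf_len_aa = orf_len_aa)
  stopifnot(divergence >= 0, divergence <= 1,
            psm_false_fraction >= 0, psm_false_fraction <= 1,
            all(unlist(cfg[c("n_paralog_families", "copies_per_family",
                             "n_unique_loci", "n_isoform_loci",
                             "isoform_depth", "rna_len", "coverage",
                             "n_psms")]) >= 0))
  class(cfg) <- "sim_config"
  cfg
}

## Seed-scoped RNG evaluation: restores the caller's RNG state.
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

random_dna <- function(n, avoid_atg = FALSE) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    if (!avoid_atg || !grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

random_protein <- function(len_aa) {
  paste(c("M", sample(AA20, len_aa - 1L, replace = TRUE)), collapse = "")
}

## Encode a protein as an ORF nucleotide sequence (random synonymous
## codons) terminated by a random stop codon.
encode_orf <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  codons_for <- split(names(gc), unname(gc))
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  cods <- vapply(res, function(a) {
    cc <- codons_for[[a]]
    cc[sample.int(length(cc), 1L)]
  }, "", USE.NAMES = FALSE)
  cods[1L] <- "ATG"
  paste(c(cods, sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

mutate_dna <- function(seq, p) {
  if (p <= 0) return(seq)
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(res)) < p
  res[hit] <- vapply(res[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(res, collapse = "")
}

## Assemble one genomic cassette: utr5 | orf (optionally split by an
## intron) | utr3, in transcript-sense coordinates. Returns the sense
## sequence plus local coordinates of ORF blocks and host-transcript
## exons.
build_cassette <- function(utr5, orf_nt, utr3, intron = NULL) {
  u <- nchar(utr5); o <- nchar(orf_nt); v <- nchar(utr3)
  if (is.null(intron)) {
    seq <- paste0(utr5, orf_nt, utr3)
    list(seq = seq,
         orf_blocks = list(c(u + 1L, u + o)),
         exons = list(c(1L, u + o + v)),
         orf_tx = c(u + 1L, u + o))
  } else {
    i <- nchar(intron)
    split_nt <- 3L * (o %/% 6L)         # split inside the ORF, codon boundary
    seq <- paste0(utr5, substr(orf_nt, 1L, split_nt), intron,
                  substr(orf_nt, split_nt + 1L, o), utr3)
    list(seq = seq,
         orf_blocks = list(c(u + 1L, u + split_nt),
                           c(u + split_nt + i + 1L, u + i + o)),
         exons = list(c(1L, u + split_nt),
                      c(u + split_nt + i + 1L, u + i + o + v)),
         orf_tx = c(u + 1L, u + o))
  }
}

## Convert cassette-local sense coordinates to genomic, honoring strand.
local_to_genomic <- function(ivs, g0, total_len, strand) {
  out <- lapply(ivs, function(iv) {
    if (strand == "+") c(g0 + iv[1L] - 1L, g0 + iv[2L] - 1L)
    else c(g0 + total_len - iv[2L], g0 + total_len - iv[1L])
  })
  out[order(vapply(out, `[[`, 0, 1L))]
}

#' Simulate a genome with planted smORFs and reference annotation
#'
#' Generates one chromosome holding, in order: unique intergenic smORF
#' loci (expected mapping group `Default`), paralog families of
#' near-identical copies (`MM`), isoform nests where the smORF is
#' overlapped by several reference transcripts (`Amb`), and one locus
#' per annotation class (uORF, aiORF, rtORF, riORF, lncORF) with the
#' reference features that define it. Roughly half the planted smORFs
#' are spliced over one intron; a subset of loci are placed on the minus
#' strand. Output is byte-identical under the same seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome` ([Biostrings::DNAStringSet]),
#'   `annotation` (reference-feature [GenomicRanges::GRanges] with
#'   `type`, ids and `transcript_biotype`), `smorf_blocks` (named
#'   [GenomicRanges::GRangesList]), `tx_models` (host-transcript exon
#'   GRangesList), `smorfs` (truth data.frame: `orf_id`,
#'   `transcript_id`, `protein`, `strand`, `locus_type`, `family`,
#'   `expected_group`, `expected_class`, `spliced`) and `cfg`.
#' @export
make_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    chrom <- "chr1"
    parts <- list(random_dna(300L))
    cursor <- 301L
    # plain-vector accumulators; S4 containers are built once at the end
    sm <- list(orf_id = character(), transcript_id = character(),
               protein = character(), strand = character(),
               locus_type = character(), family = character(),
               expected_group = character(), expected_class = character(),
               spliced = logical())
    blk <- list(id = character(), start = integer(), end = integer(),
                strand = character())
    txe <- list(id = character(), start = integer(), end = integer(),
                strand = character())
    ann <- list(start = integer(), end = integer(), strand = character(),
                type = character(), gene_id = character(),
                transcript_id = character(), biotype = character())
    orf_counter <- 0L

    plant <- function(protein, strand, spliced, locus_type, family,
                      expected_group, expected_class, orf_nt = NULL) {
      utr5 <- random_dna(60L, avoid_atg = TRUE)
      # in-frame stop immediately upstream keeps the planted ATG the
      # most upstream start of its inter-stop segment
      substr(utr5, 58L, 60L) <- "TAA"
      utr3 <- random_dna(60L)
      if (is.null(orf_nt)) orf_nt <- encode_orf(protein)
      intron <- if (spliced) random_dna(42L) else NULL
      cass <- build_cassette(utr5, orf_nt, utr3, intron)
      L <- nchar(cass$seq)
      g0 <- cursor
      ins <- if (strand == "+") cass$seq else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cass$seq)))
      parts[[length(parts) + 1L]] <<- ins
      parts[[length(parts) + 1L]] <<- random_dna(250L)
      cursor <<- cursor + L + 250L
      ob <- local_to_genomic(cass$orf_blocks, g0, L, strand)
      ex <- local_to_genomic(cass$exons, g0, L, strand)
      orf_counter <<- orf_counter + 1L
      frame <- (nchar(utr5)) %% 3L
      orf_id <- sprintf("%s:%d-%d_%s_f%d", chrom, ob[[1L]][1L],
                        ob[[length(ob)]][2L], strand, frame)
      tx_id <- sprintf("simtx_%03d", orf_counter)
      blk$id <<- c(blk$id, rep.int(orf_id, length(ob)))
      blk$start <<- c(blk$start, vapply(ob, `[[`, 0, 1L))
      blk$end <<- c(blk$end, vapply(ob, `[[`, 0, 2L))
      blk$strand <<- c(blk$strand, rep.int(strand, length(ob)))
      txe$id <<- c(txe$id, rep.int(tx_id, length(ex)))
      txe$start <<- c(txe$start, vapply(ex, `[[`, 0, 1L))
      txe$end <<- c(txe$end, vapply(ex, `[[`, 0, 2L))
      txe$strand <<- c(txe$strand, rep.int(strand, length(ex)))
      sm$orf_id <<- c(sm$orf_id, orf_id)
      sm$transcript_id <<- c(sm$transcript_id, tx_id)
      sm$protein <<- c(sm$protein, protein)
      sm$strand <<- c(sm$strand, strand)
      sm$locus_type <<- c(sm$locus_type, locus_type)
      sm$family <<- c(sm$family, if (is.na(family)) NA_character_ else family)
      sm$expected_group <<- c(sm$expected_group, expected_group)
      sm$expected_class <<- c(sm$expected_class, expected_class)
      sm$spliced <<- c(sm$spliced, spliced)
      list(orf_id = orf_id, tx_id = tx_id,
           span = c(min(vapply(ex, `[[`, 0, 1L)),
                    max(vapply(ex, `[[`, 0, 2L))),
           orf_span = c(ob[[1L]][1L], ob[[length(ob)]][2L]))
    }

    add_tx_feature <- function(gene_id, tx_id, start, end, strand, biotype,
                               type = "transcript") {
      ann$start <<- c(ann$start, as.integer(start))
      ann$end <<- c(ann$end, as.integer(end))
      ann$strand <<- c(ann$strand, strand)
      ann$type <<- c(ann$type, type)
      ann$gene_id <<- c(ann$gene_id, gene_id)
      ann$transcript_id <<- c(ann$transcript_id, tx_id)
      ann$biotype <<- c(ann$biotype, biotype)
    }

    # --- unique intergenic loci -> Default / noncoding
    for (i in seq_len(cfg$n_unique_loci)) {
      strand <- if (i %% 4L == 0L) "-" else "+"
      plant(random_protein(sample(cfg$orf_len_aa[1L]:cfg$orf_len_aa[2L], 1L)),
            strand, spliced = i %% 2L == 0L, locus_type = "unique",
            family = NA, expected_group = "Default",
            expected_class = "noncoding")
    }

    # --- paralog families -> MM (exact copies when divergence = 0)
    for (f in seq_len(cfg$n_paralog_families)) {
      prot <- random_protein(
        sample(cfg$orf_len_aa[1L]:cfg$orf_len_aa[2L], 1L))
      base_nt <- encode_orf(prot)
      for (k in seq_len(cfg$copies_per_family)) {
        nt <- if (k == 1L) base_nt else mutate_dna(base_nt, cfg$divergence)
        grp <- if (cfg$divergence == 0 && cfg$copies_per_family >= 2L)
          "MM" else NA_character_
        plant(prot, "+", spliced = FALSE, locus_type = "paralog",
              family = sprintf("fam%02d", f), expected_group = grp,
              expected_class = "noncoding", orf_nt = nt)
      }
    }

    # --- isoform nests -> Amb
    for (i in seq_len(cfg$n_isoform_loci)) {
      info <- plant(random_protein(
        sample(cfg$orf_len_aa[1L]:cfg$orf_len_aa[2L], 1L)),
        "+", spliced = FALSE, locus_type = "isoform_nest", family = NA,
        expected_group = "Amb", expected_class = "other-overlap")
      for (j in seq_len(cfg$isoform_depth))
        add_tx_feature(sprintf("nest%02d", i),
                       sprintf("nest%02d_iso%d", i, j),
                       max(1L, info$span[1L] - 20L * j),
                       info$span[2L] + 15L * j, "+", "protein_coding")
    }

    # --- one locus per annotation class
    # uORF: smORF inside the 5' UTR of a coding transcript
    info <- plant(random_protein(18L), "+", spliced = FALSE,
                  locus_type = "class_uORF", family = NA,
                  expected_group = NA_character_, expected_class = "uORF")
    utr_end <- info$orf_span[2L] + 10L
    cds_start <- utr_end + 1L
    add_tx_feature("guorf", "guorf_t1", info$span[1L] - 10L,
                   cds_start + 200L, "+", "protein_coding")
    add_tx_feature("guorf", "guorf_t1", info$span[1L] - 10L, utr_end, "+",
                   "protein_coding", type = "five_prime_utr")
    add_tx_feature("guorf", "guorf_t1", cds_start, cds_start + 149L, "+",
                   "protein_coding", type = "CDS")

    # aiORF: smORF overlapping a CDS in frame (alternative initiation)
    info <- plant(random_protein(30L), "+", spliced = FALSE,
                  locus_type = "class_aiORF", family = NA,
                  expected_group = NA_character_, expected_class = "aiORF")
    cds_start <- info$orf_span[1L] + 9L          # in frame with the smORF
    add_tx_feature("gai", "gai_t1", info$span[1L] - 5L, cds_start + 299L,
                   "+", "protein_coding")
    add_tx_feature("gai", "gai_t1", cds_start, cds_start + 149L, "+",
                   "protein_coding", type = "CDS")

    # rtORF: smORF on a pseudogene locus
    info <- plant(random_protein(25L), "+", spliced = FALSE,
                  locus_type = "class_rtORF", family = NA,
                  expected_group = NA_character_, expected_class = "rtORF")
    add_tx_feature("grt", "grt_t1", info$span[1L] - 5L, info$span[2L] + 5L,
                   "+", "processed_pseudogene")

    # riORF: smORF within a retained-intron transcript
    info <- plant(random_protein(25L), "+", spliced = FALSE,
                  locus_type = "class_riORF", family = NA,
                  expected_group = NA_character_, expected_class = "riORF")
    add_tx_feature("gri", "gri_t1", info$span[1L] - 5L, info$span[2L] + 5L,
                   "+", "retained_intron")

    # lncORF: smORF within a lncRNA transcript (minus strand)
    info <- plant(random_protein(25L), "-", spliced = FALSE,
                  locus_type = "class_lncORF", family = NA,
                  expected_group = NA_character_, expected_class = "lncORF")
    add_tx_feature("glnc", "glnc_t1", info$span[1L] - 5L,
                   info$span[2L] + 5L, "-", "lncRNA")

    genome <- Biostrings::DNAStringSet(
      setNames(paste(unlist(parts), collapse = ""), chrom))
    smorfs <- data.frame(sm, stringsAsFactors = FALSE)
    annotation <- GenomicRanges::GRanges(
      rep.int(chrom, length(ann$start)),
      IRanges::IRanges(ann$start, ann$end), ann$strand,
      type = ann$type, gene_id = ann$gene_id,
      transcript_id = ann$transcript_id,
      transcript_biotype = ann$biotype,
      phase = ifelse(ann$type == "CDS", 0L, NA_integer_))
    blk_gr <- GenomicRanges::GRanges(
      rep.int(chrom, length(blk$start)),
      IRanges::IRanges(blk$start, blk$end), blk$strand)
    smorf_blocks <- GenomicRanges::split(
      blk_gr, factor(blk$id, levels = unique(blk$id)))
    txe_gr <- GenomicRanges::GRanges(
      rep.int(chrom, length(txe$start)),
      IRanges::IRanges(txe$start, txe$end), txe$strand)
    tx_models <- GenomicRanges::split(
      txe_gr, factor(txe$id, levels = unique(txe$id)))
    list(genome = genome, annotation = annotation,
         smorf_blocks = smorf_blocks, tx_models = tx_models,
         smorfs = smorfs, cfg = cfg)
  })
}

revcomp_str <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) intToUtf8(rev(utf8ToInt(x))), "",
                USE.NAMES = FALSE))
}

## All exact genomic matches of a read sequence, both strands. Works on
## plain character strings (named vector of chromosome sequences) so the
## per-read cost stays at C string-search level.
exact_matches <- function(read_seq, genome_chars) {
  chroms <- character(0); starts <- integer(0); strands <- character(0)
  rc <- revcomp_str(read_seq)
  w <- nchar(read_seq)
  for (chrom in names(genome_chars)) {
    f <- gregexpr(read_seq, genome_chars[[chrom]], fixed = TRUE)[[1L]]
    if (f[1L] != -1L) {
      chroms <- c(chroms, rep.int(chrom, length(f)))
      starts <- c(starts, as.integer(f))
      strands <- c(strands, rep.int("+", length(f)))
    }
    r <- gregexpr(rc, genome_chars[[chrom]], fixed = TRUE)[[1L]]
    if (r[1L] != -1L) {
      chroms <- c(chroms, rep.int(chrom, length(r)))
      starts <- c(starts, as.integer(r))
      strands <- c(strands, rep.int("-", length(r)))
    }
  }
  data.frame(chrom = chroms, start = starts, end = starts + w - 1L,
             strand = strands, stringsAsFactors = FALSE)
}

#' Simulate ribosome-protected-fragment or RNA-seq alignments
#'
#' Draws reads uniformly along the planted ORF blocks (RPF mode, 25-34
#' nt by default, strand-matched to the ORF) or along the host
#' transcript exons (RNA mode, 100 nt by default, both strands), then
#' places each read by exact matching against the whole genome: every
#' exact hit is reported as an alignment, the hit at the true origin is
#' flagged primary, and `n_hits` counts all reported alignments — so
#' multi-mapping truth is analytic, not heuristic.
#'
#' @param sim Output of [make_genome()].
#' @param type `"rpf"` or `"rna"`.
#' @param coverage Reads per planted ORF (default `cfg$coverage`).
#' @param seed RNG seed (default derived from `cfg$seed`).
#' @return A data.frame compatible with [read_alignments()] (columns
#'   `read_id`, `chrom`, `strand`, `is_secondary`, `n_hits`, list-column
#'   `blocks`) plus `seq`, `start`, `origin_smorf`. Pass it to
#'   [write_sam()] or straight to [count_reads()].
#' @export
make_reads <- function(sim, type = c("rpf", "rna"), coverage = NULL,
                       seed = NULL) {
  type <- match.arg(type)
  cfg <- sim$cfg
  if (is.null(coverage)) coverage <- cfg$coverage
  if (is.null(seed)) seed <- cfg$seed + if (type == "rpf") 1L else 2L
  genome_chars <- setNames(as.character(sim$genome), names(sim$genome))
  with_sim_seed(seed, {
    acc <- list(read_id = character(), chrom = character(),
                start = integer(), strand = character(),
                is_secondary = logical(), n_hits = integer(),
                seq = character(), origin_smorf = character())
    rid <- 0L
    for (i in seq_len(nrow(sim$smorfs))) {
      orf_id <- sim$smorfs$orf_id[i]
      strand <- sim$smorfs$strand[i]
      src <- if (type == "rpf") sim$smorf_blocks[[orf_id]] else
        sim$tx_models[[sim$smorfs$transcript_id[i]]]
      bw <- GenomicRanges::width(src)
      bs <- GenomicRanges::start(src)
      bchrom <- as.character(GenomicRanges::seqnames(src))
      for (r in seq_len(coverage)) {
        len <- if (type == "rpf")
          sample(cfg$rpf_len_range[1L]:cfg$rpf_len_range[2L], 1L) else
            cfg$rna_len
        fit <- which(bw >= len)
        if (length(fit) == 0L) next
        b <- fit[sample.int(length(fit), 1L)]
        pos <- bs[b] + sample.int(bw[b] - len + 1L, 1L) - 1L
        chrom <- bchrom[b]
        gseq <- substr(genome_chars[[chrom]], pos, pos + len - 1L)
        read_strand <- if (type == "rna" && runif(1) < 0.5)
          setdiff(c("+", "-"), strand) else strand
        read_seq <- if (read_strand == "+") gseq else revcomp_str(gseq)
        hits <- exact_matches(read_seq, genome_chars)
        is_origin <- hits$chrom == chrom & hits$start == pos &
          hits$strand == read_strand
        if (!any(is_origin)) stop("internal: origin placement not found")
        ord <- order(!is_origin, hits$start)
        hits <- hits[ord, , drop = FALSE]
        rid <- rid + 1L
        nh <- nrow(hits)
        acc$read_id <- c(acc$read_id,
                         rep.int(sprintf("%s_r%05d", type, rid), nh))
        acc$chrom <- c(acc$chrom, hits$chrom)
        acc$start <- c(acc$start, hits$start)
        acc$strand <- c(acc$strand, hits$strand)
        acc$is_secondary <- c(acc$is_secondary,
                              c(FALSE, rep(TRUE, nh - 1L)))
        acc$n_hits <- c(acc$n_hits, rep.int(nh, nh))
        acc$seq <- c(acc$seq, rep.int(read_seq, nh))
        acc$origin_smorf <- c(acc$origin_smorf, rep.int(orf_id, nh))
      }
    }
    aln <- data.frame(acc, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(
      aln$chrom, IRanges::IRanges(aln$start, width = nchar(aln$seq)),
      aln$strand)
    aln$blocks <- IRanges::relist(
      gr, IRanges::PartitioningByEnd(seq_along(gr)))
    aln
  })
}

#' Write simulated alignments as SAM text
#'
#' Emits a valid SAM file (header with `@SQ` lines; flag 0x10 for the
#' minus strand, 0x100 for secondary alignments; ungapped `M` CIGARs;
#' `NH` tags). The stored SEQ is the forward-genome-strand sequence, as
#' the SAM convention requires.
#'
#' @param reads Data.frame from [make_reads()].
#' @param genome The simulated genome ([Biostrings::DNAStringSet]).
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  len <- nchar(reads$seq)
  seq_fwd <- ifelse(reads$strand == "+", reads$seq,
                    vapply(reads$seq, function(s)
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(s))), "", USE.NAMES = FALSE))
  flag <- ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$is_secondary, 256L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                   reads$read_id, flag, reads$chrom, reads$start,
                   ifelse(reads$n_hits > 1L, 0L, 60L), len, seq_fwd,
                   reads$n_hits)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Simulate a PSM table with known false-match structure
#'
#' True target PSMs draw real (sub)peptides from forward predicted or
#' annotated entries with scores from a high-mean normal; false target
#' PSMs pair random peptide sequences with random forward entries and
#' draw scores from a low-mean normal; decoy PSMs are generated
#' symmetrically to the false targets against decoy entries. The
#' fraction of target PSMs that are false is `cfg$psm_false_fraction`.
#'
#' @param db Database data.frame from [build_custom_db()].
#' @param cfg A [sim_config()].
#' @param seed RNG seed (default `cfg$seed + 3`).
#' @param score_true,score_false `c(mean, sd)` of the score
#'   distributions.
#' @return A data.frame in the pin-style layout of [read_psm_table()]
#'   (with `protein_ids` and `is_decoy` precomputed) plus a logical
#'   truth column `is_true` (`NA` for decoy rows).
#' @export
make_psms <- function(db, cfg = sim_config(), seed = NULL,
                      score_true = c(12, 2), score_false = c(4, 2)) {
  if (is.null(seed)) seed <- cfg$seed + 3L
  fwd <- db[db$category %in% c("predicted", "annotated"), , drop = FALSE]
  dec <- db[db$category == "decoy", , drop = FALSE]
  stopifnot(nrow(fwd) > 0L, nrow(dec) > 0L)
  with_sim_seed(seed, {
    n_false <- round(cfg$n_psms * cfg$psm_false_fraction)
    n_true <- cfg$n_psms - n_false
    sample_subpep <- function(protein) {
      len <- min(nchar(protein), sample(8:12, 1L))
      s <- sample.int(nchar(protein) - len + 1L, 1L)
      substr(protein, s, s + len - 1L)
    }
    random_pep <- function() {
      repeat {
        p <- paste(sample(AA20, sample(8:12, 1L), replace = TRUE),
                   collapse = "")
        if (!any(grepl(p, fwd$protein, fixed = TRUE))) return(p)
      }
    }
    true_idx <- sample.int(nrow(fwd), n_true, replace = TRUE)
    true_pep <- vapply(fwd$protein[true_idx], sample_subpep, "",
                       USE.NAMES = FALSE)
    true_prot <- vapply(true_pep, function(p)
      paste(fwd$entry_id[grepl(p, fwd$protein, fixed = TRUE)],
            collapse = ";"), "", USE.NAMES = FALSE)
    false_pep <- vapply(seq_len(n_false), function(i) random_pep(), "")
    false_prot <- fwd$entry_id[sample.int(nrow(fwd), n_false,
                                          replace = TRUE)]
    dec_pep <- vapply(seq_len(n_false), function(i) random_pep(), "")
    dec_prot <- dec$entry_id[sample.int(nrow(dec), n_false,
                                        replace = TRUE)]
    tab <- data.frame(
      spectrum_id = sprintf("spec_%06d", seq_len(n_true + 2L * n_false)),
      peptide = c(true_pep, false_pep, dec_pep),
      charge = sample(2:3, n_true + 2L * n_false, replace = TRUE),
      score = c(rnorm(n_true, score_true[1L], score_true[2L]),
                rnorm(2L * n_false, score_false[1L], score_false[2L])),
      proteins = c(true_prot, false_prot, dec_prot),
      label = rep(c(1L, 1L, -1L), c(n_true, n_false, n_false)),
      is_true = c(rep(TRUE, n_true), rep(FALSE, n_false),
                  rep(NA, n_false)),
      stringsAsFactors = FALSE)
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    tab$protein_ids <- strsplit(tab$proteins, ";", fixed = TRUE)
    tab$is_decoy <- tab$label == -1L
    tab
  })
}

#' Simulate affinity, homology and repeat side tables
#'
#' The affinity table straddles the HLA filter boundaries (100 nM, 0.02
#' percentile, 7-12 aa) and the homology table the conservation
#' thresholds (E-value 1e-3, bit score 50), each with fixed boundary
#' rows plus random rows; both carry an `expected_keep` truth column
#' evaluated from the stated rule at generation time. The repeats BED
#' intervals cover the paralog-family smORFs and one intergenic decoy
#' interval.
#'
#' @param sim Output of [make_genome()].
#' @param n_random Random rows per table in addition to the fixed
#'   boundary rows.
#' @param seed RNG seed (default `cfg$seed + 4`).
#' @return A list with `affinity` (data.frame), `homology` (data.frame),
#'   `repeats` ([GenomicRanges::GRanges]) and `repeat_truth` (ids of
#'   covered smORFs).
#' @export
make_side_tables <- function(sim, n_random = 50L, seed = NULL) {
  cfg <- sim$cfg
  if (is.null(seed)) seed <- cfg$seed + 4L
  with_sim_seed(seed, {
    rand_pep <- function(len) paste(sample(AA20, len, replace = TRUE),
                                    collapse = "")
    fixed_aff <- data.frame(
      affinity = c(100, 99, 100, 50, 101, 100, 100.1),
      percentile = c(0.02, 0.01, 0.02, 0.01, 0.02, 0.02, 0.02),
      len = c(12L, 9L, 7L, 13L, 9L, 6L, 9L))
    rand_aff <- data.frame(
      affinity = round(runif(n_random, 0, 200), 2),
      percentile = round(runif(n_random, 0, 0.04), 4),
      len = sample(6:14, n_random, replace = TRUE))
    aff <- rbind(fixed_aff, rand_aff)
    affinity <- data.frame(
      sequence = vapply(aff$len, rand_pep, ""),
      affinity = aff$affinity, percentile = aff$percentile,
      expected_keep = aff$affinity <= 100 & aff$percentile <= 0.02 &
        aff$len >= 7L & aff$len <= 12L,
      stringsAsFactors = FALSE)

    species <- c("Homo_sapiens", "Rattus_norvegicus", "Danio_rerio",
                 "Drosophila_melanogaster")
    ids <- sim$smorfs$orf_id
    fixed_hom <- data.frame(
      e_value = c(0.01, 1e-5, 1e-5, 0.001, 0.0009, 1e-8),
      bit_score = c(60, 49, 50, 80, 51, 120))
    rand_hom <- data.frame(
      e_value = 10^runif(n_random, -8, 0),
      bit_score = round(runif(n_random, 20, 120), 1))
    hom <- rbind(fixed_hom, rand_hom)
    homology <- data.frame(
      smorf_id = sample(ids, nrow(hom), replace = TRUE),
      species = sample(species, nrow(hom), replace = TRUE),
      e_value = hom$e_value, bit_score = hom$bit_score,
      expected_keep = hom$e_value < 1e-3 & hom$bit_score > 50,
      stringsAsFactors = FALSE)

    par_ids <- sim$smorfs$orf_id[sim$smorfs$locus_type == "paralog"]
    cov <- unlist(GenomicRanges::GRangesList(
      as.list(sim$smorf_blocks[par_ids])), use.names = FALSE)
    cov <- GenomicRanges::reduce(cov, ignore.strand = TRUE)
    decoy_iv <- GenomicRanges::GRanges(
      names(sim$genome)[1L], IRanges::IRanges(1L, 50L), "*")
    repeats <- c(GenomicRanges::granges(cov), decoy_iv)
    repeats$name <- c(sprintf("SimRepeat_%d", seq_along(cov)),
                      "SimRepeat_decoy")
    list(affinity = affinity, homology = homology, repeats = repeats,
         repeat_truth = par_ids)
  })
}

#' Simulate a paralog family distinguished by one diagnostic residue
#'
#' Builds a microprotein and `n_copies - 1` homologs that are identical
#' to it except at a single diagnostic position, where the microprotein
#' carries a private residue — the situation in which only tryptic
#' peptides spanning that position are unique tryptic peptides. The
#' protein is built from fixed-length tryptic blocks (K-terminated) so
#' peptides are well formed.
#'
#' @param n_copies Family size (target + homologs).
#' @param n_blocks Number of 9-residue tryptic blocks in the protein.
#' @param seed RNG seed.
#' @return A list with `target` (named sequence), `homologs` (named
#'   character), `diag_pos` (1-based residue position), `db`
#'   ([build_custom_db()] over the family) and `expected_utps` (the
#'   target's tryptic peptides covering `diag_pos`).
#' @export
make_utp_family <- function(n_copies = 50L, n_blocks = 4L, seed = 1L) {
  with_sim_seed(seed, {
    block <- function() paste(c("M", sample(setdiff(AA20, c("K", "R", "P", "M")),
                                            7L, replace = TRUE), "K"),
                              collapse = "")
    base <- paste(vapply(seq_len(n_blocks), function(i) block(), ""),
                  collapse = "")
    base <- paste0("M", substr(base, 2L, nchar(base)))
    diag_pos <- 9L * (n_blocks %/% 2L) + 5L   # middle of a block
    base_res <- substr(base, diag_pos, diag_pos)
    private <- sample(setdiff(AA20, c(base_res, "K", "R", "P")), 1L)
    target <- base
    substr(target, diag_pos, diag_pos) <- private
    homologs <- setNames(rep(base, n_copies - 1L),
                         sprintf("homolog_%02d", seq_len(n_copies - 1L)))
    db <- build_custom_db(c(target_smorf = target), homologs)
    peps <- digest_trypsin(target, "target_smorf",
                           compute_properties = FALSE)
    covers <- peps$start <= diag_pos &
      peps$start + nchar(peps$sequence) - 1L >= diag_pos
    list(target = c(target_smorf = target), homologs = homologs,
         diag_pos = diag_pos, db = db,
         expected_utps = peps$sequence[covers])
  })
}

#' Combined feature set for read counting
#'
#' The coverage analysis counts reads against the reference annotation
#' with the smORF coordinates appended: this helper builds that feature
#' set from a simulation (smORF blocks plus one range per reference
#' transcript).
#'
#' @param sim Output of [make_genome()].
#' @return A named [GenomicRanges::GRangesList] usable as the `features`
#'   argument of [count_reads()] / [coverage_profiles()].
#' @export
ribocov_features <- function(sim) {
  feats <- as.list(sim$smorf_blocks)
  tx <- sim$annotation[sim$annotation$type == "transcript"]
  if (length(tx)) {
    tx_feats <- lapply(seq_along(tx), function(i)
      GenomicRanges::granges(tx[i]))
    names(tx_feats) <- tx$transcript_id
    feats <- c(feats, tx_feats[!duplicated(names(tx_feats))])
  }
  GenomicRanges::GRangesList(feats)
}

#' Write all simulated fixtures to disk
#'
#' Writes genome FASTA, reference and smORF GTFs, RPF and RNA SAM files,
#' PSM/affinity/homology TSVs, repeats BED and the truth table, all as
#' plain text.
#'
#' @param sim Output of [make_genome()].
#' @param dir Output directory (created if needed).
#' @param reads_rpf,reads_rna Optional precomputed read sets (defaults
#'   regenerate from `sim`).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(sim, dir, reads_rpf = NULL, reads_rna = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  rtracklayer::export(sim$annotation, p("reference.gtf"), format = "gtf")
  orfs <- data.frame(orf_id = sim$smorfs$orf_id, stringsAsFactors = FALSE)
  orfs$blocks <- as.list(sim$smorf_blocks[sim$smorfs$orf_id])
  write_smorf_gtf(orfs, p("smorfs.gtf"))
  if (is.null(reads_rpf)) reads_rpf <- make_reads(sim, "rpf")
  if (is.null(reads_rna)) reads_rna <- make_reads(sim, "rna")
  write_sam(reads_rpf, sim$genome, p("reads_rpf.sam"))
  write_sam(reads_rna, sim$genome, p("reads_rna.sam"))
  db <- build_custom_db(setNames(sim$smorfs$protein, sim$smorfs$orf_id))
  write_db_fasta(db, p("db.fa"))
  psms <- make_psms(db, sim$cfg)
  write.table(psms[, c("spectrum_id", "peptide", "charge", "score",
                       "proteins", "label", "is_true")],
              p("psms.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  side <- make_side_tables(sim)
  write.table(side$affinity, p("affinity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(side$homology, p("homology.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rtracklayer::export(side$repeats, p("repeats.bed"), format = "bed")
  write.table(sim$smorfs, p("truth_smorfs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(genome = p("genome.fa"), reference = p("reference.gtf"),
             smorfs = p("smorfs.gtf"), rpf = p("reads_rpf.sam"),
             rna = p("reads_rna.sam"), db = p("db.fa"),
             psms = p("psms.tsv"), affinity = p("affinity.tsv"),
             homology = p("homology.tsv"), repeats = p("repeats.bed"),
             truth = p("truth_smorfs.tsv"))
  invisible(paths)
}
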