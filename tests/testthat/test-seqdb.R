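test_that("spliced sequence extraction honors exon order and strand", {
  genome <- Biostrings::DNAStringSet(c(chrA = "ATGCCCAAA"))
  plus <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 6), "+")
  expect_identical(extract_transcript_sequence(plus, genome), "ATGCCC")
  minus <- GenomicRanges::GRanges("chrA",
                                  IRanges::IRanges(c(1, 7), c(3, 9)), "-")
  expect_identical(extract_transcript_sequence(minus, genome), "TTTCAT")
  bad_chrom <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 3), "+")
  expect_error(extract_transcript_sequence(bad_chrom, genome),
               "unknown chromosome")
  oob <- GenomicRanges::GRanges("chrA", IRanges::IRanges(5, 50), "+")
  expect_error(extract_transcript_sequence(oob, genome), "bounds")
})

test_that("ORF extraction picks the most upstream ATG per segment", {
  o <- three_frame_orfs("ATGAAATAA")
  expect_identical(o$protein[o$frame == 0], "MK")
  # two in-frame ATGs between the same stops: upstream one wins
  o <- three_frame_orfs("ATGGCCATGAAATAA")
  expect_identical(o$protein[o$frame == 0], "MAMK")
  # one ORF per inter-stop segment
  o <- three_frame_orfs("TTTATGAAATAGATGCCCTAA")
  expect_identical(o$protein[o$frame == 0], c("MK", "MP"))
  expect_identical(o$tx_start[o$frame == 0], c(4L, 13L))
})

test_that("ORF extraction enforces length cap, ATG rule and X policy", {
  long <- paste0("ATG", strrep("GCC", 10), "TAA")
  expect_identical(nrow(three_frame_orfs(long, max_aa = 5L)[
    three_frame_orfs(long, max_aa = 5L)$frame == 0, ]), 0L)
  # segment without ATG yields nothing unless require_atg = FALSE
  noatg <- "TTTAAACCCTAA"
  expect_false(any(three_frame_orfs(noatg)$frame == 0))
  relaxed <- three_frame_orfs(noatg, require_atg = FALSE)
  expect_identical(relaxed$protein[relaxed$frame == 0], "FKP")
  expect_false(relaxed$started_at_atg[relaxed$frame == 0])
  # truncated ORF (no closing stop) is kept and flagged
  trunc <- three_frame_orfs("ATGAAACCC")
  expect_false(trunc$has_stop[trunc$frame == 0])
  expect_identical(trunc$protein[trunc$frame == 0], "MKP")
  # N codon translates to X, at most one X tolerated by default
  one_x <- three_frame_orfs("ATGNNNAAATAA")
  expect_identical(one_x$protein[one_x$frame == 0], "MXK")
  two_x <- three_frame_orfs("ATGNNNNNNTAA")
  expect_false(any(two_x$frame == 0))
  strict <- three_frame_orfs("ATGNNNAAATAA", x_policy = "drop")
  expect_false(any(strict$frame == 0))
})

test_that("ORF extraction matches the brute-force scanner on random sequences", {
  set.seed(42)
  for (i in 1:60) {
    seq <- random_dna_str(sample(100:3000, 1))
    got <- three_frame_orfs(seq)
    got <- got[order(got$frame, got$tx_start),
               c("frame", "tx_start", "tx_end", "protein", "has_stop")]
    rownames(got) <- NULL
    exp <- oracle_orfs(seq)
    rownames(exp) <- NULL
    expect_identical(got, exp, info = paste("seq", i))
  }
})

test_that("no emitted protein contains a stop and ATG ORFs start with M", {
  set.seed(7)
  for (i in 1:20) {
    o <- three_frame_orfs(random_dna_str(1500))
    expect_false(any(grepl("*", o$protein, fixed = TRUE)))
    expect_true(all(substr(o$protein[o$started_at_atg], 1, 1) == "M"))
  }
})

test_that("transcript intervals project to genomic blocks conserving length", {
  exons <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(101, 301), c(150, 340)),
                                  "+")
  one <- map_orf_to_genome(exons, 5, 20)
  expect_identical(length(one), 1L)
  expect_identical(GenomicRanges::start(one), 105L)
  expect_identical(GenomicRanges::end(one), 120L)
  spanning <- map_orf_to_genome(exons, 45, 60)
  expect_identical(length(spanning), 2L)
  expect_identical(sum(GenomicRanges::width(spanning)), 16L)
  expect_identical(GenomicRanges::start(spanning), c(145L, 301L))
  expect_error(map_orf_to_genome(exons, 80, 120), "outside")

  # minus strand: transcript coordinates run against the genome
  minus <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(101, 301), c(150, 340)),
                                  "-")
  b <- map_orf_to_genome(minus, 1, 10)   # 5' end = end of last exon
  expect_identical(GenomicRanges::start(b), 331L)
  expect_identical(GenomicRanges::end(b), 340L)
  junction <- map_orf_to_genome(minus, 35, 45)
  expect_identical(sum(GenomicRanges::width(junction)), 11L)
})

test_that("mapped ORF blocks extract and translate back to the planted protein", {
  sim <- make_genome(sim_config(seed = 11, n_unique_loci = 20,
                                n_paralog_families = 1,
                                n_isoform_loci = 1))
  for (i in seq_len(nrow(sim$smorfs))) {
    blocks <- sim$smorf_blocks[[sim$smorfs$orf_id[i]]]
    nt <- extract_transcript_sequence(blocks, sim$genome)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    expect_identical(sub("\\*$", "", aa), sim$smorfs$protein[i])
  }
})

test_that("planted ORFs are rediscovered by prediction on host transcripts", {
  sim <- make_genome(sim_config(seed = 3, n_unique_loci = 6,
                                n_paralog_families = 1, n_isoform_loci = 1))
  pred <- predict_smorfs(sim$genome, sim$tx_models)
  expect_true(all(sim$smorfs$protein %in% pred$protein))
  # planted ids match the prediction's genomic footprint ids
  expect_true(all(sim$smorfs$orf_id %in% pred$orf_id))
})

test_that("custom database construction tags, orders, dedups and decoys", {
  db <- build_custom_db(c(p1 = "MKLV", p2 = "MAAA", p3 = "MKLV"),
                        c(a1 = "MKWWW", a2 = "MPPP"), c(c1 = "MCCC"))
  # 3 predicted dedup to 2 + 2 annotated + 1 contaminant = 5 forward + 5 decoys
  expect_identical(nrow(db), 10L)
  expect_identical(sum(db$category == "decoy"), 5L)
  expect_identical(db$category[1:5],
                   c("predicted", "predicted", "annotated", "annotated",
                     "contaminant"))
  expect_identical(db$orf_ids[db$entry_id == "p1"], "p1;p3")
  expect_identical(db$protein[db$entry_id == "rev_p1"], "VLKM")
  # reversing a decoy recovers its source
  for (i in which(db$category == "decoy")) {
    src <- db$protein[db$entry_id == db$source_id[i]]
    expect_identical(paste(rev(strsplit(db$protein[i], "")[[1]]),
                           collapse = ""), src)
  }
  expect_error(build_custom_db(c(x = "MK"), c(x = "MR")), "duplicate")
  # simple count contract without dedup collisions
  db2 <- build_custom_db(c(q1 = "MA", q2 = "MC", q3 = "MD"),
                         c(r1 = "ME", r2 = "MF"), c(s1 = "MG"))
  expect_identical(nrow(db2), 12L)
})

test_that("database FASTA round-trips entries, categories and provenance", {
  db <- build_custom_db(c(p1 = "MKLV", p3 = "MKLV", p2 = "MAAA"),
                        c(a1 = "MKWWW"), c(c1 = "MCCC"))
  path <- tempfile(fileext = ".fa")
  write_db_fasta(db, path)
  back <- read_db_fasta(path)
  expect_identical(back$entry_id, db$entry_id)
  expect_identical(back$protein, db$protein)
  expect_identical(back$category, db$category)
  expect_identical(back$source_id, db$source_id)
  expect_identical(back$orf_ids, db$orf_ids)
})

test_that("smORF GTF writing yields transcript+exon lines and round-trips", {
  blocks <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(11, 61), c(40, 90)),
                                   "-")
  orfs <- data.frame(orf_id = "chr1:11-90_-_f0", stringsAsFactors = FALSE)
  orfs$blocks <- list(blocks)
  path <- tempfile(fileext = ".gtf")
  write_smorf_gtf(orfs, path)
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  expect_identical(length(lines), 3L)  # 1 transcript + 2 exons
  back <- read_smorf_gtf(path)
  expect_identical(names(back), "chr1:11-90_-_f0")
  expect_identical(GenomicRanges::start(back[[1]]), c(11L, 61L))
  expect_identical(GenomicRanges::end(back[[1]]), c(40L, 90L))
  expect_identical(as.character(GenomicRanges::strand(back[[1]])),
                   c("-", "-"))
  # empty set still writes a parseable (header-only) file
  empty <- data.frame(orf_id = character(), stringsAsFactors = FALSE)
  empty$blocks <- list()
  p2 <- tempfile(fileext = ".gtf")
  write_smorf_gtf(empty, p2)
  expect_true(file.exists(p2))
})
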