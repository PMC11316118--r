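#' Read a genome FASTA into a DNAStringSet
#'
#' Sequence names are truncated at the first whitespace. The alphabet is
#' restricted to A, C, G, T and N: other IUPAC ambiguity codes are either
#' collapsed to N or rejected.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @param iupac How to treat non-ACGTN IUPAC codes: `"to_n"` replaces them
#'   with N, `"error"` aborts.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path, iupac = c("to_n", "error")) {
  iupac <- match.arg(iupac)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (any(Biostrings::width(genome) == 0L))
    stop("empty sequence in genome FASTA: ", path)
  freq <- Biostrings::alphabetFrequency(genome)
  other <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(other > 0L)) {
    if (iupac == "error")
      stop("genome contains IUPAC codes outside {A,C,G,T,N}")
    raw <- as.character(genome)
    raw <- gsub("[^ACGTN]", "N", raw)
    genome <- Biostrings::DNAStringSet(setNames(raw, names(genome)))
  }
  genome
}

#' Read transcript models (exon structures) from a GTF file
#'
#' Only `exon` features are used; CDS and other feature types are ignored.
#' Exons are grouped by `transcript_id` and sorted by genomic start.
#'
#' @param path Path to a GTF file with `transcript_id` attributes.
#' @return A [GenomicRanges::GRangesList], one element per transcript,
#'   exons sorted by genomic start.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("exon features must carry a transcript_id attribute")
  exs <- GenomicRanges::split(gr, gr$transcript_id)
  GenomicRanges::sort(exs)
}

## Validates one transcript's exon GRanges: single chrom/strand, sorted,
## non-overlapping, within genome bounds when genome is supplied.
validate_exons <- function(exons, genome = NULL) {
  if (length(exons) == 0L) stop("transcript must have at least one exon")
  chrom <- unique(as.character(GenomicRanges::seqnames(exons)))
  strand <- unique(as.character(GenomicRanges::strand(exons)))
  if (length(chrom) != 1L) stop("transcript exons span multiple chromosomes")
  if (length(strand) != 1L || !strand %in% c("+", "-"))
    stop("transcript must have a single strand in {+,-}")
  st <- GenomicRanges::start(exons)
  en <- GenomicRanges::end(exons)
  if (is.unsorted(st)) stop("exons must be sorted by genomic start")
  if (length(exons) > 1L && any(st[-1L] <= en[-length(en)]))
    stop("exons overlap")
  if (!is.null(genome)) {
    if (!chrom %in% names(genome))
      stop("unknown chromosome: ", chrom)
    if (any(st < 1L) ||
        any(en > Biostrings::width(genome)[match(chrom, names(genome))]))
      stop("exon out of chromosome bounds on ", chrom)
  }
  invisible(list(chrom = chrom, strand = strand))
}

#' Extract the spliced sequence of a transcript
#'
#' Exon sequences are concatenated in 5'-to-3' transcript order: for a
#' minus-strand transcript this is the reverse complement of the exons
#' concatenated in descending genomic order.
#'
#' @param exons A [GenomicRanges::GRanges] of the transcript's exons
#'   (single chromosome and strand, sorted by genomic start), or a
#'   [GenomicRanges::GRangesList] of such objects.
#' @param genome A named [Biostrings::DNAStringSet].
#' @return A character string (or named character vector for a
#'   GRangesList input) with the spliced 5'-to-3' sequence.
#' @export
extract_transcript_sequence <- function(exons, genome) {
  if (is(exons, "GRangesList"))
    return(vapply(seq_along(exons), function(i)
      extract_transcript_sequence(exons[[i]], genome),
      character(1)) |> setNames(names(exons)))
  meta <- validate_exons(exons, genome)
  pieces <- as.character(Biostrings::extractAt(
    genome[[meta$chrom]],
    IRanges::IRanges(GenomicRanges::start(exons),
                     GenomicRanges::end(exons))))
  seq <- paste(pieces, collapse = "")
  if (meta$strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  seq
}

#' Three-frame translation with ATG-priority ORF extraction
#'
#' Each of the three forward reading frames is segmented at stop codons.
#' Within every inter-stop segment that contains at least one ATG, a
#' single ORF is emitted, starting at the most upstream ATG of the
#' segment and ending at the segment's closing stop codon (or at the last
#' complete codon of the transcript for 3'-truncated segments, which are
#' kept and flagged). Proteins longer than `max_aa` residues are
#' discarded. Codons containing N translate to X; proteins with more than
#' `max_x` X residues are dropped (`x_policy = "drop"` drops any ORF
#' whose protein contains X).
#'
#' @param tx_seq Spliced transcript sequence (character, ACGTN).
#' @param max_aa Maximum protein length in amino acids (default 150, the
#'   conventional smORF ceiling).
#' @param require_atg If `TRUE` (default) segments without an ATG yield
#'   nothing; if `FALSE` such segments emit a stop-to-stop ORF starting at
#'   the first codon of the segment.
#' @param x_policy `"translate"` (default) keeps proteins with at most
#'   `max_x` X residues; `"drop"` discards any ORF containing X.
#' @param max_x Maximum number of X residues tolerated per protein.
#' @return A data.frame with columns `frame` (0, 1, 2), `tx_start`,
#'   `tx_end` (1-based inclusive transcript coordinates; `tx_end` covers
#'   the stop codon when one terminates the ORF), `protein`,
#'   `started_at_atg` and `has_stop`.
#' @export
three_frame_orfs <- function(tx_seq, max_aa = 150L, require_atg = TRUE,
                             x_policy = c("translate", "drop"), max_x = 1L) {
  x_policy <- match.arg(x_policy)
  tx_seq <- toupper(tx_seq)
  if (nchar(tx_seq) < 3L) stop("transcript sequence shorter than one codon")
  acc <- list(frame = integer(), tx_start = integer(), tx_end = integer(),
              protein = character(), started_at_atg = logical(),
              has_stop = logical())
  gc_tab <- Biostrings::GENETIC_CODE
  for (frame in 0:2) {
    n_codon <- (nchar(tx_seq) - frame) %/% 3L
    if (n_codon < 1L) next
    codon_starts <- frame + 3L * (seq_len(n_codon) - 1L) + 1L
    codons <- substring(tx_seq, codon_starts, codon_starts + 2L)
    res <- unname(gc_tab[codons])
    res[is.na(res)] <- "X"          # codons containing N (or invalid)
    aa <- paste(res, collapse = "")
    stops <- which(res == "*")
    seg_start <- c(1L, stops + 1L)              # first codon of each segment
    seg_stop <- c(stops, length(res) + 1L)      # codon index of closing stop
    # index of the first M at or after each position
    is_m <- res == "M"
    # per segment, the most upstream start codon
    start_codon <- integer(0); seg_end <- integer(0); from_atg <- logical(0)
    for (k in seq_along(seg_start)) {
      s0 <- seg_start[k]; s1 <- seg_stop[k]
      if (s1 <= s0) next
      m <- which(is_m[s0:(s1 - 1L)])
      if (length(m) == 0L && require_atg) next
      start_codon <- c(start_codon,
                       if (length(m)) s0 + m[1L] - 1L else s0)
      seg_end <- c(seg_end, s1)
      from_atg <- c(from_atg, length(m) > 0L)
    }
    if (length(start_codon) == 0L) next
    prot <- substring(aa, start_codon, seg_end - 1L)
    keep <- nchar(prot) <= max_aa
    nx <- nchar(prot) - nchar(gsub("X", "", prot, fixed = TRUE))
    keep <- keep & if (x_policy == "drop") nx == 0L else nx <= max_x
    if (!any(keep)) next
    has_stop <- seg_end[keep] <= length(res)
    acc$frame <- c(acc$frame, rep.int(frame, sum(keep)))
    acc$tx_start <- c(acc$tx_start, frame + 3L * (start_codon[keep] - 1L) + 1L)
    acc$tx_end <- c(acc$tx_end,
                    frame + 3L * (seg_end[keep] - 1L) + ifelse(has_stop, 3L, 0L))
    acc$protein <- c(acc$protein, prot[keep])
    acc$started_at_atg <- c(acc$started_at_atg, from_atg[keep])
    acc$has_stop <- c(acc$has_stop, has_stop)
  }
  out <- data.frame(acc, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Map a transcript interval to genomic exon blocks
#'
#' Projects a 1-based closed interval in spliced-transcript coordinates
#' onto the genome through the transcript's exon structure, yielding the
#' minimal set of genomic blocks. Block widths always sum to the interval
#' length.
#'
#' @param exons Transcript exons as in [extract_transcript_sequence()].
#' @param tx_start,tx_end 1-based inclusive positions in the spliced
#'   transcript (5'-to-3').
#' @return A [GenomicRanges::GRanges] of blocks sorted by genomic start,
#'   carrying the transcript's strand.
#' @export
map_orf_to_genome <- function(exons, tx_start, tx_end) {
  meta <- validate_exons(exons)
  w <- GenomicRanges::width(exons)
  total <- sum(w)
  if (tx_start < 1L || tx_end > total || tx_start > tx_end)
    stop("interval [", tx_start, ",", tx_end, "] outside transcript of length ",
         total)
  # exon order along the transcript
  ord <- if (meta$strand == "+") seq_along(exons) else rev(seq_along(exons))
  offs <- cumsum(c(0L, w[ord]))[seq_along(ord)]     # tx offset before each exon
  blocks <- NULL
  for (i in seq_along(ord)) {
    e <- ord[i]
    lo <- offs[i] + 1L
    hi <- offs[i] + w[e]
    s <- max(tx_start, lo)
    t <- min(tx_end, hi)
    if (s > t) next
    if (meta$strand == "+") {
      gs <- GenomicRanges::start(exons)[e] + (s - lo)
      ge <- GenomicRanges::start(exons)[e] + (t - lo)
    } else {
      ge <- GenomicRanges::end(exons)[e] - (s - lo)
      gs <- GenomicRanges::end(exons)[e] - (t - lo)
    }
    blocks <- rbind(blocks, c(gs, ge))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = meta$chrom,
    ranges = IRanges::IRanges(start = blocks[, 1L], end = blocks[, 2L]),
    strand = meta$strand)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Predict smORF candidates from transcript models
#'
#' Runs [three_frame_orfs()] on every transcript and maps each ORF back to
#' genomic blocks. ORFs from different transcripts that resolve to the
#' same genomic footprint (same blocks, strand and frame) are merged into
#' one candidate whose `transcript_id` lists all source transcripts.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param tx_models [GenomicRanges::GRangesList] from
#'   [read_transcript_models()].
#' @inheritParams three_frame_orfs
#' @return A data.frame with one row per smORF candidate: `orf_id`
#'   (`chrom:start-end_strand_f<frame>`), `transcript_id`
#'   (semicolon-joined), `frame`, `tx_start`, `tx_end`, `protein`,
#'   `started_at_atg`, `has_stop`, and a list-column `blocks` of
#'   [GenomicRanges::GRanges] genomic blocks.
#' @export
predict_smorfs <- function(genome, tx_models, max_aa = 150L,
                           require_atg = TRUE,
                           x_policy = c("translate", "drop"), max_x = 1L) {
  x_policy <- match.arg(x_policy)
  rows <- list()
  for (tx_id in names(tx_models)) {
    exons <- tx_models[[tx_id]]
    seq <- extract_transcript_sequence(exons, genome)
    if (nchar(seq) < 3L) next
    orfs <- three_frame_orfs(seq, max_aa = max_aa, require_atg = require_atg,
                             x_policy = x_policy, max_x = max_x)
    if (nrow(orfs) == 0L) next
    for (i in seq_len(nrow(orfs))) {
      blocks <- map_orf_to_genome(exons, orfs$tx_start[i], orfs$tx_end[i])
      orf_id <- sprintf("%s:%d-%d_%s_f%d",
                        as.character(GenomicRanges::seqnames(blocks))[1L],
                        min(GenomicRanges::start(blocks)),
                        max(GenomicRanges::end(blocks)),
                        as.character(GenomicRanges::strand(blocks))[1L],
                        orfs$frame[i])
      rows[[length(rows) + 1L]] <- list(
        orf_id = orf_id, transcript_id = tx_id, frame = orfs$frame[i],
        tx_start = orfs$tx_start[i], tx_end = orfs$tx_end[i],
        protein = orfs$protein[i], started_at_atg = orfs$started_at_atg[i],
        has_stop = orfs$has_stop[i], blocks = blocks)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(orf_id = character(), transcript_id = character(),
                      frame = integer(), tx_start = integer(),
                      tx_end = integer(), protein = character(),
                      started_at_atg = logical(), has_stop = logical(),
                      blocks = I(list())))
  df <- data.frame(
    orf_id = vapply(rows, `[[`, "", "orf_id"),
    transcript_id = vapply(rows, `[[`, "", "transcript_id"),
    frame = vapply(rows, `[[`, 0L, "frame"),
    tx_start = vapply(rows, `[[`, 0L, "tx_start"),
    tx_end = vapply(rows, `[[`, 0L, "tx_end"),
    protein = vapply(rows, `[[`, "", "protein"),
    started_at_atg = vapply(rows, `[[`, NA, "started_at_atg"),
    has_stop = vapply(rows, `[[`, NA, "has_stop"),
    stringsAsFactors = FALSE)
  df$blocks <- I(lapply(rows, `[[`, "blocks"))
  # merge ORFs sharing a genomic footprint (overlapping isoforms)
  if (anyDuplicated(df$orf_id)) {
    keep <- !duplicated(df$orf_id)
    tx_by_id <- split(df$transcript_id, df$orf_id)
    df <- df[keep, , drop = FALSE]
    df$transcript_id <- vapply(
      df$orf_id, function(id) paste(unique(tx_by_id[[id]]), collapse = ";"), "")
  }
  rownames(df) <- NULL
  df
}

#' Assemble the tagged custom proteomics database
#'
#' Combines predicted smORF proteins (deduplicated on sequence, with
#' provenance ids merged), tagged reference-proteome entries and
#' contaminants, then appends one reversed-sequence decoy per forward
#' entry (decoy id `rev_<id>`). Categories partition the database and the
#' output order is deterministic: predicted, annotated, contaminant, then
#' decoys in the same order.
#'
#' @param predicted Either the data.frame from [predict_smorfs()] or a
#'   named character vector of predicted protein sequences.
#' @param reference Named character vector of annotated (reference
#'   proteome) sequences; may be empty.
#' @param contaminants Named character vector of contaminant sequences;
#'   may be empty.
#' @return A data.frame with columns `entry_id`, `protein`, `category`
#'   (`predicted`, `annotated`, `contaminant` or `decoy`), `source_id`
#'   (forward entry id for decoys, `NA` otherwise) and `orf_ids`
#'   (semicolon-joined provenance for predicted entries).
#' @export
build_custom_db <- function(predicted, reference = character(),
                            contaminants = character()) {
  if (is.data.frame(predicted)) {
    pred <- setNames(predicted$protein, predicted$orf_id)
  } else pred <- predicted
  stopifnot(is.character(pred), is.character(reference),
            is.character(contaminants))
  if (length(pred) && is.null(names(pred)))
    stop("predicted proteins must be named")
  # dedup predicted on protein sequence, merge provenance ids
  orf_ids <- character(0)
  if (length(pred)) {
    ids_by_seq <- split(names(pred), pred)[unique(pred)]
    pred <- setNames(unique(pred), vapply(ids_by_seq, `[[`, "", 1L))
    orf_ids <- vapply(ids_by_seq, paste, "", collapse = ";")
  }
  fwd <- data.frame(
    entry_id = c(names(pred), names(reference), names(contaminants)),
    protein = toupper(c(unname(pred), unname(reference), unname(contaminants))),
    category = rep(c("predicted", "annotated", "contaminant"),
                   c(length(pred), length(reference), length(contaminants))),
    source_id = NA_character_,
    orf_ids = c(unname(orf_ids), rep(NA_character_,
                                     length(reference) + length(contaminants))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(fwd$entry_id))
    stop("duplicate entry ids across database categories: ",
         paste(unique(fwd$entry_id[duplicated(fwd$entry_id)]), collapse = ", "))
  dec <- data.frame(
    entry_id = paste0("rev_", fwd$entry_id),
    protein = as.character(Biostrings::reverse(
      Biostrings::BStringSet(fwd$protein))),
    category = "decoy",
    source_id = fwd$entry_id,
    orf_ids = NA_character_,
    stringsAsFactors = FALSE)
  out <- rbind(fwd, dec)
  rownames(out) <- NULL
  out
}

#' Write / read a tagged database FASTA
#'
#' Headers carry the category tag in the form
#' `>entry_id|cat=predicted|orfs=id1;id2` so that post-processing can
#' recognize annotated sequences to be removed.
#'
#' @param db Database data.frame from [build_custom_db()].
#' @param path Output FASTA path.
#' @return `write_db_fasta` invisibly returns `path`; `read_db_fasta`
#'   returns a database data.frame.
#' @export
write_db_fasta <- function(db, path) {
  hdr <- paste0(db$entry_id, "|cat=", db$category,
                ifelse(is.na(db$orf_ids), "", paste0("|orfs=", db$orf_ids)),
                ifelse(is.na(db$source_id), "", paste0("|src=", db$source_id)))
  aa <- Biostrings::BStringSet(setNames(db$protein, hdr))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname write_db_fasta
#' @export
read_db_fasta <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  hdr <- names(aa)
  field <- function(key) {
    m <- regmatches(hdr, regexpr(paste0("\\|", key, "=[^|]*"), hdr))
    out <- rep(NA_character_, length(hdr))
    hit <- grepl(paste0("\\|", key, "="), hdr)
    out[hit] <- sub(paste0("^\\|", key, "="), "", m)
    out
  }
  data.frame(
    entry_id = sub("\\|.*$", "", hdr),
    protein = as.character(aa),
    category = field("cat"),
    source_id = field("src"),
    orf_ids = field("orfs"),
    stringsAsFactors = FALSE)
}

#' Write smORF candidates to a GTF file
#'
#' Emits one `transcript` line spanning each smORF plus one `exon` line
#' per genomic block, 1-based closed coordinates, strand preserved.
#' `gene_id` and `transcript_id` are both set to the `orf_id`.
#'
#' @param orfs data.frame from [predict_smorfs()] (needs `orf_id` and the
#'   `blocks` list-column).
#' @param path Output GTF path.
#' @return Invisibly, `path`.
#' @export
write_smorf_gtf <- function(orfs, path) {
  grs <- list()
  for (i in seq_len(nrow(orfs))) {
    b <- orfs$blocks[[i]]
    span <- range(GenomicRanges::granges(b))
    S4Vectors::mcols(span) <- S4Vectors::DataFrame(
      type = "transcript", gene_id = orfs$orf_id[i],
      transcript_id = orfs$orf_id[i])
    bb <- GenomicRanges::granges(b)
    S4Vectors::mcols(bb) <- S4Vectors::DataFrame(
      type = "exon", gene_id = orfs$orf_id[i],
      transcript_id = orfs$orf_id[i])
    grs[[length(grs) + 1L]] <- c(span, bb)
  }
  if (length(grs) == 0L) {
    writeLines("#gtf: no smORF records", path)
    return(invisible(path))
  }
  gr <- suppressWarnings(do.call(c, grs))
  gr$source <- "smorfkit"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a smORF GTF back into genomic blocks
#'
#' @param path GTF written by [write_smorf_gtf()] (or any GTF whose exon
#'   features carry `transcript_id`).
#' @return A [GenomicRanges::GRangesList] of exon blocks, one element per
#'   smORF, sorted by genomic start.
#' @export
read_smorf_gtf <- function(path) {
  read_transcript_models(path)
}
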