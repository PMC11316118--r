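#' Read a reference annotation GTF for smORF classification
#'
#' Imports the GTF and returns the feature sets the classifier needs:
#' transcript records (with biotype), CDS and five_prime_utr features.
#' The biotype is taken from `transcript_biotype` when present, falling
#' back to `gene_biotype`.
#'
#' @param path Reference GTF path.
#' @return A list with `transcripts`, `cds` and `utr5`
#'   ([GenomicRanges::GRanges] each; `transcripts` carries a `biotype`
#'   metadata column).
#' @export
read_reference_annotation <- function(path) {
  as_reference_annotation(rtracklayer::import(path, format = "gtf"))
}

#' Coerce an annotation GRanges to the classifier's feature sets
#'
#' @param gr A [GenomicRanges::GRanges] with a `type` column
#'   (`transcript`, `CDS`, `five_prime_utr`) and biotype attributes, as
#'   produced by `rtracklayer::import` on a GTF or by [make_genome()].
#' @return See [read_reference_annotation()].
#' @export
as_reference_annotation <- function(gr) {
  tx <- gr[gr$type == "transcript"]
  bt <- if (!is.null(tx$transcript_biotype)) tx$transcript_biotype else
    tx$gene_biotype
  if (is.null(bt)) {
    warning("no biotype attribute in annotation; ",
            "falling back to coordinate-only rules")
    bt <- rep(NA_character_, length(tx))
  }
  tx$biotype <- bt
  list(transcripts = tx,
       cds = gr[gr$type == "CDS"],
       utr5 = gr[gr$type == "five_prime_utr"])
}

#' Count reference features overlapping each smORF
#'
#' Number of distinct reference features (transcript records by default)
#' sharing at least one base with any block of the smORF. Unstranded, as
#' isoform density is a property of the locus.
#'
#' @param smorf_blocks Named [GenomicRanges::GRangesList] of smORF
#'   genomic blocks (e.g. from [read_smorf_gtf()]).
#' @param reference A [GenomicRanges::GRanges] of reference features, or
#'   the list from [read_reference_annotation()] (its `transcripts` are
#'   used).
#' @return Named integer vector, one count per smORF.
#' @export
count_overlapping_features <- function(smorf_blocks, reference) {
  if (is.list(reference) && !is(reference, "GRanges"))
    reference <- reference$transcripts
  smorf_blocks <- as_feature_list(smorf_blocks)
  hits <- GenomicRanges::findOverlaps(smorf_blocks, reference,
                                      ignore.strand = TRUE)
  n <- tabulate(S4Vectors::queryHits(hits), nbins = length(smorf_blocks))
  setNames(n, names(smorf_blocks))
}

#' Classify smORFs by genomic context
#'
#' Assigns exactly one class per smORF by precedence-ordered rules:
#' \enumerate{
#'   \item overlaps a pseudogene or retrotransposon-derived biotype ->
#'     `rtORF`;
#'   \item overlaps an annotated CDS on the same strand with compatible
#'     reading frame (an alternative initiation site of that ORF) ->
#'     `aiORF`;
#'   \item entirely within the 5' UTR of a coding transcript on the same
#'     strand -> `uORF`;
#'   \item within a `retained_intron` transcript -> `riORF`;
#'   \item within a lncRNA biotype -> `lncORF`;
#'   \item overlaps no annotated transcript -> `noncoding`;
#'   \item otherwise `other-overlap`.
#' }
#' The precedence order is recorded in the `"precedence"` attribute of
#' the result. Frame compatibility for `aiORF` is assessed on genomic
#' coordinates of the 5'-most blocks (a single-exon heuristic).
#'
#' @param smorf_blocks Named [GenomicRanges::GRangesList] of smORF
#'   blocks, strand set.
#' @param annotation List from [read_reference_annotation()].
#' @return A data.frame with `smorf_id` and `label`.
#' @export
classify_smorfs <- function(smorf_blocks, annotation) {
  smorf_blocks <- as_feature_list(smorf_blocks)
  tx <- annotation$transcripts
  cds <- annotation$cds
  utr5 <- annotation$utr5
  rt_like <- grepl("pseudogene|retrotransposon", tx$biotype %||% "",
                   ignore.case = TRUE)
  labels <- vapply(seq_along(smorf_blocks), function(i) {
    b <- smorf_blocks[[i]]
    strand <- as.character(GenomicRanges::strand(b))[1L]
    tx_hits <- GenomicRanges::findOverlaps(b, tx, ignore.strand = TRUE)
    tx_idx <- unique(S4Vectors::subjectHits(tx_hits))
    if (any(rt_like[tx_idx])) return("rtORF")
    # aiORF: same-strand, frame-compatible CDS overlap
    if (length(cds)) {
      ch <- GenomicRanges::findOverlaps(b, cds, ignore.strand = FALSE)
      for (j in unique(S4Vectors::subjectHits(ch))) {
        if (strand == "+") {
          ph <- (min(GenomicRanges::start(b)) -
                   GenomicRanges::start(cds)[j]) %% 3L
        } else {
          ph <- (GenomicRanges::end(cds)[j] -
                   max(GenomicRanges::end(b))) %% 3L
        }
        if (ph == 0L) return("aiORF")
      }
    }
    # uORF: fully contained in same-strand 5' UTR of a coding transcript
    if (length(utr5)) {
      utx <- unique(utr5$transcript_id)
      coding_tx <- unique(cds$transcript_id)
      for (t in intersect(utx, coding_tx)) {
        u <- utr5[utr5$transcript_id == t]
        if (as.character(GenomicRanges::strand(u))[1L] != strand) next
        uncovered <- GenomicRanges::setdiff(b, u, ignore.strand = TRUE)
        if (sum(GenomicRanges::width(uncovered)) == 0L) return("uORF")
      }
    }
    bts <- tolower(tx$biotype[tx_idx] %||% character(0))
    if (any(bts == "retained_intron", na.rm = TRUE)) return("riORF")
    if (any(bts %in% c("lncrna", "lincrna"), na.rm = TRUE)) return("lncORF")
    if (length(tx_idx) == 0L) return("noncoding")
    "other-overlap"
  }, character(1))
  out <- data.frame(smorf_id = names(smorf_blocks), label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "precedence") <-
    c("rtORF", "aiORF", "uORF", "riORF", "lncORF", "noncoding",
      "other-overlap")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag smORFs residing in repeat regions
#'
#' @param smorf_blocks Named [GenomicRanges::GRangesList].
#' @param repeats A [GenomicRanges::GRanges] of repeat intervals (e.g.
#'   `rtracklayer::import(bed)`), ideally with a `name` column.
#' @return A data.frame with `smorf_id`, `in_repeat` (>= 1 base overlap)
#'   and `repeat_names` (semicolon-joined).
#' @export
repeat_overlap <- function(smorf_blocks, repeats) {
  smorf_blocks <- as_feature_list(smorf_blocks)
  hits <- GenomicRanges::findOverlaps(smorf_blocks, repeats,
                                      ignore.strand = TRUE)
  nm <- if (!is.null(repeats$name)) repeats$name else
    as.character(seq_along(repeats))
  by_q <- split(nm[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
  rep_names <- rep("", length(smorf_blocks))
  rep_names[as.integer(names(by_q))] <-
    vapply(by_q, function(x) paste(unique(x), collapse = ";"), "")
  data.frame(smorf_id = names(smorf_blocks),
             in_repeat = seq_along(smorf_blocks) %in%
               S4Vectors::queryHits(hits),
             repeat_names = rep_names,
             stringsAsFactors = FALSE)
}

#' Conservation presence matrix from homology hit tables
#'
#' Filters tabular homology hits (tBLASTN-style) to those with E-value
#' < `max_evalue` and bit score > `min_bitscore` (strict inequalities),
#' then reports per-smORF, per-species presence and the number of
#' species in which each smORF is conserved.
#'
#' @param hits Data.frame with columns `smorf_id`, `species`, `e_value`,
#'   `bit_score`.
#' @param species_list Character vector fixing the column order of the
#'   matrix; defaults to the species present in `hits`.
#' @param max_evalue,min_bitscore Filter thresholds (defaults 1e-3, 50).
#' @return A list with `presence` (logical smORF x species matrix) and
#'   `n_species` (named integer vector).
#' @export
conservation_counts <- function(hits, species_list = NULL,
                                max_evalue = 1e-3, min_bitscore = 50) {
  need <- c("smorf_id", "species", "e_value", "bit_score")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(hits$e_value < 0)) stop("negative E-value")
  kept <- hits[hits$e_value < max_evalue & hits$bit_score > min_bitscore, ,
               drop = FALSE]
  if (is.null(species_list)) species_list <- sort(unique(hits$species))
  ids <- sort(unique(hits$smorf_id))
  presence <- matrix(FALSE, length(ids), length(species_list),
                     dimnames = list(ids, species_list))
  if (nrow(kept))
    presence[cbind(match(kept$smorf_id, ids),
                   match(kept$species, species_list))] <- TRUE
  list(presence = presence, n_species = rowSums(presence))
}
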